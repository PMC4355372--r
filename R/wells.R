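#' Canonicalize 96-well plate labels
#'
#' Converts well labels to the canonical letter-row + 1-based column form
#' without zero padding ("A1"), accepting the zero-padded dialect ("A01")
#' emitted by some plate readers. Labels outside the 96-well grid
#' (rows A-H, columns 1-12) are rejected.
#'
#' @param x character vector of well labels.
#' @return character vector of canonical labels.
#' @examples
#' canonical_well(c("A01", "h12"))
#' @export
canonical_well <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regmatches(x, regexec("^([A-H])0?([1-9][0-9]?)$", x))
  bad <- vapply(m, length, 1L) == 0L
  col <- rep(NA_integer_, length(x))
  row <- rep(NA_character_, length(x))
  row[!bad] <- vapply(m[!bad], `[`, "", 2L)
  col[!bad] <- as.integer(vapply(m[!bad], `[`, "", 3L))
  bad <- bad | (!is.na(col) & (col < 1L | col > 12L))
  if (any(bad)) {
    stop("malformed or out-of-grid well label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected rows A-H, columns 1-12)")
  }
  paste0(row, col)
}

#' All wells of a 96-well plate
#'
#' @return character vector of the 96 canonical well labels in row-major
#'   order (A1..A12, B1..B12, ..., H12).
#' @export
well_grid <- function() {
  paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, times = 8L))
}

#' Row letter and column number of a well label
#'
#' @param x character vector of (canonicalizable) well labels.
#' @return data.frame with columns `well`, `row`, `col`.
#' @export
well_position <- function(x) {
  w <- canonical_well(x)
  data.frame(well = w,
             row = substr(w, 1L, 1L),
             col = as.integer(substring(w, 2L)),
             stringsAsFactors = FALSE)
}
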
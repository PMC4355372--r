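#' @keywords internal
.plate_map_cols <- c("screen", "session", "plate", "well", "sirna", "role", "dose")

.known_roles <- c("sample", "neg_control", "pos_control", "empty")

.treated_flag <- function(map) {
  if ("arm" %in% names(map)) map$arm == "ir" else map$dose > 0
}

#' Validate a plate map
#'
#' Checks the structural invariants of a screen plate map: canonical 96-well
#' labels, known roles, non-negative doses, and uniqueness of
#' (screen, session, plate, arm, well) where the arm is the `arm` column if
#' present and otherwise derived from dose > 0. Plate identifiers name
#' library plates and are shared by the irradiated and non-irradiated
#' replicate copies, which are distinguished by arm.
#'
#' @param map data.frame with columns screen, session, plate, well, sirna,
#'   role, dose (and optionally arm).
#' @param require_controls if TRUE, additionally require at least 2
#'   neg_control and 2 pos_control wells on every physical plate (needed for
#'   assay QC).
#' @return the validated map, invisibly, with canonicalized well labels.
#' @export
validate_plate_map <- function(map, require_controls = FALSE) {
  missing_cols <- setdiff(.plate_map_cols, names(map))
  if (length(missing_cols)) {
    stop("plate map is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  map$well <- canonical_well(map$well)
  bad_role <- setdiff(unique(map$role), .known_roles)
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "),
         " (expected one of ", paste(.known_roles, collapse = ", "), ")")
  }
  if (!is.numeric(map$dose) || anyNA(map$dose) || any(map$dose < 0)) {
    stop("dose must be numeric and >= 0 for every well")
  }
  key <- paste(map$screen, map$session, map$plate, .treated_flag(map), map$well,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- map[duplicated(key), c("plate", "well"), drop = FALSE]
    stop("duplicate (plate, well) within a screen/session/arm: ",
         paste(unique(paste0(dup$plate, ":", dup$well)), collapse = ", "))
  }
  if (require_controls) {
    pkey <- paste(map$screen, map$session, map$plate, .treated_flag(map), sep = "\r")
    n_neg <- tapply(map$role == "neg_control", pkey, sum)
    n_pos <- tapply(map$role == "pos_control", pkey, sum)
    if (any(n_neg < 2L) || any(n_pos < 2L)) {
      stop("every plate needs >= 2 neg_control and >= 2 pos_control wells ",
           "when screen QC is requested")
    }
  }
  invisible(map)
}

#' Read a plate map from CSV
#'
#' Column order-insensitive; extra columns are carried through. See
#' [validate_plate_map()] for the checks applied.
#'
#' @param path path to a CSV file with a header row.
#' @return validated plate map data.frame in canonical column order.
#' @export
read_plate_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plate_map(map)
  map$well <- canonical_well(map$well)
  extra <- setdiff(names(map), .plate_map_cols)
  map <- map[, c(.plate_map_cols, extra), drop = FALSE]
  rownames(map) <- NULL
  map
}

#' Write a plate map to CSV
#'
#' @param map a validated plate map.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_plate_map <- function(map, path) {
  validate_plate_map(map)
  utils::write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a laser-scan object table from CSV
#'
#' One row per detected fluorescent object with its well, linear extents in
#' micrometres and fluorescence intensity. Rows with non-positive extents or
#' negative intensity are rejected rather than coerced.
#'
#' @param path path to a CSV with columns well, width_um, depth_um, intensity.
#' @return data.frame of validated objects with canonical well labels.
#' @export
read_object_table <- function(path) {
  obj <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("well", "width_um", "depth_um", "intensity")
  missing_cols <- setdiff(needed, names(obj))
  if (length(missing_cols)) {
    stop("object table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(obj)) {
    obj$well <- canonical_well(obj$well)
    if (any(obj$width_um <= 0) || any(obj$depth_um <= 0)) {
      stop("object dimensions (width_um, depth_um) must be > 0")
    }
    if (any(obj$intensity < 0)) stop("intensity must be >= 0")
  }
  obj[, needed, drop = FALSE]
}

#' Group scan objects by well
#'
#' @param objects object table as returned by [read_object_table()].
#' @param wells optional character vector of wells (e.g. from a plate map);
#'   wells absent from the table yield empty groups, and the result is
#'   restricted to these wells.
#' @return named list of per-well data.frames.
#' @export
group_objects <- function(objects, wells = NULL) {
  if (is.null(wells)) {
    wells <- sort(unique(objects$well))
  } else {
    wells <- canonical_well(wells)
  }
  f <- factor(objects$well, levels = wells)
  unmapped <- sum(is.na(f))
  if (unmapped > 0L) {
    warning(unmapped, " object(s) in wells not covered by the supplied wells")
  }
  split(objects[!is.na(f), , drop = FALSE], f[!is.na(f)], drop = FALSE)
}

#' Read a per-well count table (plate map columns plus counts)
#'
#' @param path CSV path; must contain the plate-map columns plus `count`.
#' @return validated data.frame.
#' @export
read_well_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"count" %in% names(rec)) stop("well record table must have a 'count' column")
  if (any(rec$count < 0)) stop("counts must be >= 0")
  validate_plate_map(rec)
  rec$well <- canonical_well(rec$well)
  rec
}

#' Write a per-well record table to CSV
#'
#' @param records data.frame of well records.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_well_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
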
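#' Robust Z'-factor
#'
#' Nonparametric assay-window metric between positive and negative control
#' populations: Z' = 1 - 3 (s_pos + s_neg) / |median(pos) - median(neg)|,
#' with s the median absolute deviation scaled for Normal consistency
#' (1.4826 by default). Z' > 0 indicates the two control groups are
#' resolvable well enough for hit identification; identically distributed
#' overlapping groups give negative values. Equal medians make Z'
#' undefined; NA is returned with a warning rather than an error so batch
#' reports can flag the session.
#'
#' @param pos,neg numeric control values (>= 3 each).
#' @param scale_constant MAD consistency constant.
#' @return robust Z' (<= 1), or NA if the medians coincide.
#' @examples
#' robust_zprime(rnorm(20, 0, 0.5), rnorm(20, 10, 0.5))
#' @export
robust_zprime <- function(pos, neg, scale_constant = 1.4826) {
  if (length(pos) < 3L || length(neg) < 3L) {
    stop("need >= 3 values per control group")
  }
  sep <- abs(stats::median(pos) - stats::median(neg))
  if (sep == 0) {
    warning("medians coincide; robust Z' undefined")
    return(NA_real_)
  }
  s_pos <- stats::mad(pos, constant = scale_constant)
  s_neg <- stats::mad(neg, constant = scale_constant)
  1 - 3 * (s_pos + s_neg) / sep
}

#' Robust Z' assay quality per session and arm
#'
#' Computes the robust Z' between PRKDC positive-control and non-targeting
#' negative-control wells for every (screen, session, arm) cell of a
#' normalized screen - the per-session view in which a screenable assay
#' shows positive Z' in the irradiated arm and negative Z' in the
#' non-irradiated arm, where the controls are not resolvable.
#'
#' @param wells normalized well records with role and normalized columns.
#' @param scale_constant passed to [robust_zprime()].
#' @return data.frame: screen, session, arm, n_pos, n_neg, median_pos,
#'   median_neg, scale_pos, scale_neg, zprime, undefined flag.
#' @export
screen_qc <- function(wells, scale_constant = 1.4826) {
  if (!"normalized" %in% names(wells)) {
    stop("wells must carry a 'normalized' column; run normalize_screen() first")
  }
  treated <- .treated_flag(wells)
  arm <- ifelse(treated, "ir", "mock")
  key <- unique(data.frame(screen = wells$screen, session = wells$session,
                           arm = arm, stringsAsFactors = FALSE))
  key <- key[order(key$screen, key$session, key$arm), , drop = FALSE]
  res <- lapply(seq_len(nrow(key)), function(i) {
    sel <- wells$screen == key$screen[i] & wells$session == key$session[i] &
      arm == key$arm[i]
    pos <- wells$normalized[sel & wells$role == "pos_control"]
    neg <- wells$normalized[sel & wells$role == "neg_control"]
    z <- suppressWarnings(robust_zprime(pos, neg, scale_constant))
    data.frame(key[i, , drop = FALSE],
               n_pos = length(pos), n_neg = length(neg),
               median_pos = stats::median(pos), median_neg = stats::median(neg),
               scale_pos = stats::mad(pos, constant = scale_constant),
               scale_neg = stats::mad(neg, constant = scale_constant),
               zprime = z, undefined = is.na(z),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between paired replicate measurements
#'
#' @param rep1,rep2 paired numeric vectors (>= 3 pairs).
#' @return Pearson product-moment correlation.
#' @export
replicate_correlation <- function(rep1, rep2) {
  if (length(rep1) != length(rep2)) stop("replicate vectors must be paired")
  if (length(rep1) < 3L) stop("need >= 3 pairs")
  if (stats::var(rep1) == 0 || stats::var(rep2) == 0) {
    stop("zero variance in a replicate vector")
  }
  stats::cor(rep1, rep2)
}

#' Between-screen replicate correlation per treatment arm
#'
#' Pairs the per-siRNA mean normalized values of sample wells across the
#' two replicate screens, separately for the irradiated and mock arms, and
#' reports the Pearson correlation - the inter-assay reproducibility
#' summary of the screen.
#'
#' @param wells normalized well records covering exactly two screens.
#' @return data.frame: arm, r, n_pairs.
#' @export
screen_replicate_correlation <- function(wells) {
  if (!"normalized" %in% names(wells)) {
    stop("wells must carry a 'normalized' column; run normalize_screen() first")
  }
  screens <- sort(unique(wells$screen))
  if (length(screens) != 2L) {
    stop("replicate correlation needs exactly 2 screens, found ", length(screens))
  }
  treated <- .treated_flag(wells)
  smp <- wells$role == "sample"
  out <- lapply(c(ir = TRUE, mock = FALSE), function(tr) {
    sel <- smp & treated == tr
    v <- tapply(wells$normalized[sel],
                list(wells$sirna[sel], wells$screen[sel]), mean)
    v <- v[stats::complete.cases(v), , drop = FALSE]
    data.frame(arm = if (tr) "ir" else "mock",
               r = replicate_correlation(v[, 1], v[, 2]),
               n_pairs = nrow(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
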
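#' Remove plate, session and screen effects from log2 counts
#'
#' Fits one linear model to the log2 counts of the entire experiment
#' simultaneously: log2 = mu + treatment + technical(plate-in-session-in-
#' screen), where the technical term is a sum-to-zero factor over library
#' plates (each spanning its irradiated and non-irradiated replicate copy)
#' whose estimates are decomposed into nested screen, session and plate
#' offsets. The normalized value is log2 minus the technical estimate; the
#' treatment effect is in the model but never subtracted, so the
#' irradiation effect is preserved - every corrected factor involves both
#' irradiated and non-irradiated observations. Joint estimation over all
#' wells makes the offsets insensitive to deviations on a few wells; a
#' Huber iteratively-reweighted variant is available for explicit
#' resistance to outliers.
#'
#' @param wells well records with columns screen, session, plate, dose
#'   (and/or arm), and `count` or a precomputed `log2` column. When only
#'   counts are present, log2(count + pseudocount) is used, the pseudocount
#'   guarding empty or failed wells.
#' @param method "ols" (default) or "robust" (Huber M-estimation via
#'   [MASS::rlm()]).
#' @param pseudocount added to counts before the log2 transform.
#' @return list of class `screen_normalization`: `wells` (input plus
#'   `log2`, `normalized`), `effects` (screen/session/plate offset tables,
#'   `treatment` effect in log2 units, `grand_mean`), `method`.
#' @export
normalize_screen <- function(wells, method = c("ols", "robust"), pseudocount = 1) {
  method <- match.arg(method)
  needed <- c("screen", "session", "plate")
  missing_cols <- setdiff(needed, names(wells))
  if (length(missing_cols)) {
    stop("well records are missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"log2" %in% names(wells)) {
    if (!"count" %in% names(wells)) stop("need a 'count' or 'log2' column")
    wells$log2 <- log2(wells$count + pseudocount)
  }
  treated <- .treated_flag(wells)
  if (!any(treated) || all(treated)) {
    stop("normalization needs both irradiated and non-irradiated wells")
  }
  sess_key <- paste0("screen ", wells$screen, ", session ", wells$session)
  one_armed <- tapply(treated, sess_key, function(z) !(any(z) && any(!z)))
  if (any(one_armed)) {
    stop("session(s) lacking one treatment arm: ",
         paste(names(one_armed)[one_armed], collapse = "; "))
  }

  pair <- interaction(wells$screen, wells$session, wells$plate,
                      drop = TRUE, lex.order = TRUE)
  y <- wells$log2
  mm <- stats::model.matrix(~ treated + pair,
                            data = data.frame(treated = treated, pair = pair),
                            contrasts.arg = list(pair = "contr.sum"))
  if (qr(mm)$rank < ncol(mm)) stop("singular design: technical factors are confounded")
  fit <- if (method == "ols") {
    stats::lm.fit(mm, y)
  } else {
    MASS::rlm(mm, y, psi = MASS::psi.huber, maxit = 100)
  }
  cf <- stats::coef(fit)
  P <- nlevels(pair)
  b <- cf[grep("^pair", names(cf))]
  pair_eff <- c(b, -sum(b))
  names(pair_eff) <- levels(pair)

  meta <- unique(data.frame(screen = wells$screen, session = wells$session,
                            plate = wells$plate, pair = as.character(pair),
                            stringsAsFactors = FALSE))
  meta <- meta[match(levels(pair), meta$pair), , drop = FALSE]
  meta$effect <- pair_eff

  scr <- tapply(meta$effect, meta$screen, mean)
  scr <- scr - mean(meta$effect)                 # anchor at overall zero
  ses_key <- paste(meta$screen, meta$session, sep = "\r")
  ses <- tapply(meta$effect, ses_key, mean)
  ses_screen <- vapply(strsplit(names(ses), "\r"), `[`, "", 1L)
  ses <- ses - mean(meta$effect) - scr[ses_screen]
  plt <- meta$effect - mean(meta$effect) -
    scr[as.character(meta$screen)] - ses[paste(meta$screen, meta$session, sep = "\r")]

  total_corr <- pair_eff[as.character(pair)] - mean(meta$effect)
  wells$normalized <- y - unname(total_corr)

  effects <- list(
    screen = data.frame(screen = names(scr), offset = unname(scr),
                        stringsAsFactors = FALSE),
    session = data.frame(screen = ses_screen,
                         session = vapply(strsplit(names(ses), "\r"), `[`, "", 2L),
                         offset = unname(ses), stringsAsFactors = FALSE),
    plate = data.frame(meta[, c("screen", "session", "plate")],
                       offset = unname(plt), stringsAsFactors = FALSE),
    treatment = unname(cf["treatedTRUE"]),
    grand_mean = mean(y)
  )
  out <- list(wells = wells, effects = effects, method = method)
  class(out) <- "screen_normalization"
  out
}

#' @export
print.screen_normalization <- function(x, ...) {
  cat(sprintf("Screen normalization (%s) of %d wells\n", x$method, nrow(x$wells)))
  cat(sprintf("  treatment effect: %.3f log2 units\n", x$effects$treatment))
  cat(sprintf("  offsets: %d screen, %d session, %d plate (sum-to-zero)\n",
              nrow(x$effects$screen), nrow(x$effects$session),
              nrow(x$effects$plate)))
  invisible(x)
}

#' Normalization quality report
#'
#' Summarizes what the correction removed and proves what it preserved:
#' variance explained by the technical (plate-level) factor before and
#' after normalization, and the treatment effect (mean irradiated minus
#' mean non-irradiated) before vs after, which must agree to numerical
#' tolerance because the treatment term is never subtracted.
#'
#' @param norm a `screen_normalization` object.
#' @return list: `variance` data.frame (factor, r2_before, r2_after),
#'   `treatment_before`, `treatment_after`.
#' @export
qc_normalization <- function(norm) {
  stopifnot(inherits(norm, "screen_normalization"))
  w <- norm$wells
  treated <- .treated_flag(w)
  r2_of <- function(value, f) {
    fit <- stats::lm.fit(stats::model.matrix(~ f), value)
    1 - sum(fit$residuals^2) / sum((value - mean(value))^2)
  }
  fs <- list(screen = factor(w$screen),
             session = interaction(w$screen, w$session, drop = TRUE),
             plate = interaction(w$screen, w$session, w$plate, drop = TRUE))
  variance <- data.frame(
    factor = names(fs),
    r2_before = vapply(fs, function(f) r2_of(w$log2, f), 0),
    r2_after = vapply(fs, function(f) r2_of(w$normalized, f), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  list(variance = variance,
       treatment_before = mean(w$log2[treated]) - mean(w$log2[!treated]),
       treatment_after = mean(w$normalized[treated]) - mean(w$normalized[!treated]))
}
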
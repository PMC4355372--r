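#' Interaction test between irradiation and one siRNA
#'
#' Fits the two-factor linear model value ~ treatment + group +
#' treatment:group, where group contrasts the siRNA's wells against pooled
#' non-targeting control wells, by least squares on the saturated 2x2
#' cell-means parameterization. The interaction coefficient is the
#' difference between the siRNA's irradiation effect and the controls'
#' irradiation effect, in log2 units; its t-statistic uses the pooled
#' within-cell residual variance with N - 4 degrees of freedom. A negative
#' estimate means the knockdown lowers survival specifically in
#' combination with irradiation (radiosensitization).
#'
#' @param sirna_ir,sirna_mock normalized values of the siRNA's wells with
#'   and without IR (>= 1 each).
#' @param control_ir,control_mock normalized values of the pooled negative
#'   control wells (>= 2 each).
#' @return list: estimate, se, t, df, p (two-sided).
#' @export
test_sirna <- function(sirna_ir, sirna_mock, control_ir, control_mock) {
  ns <- c(length(control_mock), length(control_ir),
          length(sirna_mock), length(sirna_ir))
  if (ns[3] < 1L || ns[4] < 1L) stop("need >= 1 siRNA well per arm")
  if (ns[1] < 2L || ns[2] < 2L) stop("need >= 2 control wells per arm")
  cells <- list(control_mock, control_ir, sirna_mock, sirna_ir)
  m <- vapply(cells, mean, 0)
  ss <- vapply(cells, function(v) sum((v - mean(v))^2), 0)
  df <- sum(ns) - 4L
  if (df <= 0L) stop("zero residual degrees of freedom")
  s2 <- sum(ss) / df
  estimate <- (m[4] - m[3]) - (m[2] - m[1])
  se <- sqrt(s2 * sum(1 / ns))
  t <- estimate / se
  list(estimate = unname(estimate), se = unname(se), t = unname(t),
       df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Interaction tests for every sample siRNA of a normalized screen
#'
#' Applies [test_sirna()] to each sample siRNA, comparing its wells (both
#' arms, all replicates) against all pooled non-targeting control wells of
#' the experiment. Plate, session and screen effects are assumed already
#' removed by [normalize_screen()], so per-plate control matching is not
#' needed.
#'
#' @param wells normalized well records (the `wells` element of a
#'   `screen_normalization`), with columns sirna, role, normalized and
#'   dose/arm.
#' @return data.frame: sirna, estimate, se, t, df, p, n_wells.
#' @export
screen_hit_tests <- function(wells) {
  if (!"normalized" %in% names(wells)) {
    stop("wells must carry a 'normalized' column; run normalize_screen() first")
  }
  treated <- .treated_flag(wells)
  ctrl <- wells$role == "neg_control"
  if (sum(ctrl & treated) < 2L || sum(ctrl & !treated) < 2L) {
    stop("need >= 2 pooled negative control wells per arm")
  }
  c_ir <- wells$normalized[ctrl & treated]
  c_mock <- wells$normalized[ctrl & !treated]
  c_stats <- c(n_ir = length(c_ir), n_mock = length(c_mock),
               m_ir = mean(c_ir), m_mock = mean(c_mock),
               ss_ir = sum((c_ir - mean(c_ir))^2),
               ss_mock = sum((c_mock - mean(c_mock))^2))

  smp <- wells[wells$role == "sample", , drop = FALSE]
  s_treated <- treated[wells$role == "sample"]
  key <- paste(smp$sirna, s_treated, sep = "\r")
  n_k <- tapply(rep(1L, nrow(smp)), key, sum)
  m_k <- tapply(smp$normalized, key, mean)
  ss_k <- tapply(smp$normalized, key, function(v) sum((v - mean(v))^2))
  ids <- sort(unique(smp$sirna))
  k_ir <- paste(ids, TRUE, sep = "\r")
  k_mock <- paste(ids, FALSE, sep = "\r")
  if (anyNA(match(c(k_ir, k_mock), names(n_k)))) {
    stop("every sample siRNA needs wells in both arms")
  }
  n1 <- n_k[k_ir]; n0 <- n_k[k_mock]
  est <- (m_k[k_ir] - m_k[k_mock]) - (c_stats["m_ir"] - c_stats["m_mock"])
  df <- n1 + n0 + c_stats["n_ir"] + c_stats["n_mock"] - 4
  s2 <- (ss_k[k_ir] + ss_k[k_mock] + c_stats["ss_ir"] + c_stats["ss_mock"]) / df
  se <- sqrt(s2 * (1 / n1 + 1 / n0 + 1 / c_stats["n_ir"] + 1 / c_stats["n_mock"]))
  t <- est / se
  data.frame(sirna = ids, estimate = unname(est), se = unname(se),
             t = unname(t), df = unname(df),
             p = unname(2 * stats::pt(-abs(t), df)),
             n_wells = unname(n1 + n0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call radiosensitizer hits with FDR control
#'
#' Benjamini-Hochberg q-values over all tested siRNAs; hits are siRNAs
#' with q at or below the threshold AND a negative interaction estimate
#' (reduced survival specifically under irradiation). The returned table
#' doubles as volcano-plot coordinates: the interaction t-statistic
#' against the FDR.
#'
#' @param tests data.frame from [screen_hit_tests()] (one row per siRNA).
#' @param fdr_threshold FDR threshold for hit calling (default 0.1).
#' @return the input with columns `q`, `is_hit`, `direction`
#'   ("sensitizer", "protector" or "none") added.
#' @export
call_hits <- function(tests, fdr_threshold = 0.1) {
  if (anyDuplicated(tests$sirna)) {
    stop("duplicate siRNA ids: ",
         paste(unique(tests$sirna[duplicated(tests$sirna)]), collapse = ", "))
  }
  tests$q <- stats::p.adjust(tests$p, method = "BH")
  signif <- tests$q <= fdr_threshold
  tests$is_hit <- signif & tests$estimate < 0
  tests$direction <- ifelse(!signif, "none",
                            ifelse(tests$estimate < 0, "sensitizer", "protector"))
  tests
}
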
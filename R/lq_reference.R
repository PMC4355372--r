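#' Published linear-quadratic parameters for four cancer cell lines
#'
#' Reference alpha/beta values (with reported standard errors and R^2)
#' obtained by fitting the linear-quadratic model to 0-8 Gy dose-response
#' data for PC-3 and DU145 prostate cancer, A549 lung adenocarcinoma and
#' U2OS osteosarcoma cells, measured by three readouts: the colony
#' formation assay (cfa), automated cell counting of stained nuclei
#' (cell_count) and the CellTiter-Blue metabolic viability assay (ctb).
#' Used as simulation defaults and as recovery targets for [fit_lq()].
#'
#' @return data.frame: cell_line, assay, alpha, se_alpha, beta, se_beta,
#'   r_squared.
#' @export
lq_reference_params <- function() {
  data.frame(
    cell_line = rep(c("PC-3", "DU145", "A549", "U2OS"), each = 3L),
    assay = rep(c("cfa", "cell_count", "ctb"), times = 4L),
    alpha = c(0.06, 0.07, 0.004,
              0.22, -0.01, -0.22,
              0.12, 0.09, -0.03,
              -0.01, -0.01, -0.01),
    se_alpha = c(0.02, 0.04, 0.02,
                 0.02, 0.04, 0.04,
                 0.02, 0.03, 0.03,
                 0.02, 0.09, 0.06),
    beta = c(0.08, 0.04, 0.03,
             0.05, 0.08, 0.07,
             0.04, 0.04, 0.02,
             0.14, 0.11, 0.02),
    se_beta = c(0.01, 0.01, 0.003,
                0.01, 0.01, 0.09,
                0.01, 0.01, 0.01,
                0.01, 0.04, 0.01),
    r_squared = c(0.99, 0.99, 0.99,
                  0.99, 0.99, 0.97,
                  0.99, 0.99, 0.98,
                  0.99, 0.97, 0.85),
    stringsAsFactors = FALSE
  )
}

#' Published linear-quadratic parameters for radiosensitization experiments
#'
#' Reference alpha/beta values for PC-3 cells under genetic (stable PRKDC
#' knockdown vs empty-vector control, measured by colony formation and by
#' automated cell counting over 0-6 Gy) and pharmacological (2 mM caffeine
#' vs untreated, automated cell counting) radiosensitization. PRKDC
#' silencing and caffeine mainly increase alpha, consistent with impaired
#' DNA double-strand-break repair.
#'
#' @return data.frame: assay, condition, alpha, se_alpha, beta, se_beta.
#' @export
lq_sensitization_params <- function() {
  data.frame(
    assay = c("cfa", "cfa", "cell_count", "cell_count", "cell_count", "cell_count"),
    condition = c("pLKO.1-EV", "pLKO.1-shPRKDC",
                  "pLKO.1-EV", "pLKO.1-shPRKDC",
                  "untreated", "caffeine_2mM"),
    alpha = c(-0.023, 0.158, 0.008, 0.142, 0.135, 0.415),
    se_alpha = c(0.027, 0.058, 0.039, 0.038, 0.035, 0.047),
    beta = c(0.102, 0.142, 0.065, 0.069, 0.014, -0.026),
    se_beta = c(0.001, 0.028, 0.012, 0.013, 0.01, 0.011),
    stringsAsFactors = FALSE
  )
}
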
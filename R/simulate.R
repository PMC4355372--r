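#' Parameters for the synthetic screen generator
#'
#' Defines the study conditions the generator emulates: a genome-wide siRNA
#' screen in 96-well plates, run as duplicate plate sets of which one is
#' irradiated, organised in screens and sessions, read out by automated
#' cell counting. Defaults are the desk-scale analogue of the full design
#' (2 screens x 2 sessions x 10 library plates per set; the full screen
#' used 136 plates per set). Each library plate carries 92 sample siRNAs,
#' 2 non-targeting negative-control wells and 2 PRKDC positive-control
#' wells, replicated into an irradiated and a non-irradiated physical copy.
#'
#' Expected log2 count per well =
#'   log2(seeding * growth)
#'   + treated * (-alpha*D - beta*D^2) * log2(e)
#'   + viability shift(siRNA) + treated * interaction shift(siRNA)
#'   + screen + session + plate offsets,
#' with observed log2 = expected + Normal(0, noise_sd) and counts returned
#' on the linear scale. Plate offsets are drawn once per library plate and
#' shared by its two arm copies, so every technical factor involves both
#' irradiated and non-irradiated observations and is removable without
#' touching the irradiation effect; `plate_arm_sd` adds an optional
#' arm-specific physical-plate component (default 0).
#'
#' @param n_screens number of replicate screens.
#' @param n_sessions sessions per screen; each session covers a distinct
#'   subset of the siRNA library.
#' @param n_plates library plates per set per session.
#' @param seeding cells seeded per well (default 1500).
#' @param growth fold population growth over the assay window in the
#'   absence of treatment (> 0).
#' @param dose IR dose of the treated set, Gy (default 4).
#' @param alpha,beta linear-quadratic parameters of the cell line; defaults
#'   are the PC-3 cell-count-assay values.
#' @param viability_mean,viability_sd log2 per-siRNA viability effect
#'   distribution (both arms).
#' @param sensitizer_frac fraction of siRNAs that are true radiosensitizers.
#' @param sensitizer_shift log2 interaction effect of a true sensitizer
#'   under IR (negative = sensitizing).
#' @param pos_viability,pos_interaction log2 viability and interaction
#'   effects of the PRKDC positive control.
#' @param plate_sd,session_sd,screen_sd technical offset sds, log2 units.
#' @param plate_arm_sd sd of an additional offset specific to each physical
#'   (arm) copy of a plate; not removable by a treatment-preserving
#'   normalization, hence 0 by default.
#' @param noise_sd measurement noise sd on log2 counts.
#' @param count_model "lognormal" (Normal noise on log2 counts) or
#'   "nbinom" (negative-binomial counts with mean 2^expected).
#' @param nb_size negative-binomial size (dispersion) when
#'   `count_model = "nbinom"`.
#' @param seed integer seed; mandatory, every draw is derived from it.
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(n_screens = 2L, n_sessions = 2L, n_plates = 10L,
                       seeding = 1500, growth = 16, dose = 4,
                       alpha = 0.07, beta = 0.04,
                       viability_mean = 0, viability_sd = 0.3,
                       sensitizer_frac = 0.05, sensitizer_shift = -0.8,
                       pos_viability = -0.8, pos_interaction = -0.8,
                       plate_sd = 0.3, session_sd = 0.2, screen_sd = 0.2,
                       plate_arm_sd = 0, noise_sd = 0.2,
                       count_model = c("lognormal", "nbinom"), nb_size = 100,
                       seed = 1L) {
  p <- list(n_screens = as.integer(n_screens), n_sessions = as.integer(n_sessions),
            n_plates = as.integer(n_plates), seeding = seeding, growth = growth,
            dose = dose, alpha = alpha, beta = beta,
            viability_mean = viability_mean, viability_sd = viability_sd,
            sensitizer_frac = sensitizer_frac, sensitizer_shift = sensitizer_shift,
            pos_viability = pos_viability, pos_interaction = pos_interaction,
            plate_sd = plate_sd, session_sd = session_sd, screen_sd = screen_sd,
            plate_arm_sd = plate_arm_sd, noise_sd = noise_sd,
            count_model = match.arg(count_model), nb_size = nb_size,
            seed = as.integer(seed))
  if (is.na(p$seed)) stop("a seed is mandatory for simulation")
  if (p$n_screens < 1L || p$n_sessions < 1L || p$n_plates < 1L) {
    stop("design must have >= 1 screen, session and plate per set")
  }
  if (p$growth <= 0) stop("growth factor must be > 0")
  if (p$dose < 0) stop("dose must be >= 0")
  sds <- c(p$viability_sd, p$plate_sd, p$session_sd, p$screen_sd,
           p$plate_arm_sd, p$noise_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  if (p$sensitizer_frac < 0 || p$sensitizer_frac > 1) {
    stop("sensitizer fraction must be in [0, 1]")
  }
  class(p) <- "sim_params"
  p
}

#' Control well layout of a simulated library plate
#' @keywords internal
.control_layout <- function() {
  list(neg = c("A1", "H12"), pos = c("A12", "H1"))
}

#' Simulate a radiation-susceptibility siRNA screen
#'
#' Generates a plate map, a per-well count table, and the ground truth
#' (per-siRNA viability/interaction shifts and per-factor technical
#' offsets) for the design described in [sim_params()]. The two replicate
#' screens assay the same library plates; within a screen each session's
#' plate set is duplicated into an irradiated ("ir") and a mock ("mock")
#' arm. Identical parameters and seed give bit-identical output.
#'
#' @param params a [sim_params()] object.
#' @return list with elements `map` (annotation columns), `wells` (map plus
#'   `count`), `truth` (list: `sirna`, `technical`), and `params`.
#' @export
simulate_screen <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)

  n_lib <- p$n_sessions * p$n_plates
  lib_plates <- sprintf("P%03d", seq_len(n_lib))
  ctl <- .control_layout()
  sample_wells <- setdiff(well_grid(), c(ctl$neg, ctl$pos))
  n_sample <- length(sample_wells)                    # 92 per plate

  sample_ids <- sprintf("si%05d", seq_len(n_lib * n_sample))
  sirna_ids <- c(sample_ids, "siNT", "siPRKDC")
  is_sens <- c(stats::runif(length(sample_ids)) < p$sensitizer_frac, FALSE, FALSE)
  viability <- c(stats::rnorm(length(sample_ids), p$viability_mean, p$viability_sd),
                 0, p$pos_viability)
  interaction <- c(ifelse(is_sens[seq_along(sample_ids)], p$sensitizer_shift, 0),
                   0, p$pos_interaction)
  sirna_truth <- data.frame(sirna = sirna_ids,
                            role = c(rep("sample", length(sample_ids)),
                                     "neg_control", "pos_control"),
                            viability_shift = viability,
                            interaction_shift = interaction,
                            is_sensitizer = is_sens,
                            stringsAsFactors = FALSE)

  # technical offsets: screen, session-in-screen, library-plate-in-session
  screen_off <- stats::rnorm(p$n_screens, 0, p$screen_sd)
  session_key <- expand.grid(session = seq_len(p$n_sessions),
                             screen = seq_len(p$n_screens))[, c("screen", "session")]
  session_off <- stats::rnorm(nrow(session_key), 0, p$session_sd)
  plate_key <- expand.grid(plate = seq_len(n_lib), screen = seq_len(p$n_screens))
  plate_key$session <- (plate_key$plate - 1L) %/% p$n_plates + 1L
  plate_off <- stats::rnorm(nrow(plate_key), 0, p$plate_sd)
  tech <- rbind(
    data.frame(factor = "screen", screen = seq_len(p$n_screens),
               session = NA_integer_, plate = NA_character_,
               arm = NA_character_, offset = screen_off,
               stringsAsFactors = FALSE),
    data.frame(factor = "session", screen = session_key$screen,
               session = session_key$session, plate = NA_character_,
               arm = NA_character_, offset = session_off,
               stringsAsFactors = FALSE),
    data.frame(factor = "plate", screen = plate_key$screen,
               session = plate_key$session, plate = lib_plates[plate_key$plate],
               arm = NA_character_, offset = plate_off,
               stringsAsFactors = FALSE)
  )

  # one plate-map block per library plate; siRNA assignment fixed by plate
  plate_sirna <- function(ip) {
    w <- c(sample_wells, ctl$neg, ctl$pos)
    s <- c(sample_ids[((ip - 1L) * n_sample + 1L):(ip * n_sample)],
           "siNT", "siNT", "siPRKDC", "siPRKDC")
    r <- c(rep("sample", n_sample), rep("neg_control", 2L), rep("pos_control", 2L))
    data.frame(well = w, sirna = s, role = r, stringsAsFactors = FALSE)
  }
  blocks <- lapply(seq_len(n_lib), plate_sirna)

  arms <- c("ir", "mock")
  rows <- vector("list", p$n_screens * n_lib * 2L)
  k <- 0L
  for (sc in seq_len(p$n_screens)) {
    for (ip in seq_len(n_lib)) {
      ss <- (ip - 1L) %/% p$n_plates + 1L
      for (a in arms) {
        k <- k + 1L
        b <- blocks[[ip]]
        rows[[k]] <- data.frame(
          screen = sc, session = ss, plate = lib_plates[ip],
          arm = a, well = b$well, sirna = b$sirna, role = b$role,
          dose = if (a == "ir") p$dose else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  map <- do.call(rbind, rows)
  map <- map[, c("screen", "session", "plate", "well", "sirna", "role",
                 "dose", "arm")]

  # arm-specific physical-plate offsets (default sd 0)
  phys_key <- unique(map[, c("screen", "session", "plate", "arm")])
  phys_off <- stats::rnorm(nrow(phys_key), 0, p$plate_arm_sd)
  names(phys_off) <- paste(phys_key$screen, phys_key$session, phys_key$plate,
                           phys_key$arm, sep = "\r")
  if (p$plate_arm_sd > 0) {
    tech <- rbind(tech, data.frame(factor = "plate_arm", screen = phys_key$screen,
                                   session = phys_key$session, plate = phys_key$plate,
                                   arm = phys_key$arm, offset = phys_off,
                                   stringsAsFactors = FALSE))
  }

  treated <- map$arm == "ir"
  idx_sirna <- match(map$sirna, sirna_truth$sirna)
  idx_session <- match(paste(map$screen, map$session),
                       paste(session_key$screen, session_key$session))
  idx_plate <- match(paste(map$screen, lib_plates[match(map$plate, lib_plates)]),
                     paste(plate_key$screen, lib_plates[plate_key$plate]))
  lq_log2 <- (-p$alpha * map$dose - p$beta * map$dose^2) * log2(exp(1))
  expected <- log2(p$seeding * p$growth) +
    ifelse(treated, lq_log2, 0) +
    sirna_truth$viability_shift[idx_sirna] +
    ifelse(treated, sirna_truth$interaction_shift[idx_sirna], 0) +
    screen_off[map$screen] + session_off[idx_session] + plate_off[idx_plate] +
    phys_off[paste(map$screen, map$session, map$plate, map$arm, sep = "\r")]

  wells <- map
  if (p$count_model == "lognormal") {
    obs <- expected + stats::rnorm(nrow(map), 0, p$noise_sd)
    wells$count <- pmax(0, 2^obs)
  } else {
    wells$count <- stats::rnbinom(nrow(map), mu = 2^expected, size = p$nb_size)
  }
  wells$expected_log2 <- expected
  rownames(map) <- rownames(wells) <- NULL
  validate_plate_map(map, require_controls = TRUE)

  list(map = map, wells = wells,
       truth = list(sirna = sirna_truth, technical = tech),
       params = p)
}

#' Simulate the scan-object list of one well
#'
#' Emulates the object-level output of a laser scanning cytometer for a
#' well holding `true_count` nuclei. Nuclei join merged cluster objects of
#' exactly 3 with probability `cluster_prob` (a remainder of 1 or 2 stays
#' single), making the counting rule exactly invertible. A fraction
#' `polyploid_frac` of the single nuclei are enlarged polyploid nuclei with
#' elevated intensity; their size places them in the cluster class, so each
#' one inflates the downstream count by 2 - the documented overcount at
#' high dose.
#'
#' @param true_count true number of nuclei in the well (>= 0).
#' @param cluster_prob probability that a nucleus is part of a 3-nucleus
#'   merged object.
#' @param polyploid_frac fraction of single nuclei that are polyploid.
#' @param seed optional integer seed.
#' @param well well label for the emitted objects.
#' @return data.frame of objects (well, width_um, depth_um, intensity) with
#'   attribute `truth`: list(true_count, n_single, n_cluster_objects,
#'   n_polyploid).
#' @export
simulate_object_list <- function(true_count, cluster_prob = 0,
                                 polyploid_frac = 0, seed = NULL,
                                 well = "A1") {
  if (true_count < 0) stop("true_count must be >= 0")
  if (cluster_prob < 0 || cluster_prob > 1 || polyploid_frac < 0 || polyploid_frac > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(well = character(), width_um = numeric(),
                      depth_um = numeric(), intensity = numeric(),
                      stringsAsFactors = FALSE)
  if (true_count == 0) {
    attr(empty, "truth") <- list(true_count = 0L, n_single = 0L,
                                 n_cluster_objects = 0L, n_polyploid = 0L)
    return(empty)
  }
  n_in_clusters <- stats::rbinom(1L, true_count, cluster_prob)
  n_cluster <- n_in_clusters %/% 3L
  n_single <- true_count - 3L * n_cluster
  n_poly <- if (n_single > 0) stats::rbinom(1L, n_single, polyploid_frac) else 0L
  n_plain <- n_single - n_poly

  rdim <- function(n, lo, hi) stats::runif(n, lo, hi)
  singles <- if (n_plain > 0) {
    data.frame(well = well,
               width_um = rdim(n_plain, 8, 25), depth_um = rdim(n_plain, 8, 25),
               intensity = stats::rlnorm(n_plain, log(100), 0.2),
               stringsAsFactors = FALSE)
  } else empty
  polys <- if (n_poly > 0) {
    data.frame(well = well,
               width_um = rdim(n_poly, 52, 80), depth_um = rdim(n_poly, 30, 80),
               intensity = stats::rlnorm(n_poly, log(250), 0.2),
               stringsAsFactors = FALSE)
  } else empty
  clusters <- if (n_cluster > 0) {
    data.frame(well = well,
               width_um = rdim(n_cluster, 55, 160), depth_um = rdim(n_cluster, 30, 160),
               intensity = stats::rlnorm(n_cluster, log(300), 0.2),
               stringsAsFactors = FALSE)
  } else empty
  out <- rbind(singles, polys, clusters)
  if (nrow(out) > 1L) out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- list(true_count = as.integer(true_count),
                             n_single = as.integer(n_single),
                             n_cluster_objects = as.integer(n_cluster),
                             n_polyploid = as.integer(n_poly))
  out
}
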
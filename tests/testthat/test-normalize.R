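sim_with_offsets <- function(seed = 21) {
  simulate_screen(sim_params(plate_sd = 0.3, session_sd = 0.2, screen_sd = 0.2,
                             noise_sd = 0.1, seed = seed))
}

# independent oracle: sequential subtraction of screen, session, then plate
# means, each computed separately per treatment arm and averaged
oracle_normalize <- function(wells) {
  treated <- wells$arm == "ir"
  y <- wells$log2
  arm_mean_of <- function(v, key) {
    m <- tapply(v, list(key, treated), mean)
    rowMeans(m)[key] - mean(rowMeans(m))
  }
  scr <- arm_mean_of(y, as.character(wells$screen))
  y <- y - scr
  ses <- arm_mean_of(y, paste(wells$screen, wells$session))
  y <- y - ses
  plt <- arm_mean_of(y, paste(wells$screen, wells$session, wells$plate))
  y - plt
}

test_that("normalization is a no-op when there is nothing to remove", {
  sim <- simulate_screen(sim_params(plate_sd = 0, session_sd = 0, screen_sd = 0,
                                    noise_sd = 0, viability_sd = 0,
                                    sensitizer_frac = 0, pos_viability = 0,
                                    pos_interaction = 0, seed = 3))
  norm <- normalize_screen(sim$wells)
  delta <- norm$wells$normalized - norm$wells$log2
  expect_lt(max(abs(delta - mean(delta))), 1e-10)
  expect_lt(max(abs(delta)), 1e-10)
})

test_that("recovered technical offsets match truth and the two-pass oracle", {
  sim <- sim_with_offsets()
  norm <- normalize_screen(sim$wells)

  oracle <- oracle_normalize(norm$wells)
  expect_lt(max(abs(norm$wells$normalized - oracle)), 1e-8)

  truth <- sim$truth$technical
  eff <- norm$effects
  scr_true <- truth$offset[truth$factor == "screen"]
  expect_lt(sqrt(mean((eff$screen$offset - (scr_true - mean(scr_true)))^2)), 0.1)

  plt <- merge(eff$plate, truth[truth$factor == "plate", ],
               by = c("screen", "session", "plate"))
  expect_gt(cor(plt$offset.x, plt$offset.y), 0.95)
  # noise-limited: each plate effect is estimated from 192 wells
  expect_lt(sqrt(mean((plt$offset.x - (plt$offset.y - ave(plt$offset.y, plt$screen, plt$session)))^2)),
            3 * 0.1 / sqrt(192) + 0.05)

  # identifiability: offsets sum to zero within each parent factor
  expect_lt(abs(sum(eff$screen$offset)), 1e-8)
  expect_true(all(abs(tapply(eff$session$offset, eff$session$screen, sum)) < 1e-8))
  expect_true(all(abs(tapply(eff$plate$offset,
                             paste(eff$plate$screen, eff$plate$session), sum)) < 1e-8))
})

test_that("per-factor constants are absorbed and the treatment effect preserved", {
  sim <- sim_with_offsets(seed = 22)
  norm0 <- normalize_screen(sim$wells)

  # add constants per library plate, session and screen to the log2 values
  w <- norm0$wells
  w$log2 <- w$log2 +
    as.numeric(factor(w$plate)) * 0.37 +
    as.numeric(factor(paste(w$screen, w$session))) * 1.1 +
    as.numeric(w$screen) * -0.6
  norm1 <- normalize_screen(w)
  delta <- norm1$wells$normalized - norm0$wells$normalized
  expect_lt(max(abs(delta - mean(delta))), 1e-9)

  qc0 <- qc_normalization(norm0)
  qc1 <- qc_normalization(norm1)
  expect_equal(qc1$treatment_after, qc0$treatment_after, tolerance = 1e-10)
  expect_equal(qc0$treatment_before, qc0$treatment_after, tolerance = 1e-10)
  expect_true(all(qc0$variance$r2_after < qc0$variance$r2_before))
})

test_that("sessions missing a treatment arm are reported by name", {
  sim <- simulate_screen(sim_params(seed = 2))
  w <- sim$wells[!(sim$wells$session == 2 & sim$wells$arm == "mock"), ]
  expect_error(normalize_screen(w), "session 2")
})

test_that("robust normalization resists a few corrupted wells", {
  sim <- sim_with_offsets(seed = 23)
  clean <- normalize_screen(sim$wells, method = "robust")

  # corrupt 1% of wells by +/-5 log2
  w <- sim$wells
  n_bad <- floor(0.01 * nrow(w))
  set.seed(9)
  bad <- sample.int(nrow(w), n_bad)
  w$count[bad] <- w$count[bad] * 2^(ifelse(seq_along(bad) %% 2 == 0, 5, -5))
  dirty_robust <- normalize_screen(w, method = "robust")
  dirty_ols <- normalize_screen(w, method = "ols")

  shift <- function(a, b) max(abs(a$effects$plate$offset - b$effects$plate$offset))
  expect_lt(shift(dirty_robust, clean), shift(dirty_ols, clean))
  expect_lt(shift(dirty_robust, clean), 0.05)
})

test_that("zero counts survive the pseudocount transform", {
  sim <- simulate_screen(sim_params(seed = 4))
  w <- sim$wells
  w$count[1:5] <- 0
  norm <- normalize_screen(w)
  expect_true(all(is.finite(norm$wells$normalized)))
})
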
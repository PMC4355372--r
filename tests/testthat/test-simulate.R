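test_that("the simulated design replicates the duplicate-set screen layout", {
  sim <- simulate_screen(sim_params(seed = 1))
  p <- sim$params
  expect_equal(nrow(sim$map), p$n_screens * p$n_sessions * p$n_plates * 2L * 96L)
  expect_setequal(unique(sim$map$arm), c("ir", "mock"))
  expect_true(all(sim$map$dose[sim$map$arm == "ir"] == p$dose))
  expect_true(all(sim$map$dose[sim$map$arm == "mock"] == 0))

  # every physical plate carries 2 neg and 2 pos control wells
  pkey <- paste(sim$map$screen, sim$map$session, sim$map$plate, sim$map$arm)
  expect_true(all(tapply(sim$map$role == "neg_control", pkey, sum) == 2L))
  expect_true(all(tapply(sim$map$role == "pos_control", pkey, sum) == 2L))

  # sessions partition the library; screens replicate it
  by_sess <- tapply(sim$map$sirna[sim$map$role == "sample"],
                    sim$map$session[sim$map$role == "sample"], unique)
  expect_length(intersect(by_sess[[1]], by_sess[[2]]), 0L)
  scr <- split(sim$map$sirna, sim$map$screen)
  expect_setequal(unique(scr[[1]]), unique(scr[[2]]))

  # ground truth: non-sensitizer sample siRNAs have interaction exactly 0
  tr <- sim$truth$sirna[sim$truth$sirna$role == "sample", ]
  expect_true(all(tr$interaction_shift[!tr$is_sensitizer] == 0))
  expect_true(all(tr$interaction_shift[tr$is_sensitizer] == p$sensitizer_shift))
})

test_that("simulation is bit-identical under a fixed seed", {
  s1 <- simulate_screen(sim_params(seed = 99))
  s2 <- simulate_screen(sim_params(seed = 99))
  expect_identical(s1$wells, s2$wells)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_screen(sim_params(seed = 100))
  expect_false(identical(s1$wells$count, s3$wells$count))
})

test_that("with all effects and noise at zero the screen is flat", {
  sim <- simulate_screen(quiet_params(dose = 0, seed = 5))
  expect_equal(sim$wells$count,
               rep(sim$params$seeding * sim$params$growth, nrow(sim$wells)),
               tolerance = 1e-12)
})

test_that("LQ killing scales treated counts by the closed-form survival", {
  sim <- simulate_screen(quiet_params(alpha = 0.22, beta = 0.05, dose = 2, seed = 6))
  w <- sim$wells
  key <- paste(w$screen, w$session, w$plate, w$well)
  ratio <- w$count[w$arm == "ir"][order(key[w$arm == "ir"])] /
    w$count[w$arm == "mock"][order(key[w$arm == "mock"])]
  # exp(-(0.22*2 + 0.05*4)) = exp(-0.64)
  expect_equal(ratio, rep(exp(-0.64), length(ratio)), tolerance = 1e-12)
})

test_that("mean log2 count converges to the stated expectation under noise", {
  p <- quiet_params(noise_sd = 0.25, seed = 1)
  draws <- vapply(1:40, function(s) {
    sim <- simulate_screen(quiet_params(noise_sd = 0.25, seed = s))
    mean(log2(sim$wells$count))
  }, 0)
  expected <- log2(p$seeding * p$growth) +
    mean(c(0, (-p$alpha * p$dose - p$beta * p$dose^2) * log2(exp(1))))
  n_wells <- 40 * 384
  mc_se <- 0.25 / sqrt(n_wells)
  expect_lt(abs(mean(draws) - expected), 4 * mc_se)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(growth = 0), "growth")
  expect_error(sim_params(sensitizer_frac = 1.5), "\\[0, 1\\]")
  expect_error(sim_params(noise_sd = -1), ">= 0")
  expect_error(sim_params(n_plates = 0), ">= 1")
  expect_error(simulate_object_list(-1), ">= 0")
  expect_error(simulate_object_list(10, cluster_prob = 2), "\\[0, 1\\]")
})

test_that("object-list simulation hits its documented limits", {
  expect_equal(nrow(simulate_object_list(0)), 0L)
  objs <- simulate_object_list(100, cluster_prob = 0, polyploid_frac = 0, seed = 2)
  expect_equal(nrow(objs), 100L)
  expect_true(all(classify_objects(objs$width_um, objs$depth_um) == "single"))
})
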
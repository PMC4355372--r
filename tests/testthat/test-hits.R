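test_that("constructed interactions are estimated exactly", {
  ctrl_ir <- c(1, 2, 3, 4)
  ctrl_mock <- c(2, 3, 4, 5)
  # shift only in the IR arm -> pure interaction of exactly delta
  delta <- -0.8
  res <- test_sirna(sirna_ir = mean(ctrl_ir) + delta + c(0, 0),
                    sirna_mock = mean(ctrl_mock) + c(0, 0),
                    control_ir = ctrl_ir, control_mock = ctrl_mock)
  expect_equal(res$estimate, delta)
  expect_lt(res$p, 1)

  # same shift in both arms -> viability main effect, zero interaction
  res0 <- test_sirna(sirna_ir = mean(ctrl_ir) + delta + c(0, 0),
                     sirna_mock = mean(ctrl_mock) + delta + c(0, 0),
                     control_ir = ctrl_ir, control_mock = ctrl_mock)
  expect_equal(res0$estimate, 0)
})

test_that("the closed-form interaction test equals the lm oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:6, 4, replace = TRUE)
    vals <- lapply(n, function(k) rnorm(k))
    res <- test_sirna(vals[[1]], vals[[2]], vals[[3]], vals[[4]])
    df <- data.frame(
      value = unlist(vals),
      treated = rep(c(1, 0, 1, 0), n),
      grp = rep(c(1, 1, 0, 0), n))
    fit <- summary(lm(value ~ treated * grp, data = df))$coefficients
    expect_equal(res$estimate, fit["treated:grp", "Estimate"], tolerance = 1e-10)
    expect_equal(res$t, fit["treated:grp", "t value"], tolerance = 1e-10)
    expect_equal(res$p, fit["treated:grp", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("input validation of the interaction test", {
  expect_error(test_sirna(numeric(), 1, rnorm(3), rnorm(3)), ">= 1 siRNA well")
  expect_error(test_sirna(1, 1, 1, rnorm(3)), ">= 2 control wells")
})

test_that("null p-values are uniform and type-I error is nominal", {
  set.seed(41)
  p <- replicate(500, {
    test_sirna(rnorm(2, 0, 0.2), rnorm(2, 0, 0.2),
               rnorm(80, 0, 0.2), rnorm(80, 0, 0.2))$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
})

test_that("Benjamini-Hochberg q-values match the hand-computed step-up", {
  tests <- data.frame(sirna = c("a", "b", "c"), estimate = c(-1, -1, 1),
                      t = c(-5, -3, 1), p = c(0.001, 0.02, 0.9))
  hits <- call_hits(tests, fdr_threshold = 0.1)
  expect_equal(hits$q, c(0.003, 0.03, 0.9))
  expect_equal(hits$is_hit, c(TRUE, TRUE, FALSE))
  expect_equal(hits$direction, c("sensitizer", "sensitizer", "none"))
})

test_that("hit calling is order invariant, monotone, and rejects duplicates", {
  set.seed(51)
  tests <- data.frame(sirna = paste0("si", 1:50),
                      estimate = rnorm(50), t = rnorm(50),
                      p = runif(50))
  h1 <- call_hits(tests)
  shuffle <- sample.int(50)
  h2 <- call_hits(tests[shuffle, ])
  expect_equal(h2$q, h1$q[shuffle])
  ord <- order(tests$p)
  expect_true(all(diff(h1$q[ord]) >= 0))

  expect_equal(sum(call_hits(transform(tests, p = 1))$is_hit), 0L)
  expect_error(call_hits(rbind(tests, tests[1, ])), "duplicate")
})

test_that("screen-level tests agree with per-siRNA lm fits", {
  sim <- simulate_screen(sim_params(n_plates = 2, seed = 61))
  norm <- normalize_screen(sim$wells)
  tests <- screen_hit_tests(norm$wells)

  w <- norm$wells
  ctrl <- w[w$role == "neg_control", ]
  for (id in sample(tests$sirna, 5)) {
    sw <- w[w$sirna == id, ]
    res <- test_sirna(sw$normalized[sw$arm == "ir"], sw$normalized[sw$arm == "mock"],
                      ctrl$normalized[ctrl$arm == "ir"],
                      ctrl$normalized[ctrl$arm == "mock"])
    row <- tests[tests$sirna == id, ]
    expect_equal(row$estimate, res$estimate, tolerance = 1e-10)
    expect_equal(row$t, res$t, tolerance = 1e-10)
  }
})
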
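test_that("system generation is deterministic and validates sizes", {
  a <- generate_system(10, 20, 10, 8, 0.2, seed = 5)
  b <- generate_system(10, 20, 10, 8, 0.2, seed = 5)
  expect_identical(a, b)
  expect_error(generate_system(n_genes = 5, n_proteins = 10), "n_genes >=")
  expect_error(generate_system(sparsity = 1.2), "sparsity")
})

test_that("per-target predictor counts follow the sparsity (binomial, 3 sigma)", {
  sys <- generate_system(n_features = 12, n_genes = 100, n_proteins = 60,
                         n_metabolites = 10, sparsity = 0.1, seed = 9)
  counts <- lengths(lapply(sys$protein_coefs, `[[`, "support"))
  expected <- 100 * 0.1
  tol <- 3 * sqrt(100 * 0.1 * 0.9) / sqrt(60)   # 3 sigma on the mean
  expect_lt(abs(mean(counts) - expected), tol + 1)  # +1 for the >=1 floor
  # supports live inside the declared network neighbourhoods
  for (p in sample(sys$proteins, 10)) {
    nb <- unique(c(sub("^P_", "",
                       network_neighbors(sys$ppi, p)),
                   sys$protein_coefs[[p]]$support))
    expect_true(all(sys$protein_coefs[[p]]$support %in% nb))
  }
})

test_that("regulatory graph contains feedback cycles of length <= 2", {
  sys <- generate_system(seed = 3)
  e <- sys$trn$edges
  self <- any(e$from == e$to)
  pair <- any(paste(e$from, e$to) %in% paste(e$to, e$from)[e$from != e$to])
  expect_true(self && pair)
})

test_that("noiseless replicates are identical and follow the true maps", {
  sys <- generate_system(seed = 7)
  comp <- simulate_compendium(sys, n_conditions = 5, n_replicates = 3,
                              noise_sd = 0, seed = 2, include_fluxes = FALSE)
  tr <- comp$layers$transcript
  expect_equal(tr[, 1], tr[, 2], ignore_attr = TRUE)
  expect_equal(tr[, 1], tr[, 3], ignore_attr = TRUE)

  # protein layer equals the ground-truth linear map exactly at zero noise
  truth <- attr(comp, "truth")
  for (p in sys$proteins) {
    pc <- sys$protein_coefs[[p]]
    expected <- pc$intercept +
      truth$S_rep[, pc$support, drop = FALSE] %*% pc$coef
    expect_equal(unname(log(comp$layers$protein[p, ])),
                 unname(drop(expected)), tolerance = 1e-12)
  }
})

test_that("replicate CV matches the noise level within sampling error", {
  sys <- generate_system(seed = 7)
  noise_sd <- 0.1
  comp <- simulate_compendium(sys, n_conditions = 30, n_replicates = 6,
                              noise_sd = noise_sd, seed = 4,
                              include_fluxes = FALSE)
  tr <- log(comp$layers$transcript)
  cond <- condition_key(comp$conditions)
  # log-abs sd per gene within replicate groups should be noise_sd * range
  rng <- sys$rnn_true$scaler$log_max - sys$rnn_true$scaler$log_min
  scale_fac <- (0.95 - 0.05)
  ratios <- c()
  for (k in unique(cond)) {
    cols <- which(cond == k)
    sds <- apply(tr[, cols, drop = FALSE], 1, sd)
    ratios <- c(ratios, sds / (noise_sd * rng / scale_fac))
  }
  expect_lt(abs(mean(ratios) - 1), 0.2)
})

test_that("identity distortion with zero noise returns the log truth", {
  truth <- exp(rand_matrix(30, 6, mean = 5, sd = 0.5, seed = 2))
  specs <- list(pl = list(profiles = colnames(truth), a = 0, b = 1,
                          warp_amp = 0, warp_freq = 1, noise_mean = 0,
                          noise_sd = 1, noise_floor = -Inf,
                          noise_rows = character(0)))
  raw <- distort_to_raw(truth, specs, missing_rate = 0, seed = 1)
  expect_equal(raw$pl, log(truth), tolerance = 1e-12)
})

test_that("masking rate is binomial and noise rows sit below the signal", {
  truth <- exp(rand_matrix(100, 10, mean = 6, sd = 0.5, seed = 3))
  specs <- list(pl = list(profiles = colnames(truth), a = 0, b = 1,
                          warp_amp = 0, warp_freq = 1, noise_mean = 0,
                          noise_sd = 0.5, noise_floor = -Inf,
                          noise_rows = rownames(truth)[1:10]))
  raw <- distort_to_raw(truth, specs, missing_rate = 0.3, seed = 5)
  n_missing <- sum(is.na(raw$pl))
  expect_lt(abs(n_missing - 0.3 * 1000), 3 * sqrt(1000 * 0.3 * 0.7))
  expect_lt(mean(raw$pl[1:10, ], na.rm = TRUE),
            mean(raw$pl[-(1:10), ], na.rm = TRUE))
  expect_error(distort_to_raw(truth, specs, missing_rate = 1.2), "missing_rate")
  # non-monotone warp is rejected
  bad <- specs; bad$pl$warp_amp <- 2; bad$pl$warp_freq <- 1
  expect_error(distort_to_raw(truth, bad, 0, 1), "monotone")
})

test_that("growth curves approach carrying capacity and validate parameters", {
  cv <- simulate_growth_curve(mu = 0.7, lag = 1, K = 1.2, od0 = 0.05,
                              horizon_h = 40, noise_sd = 0)
  expect_equal(tail(cv$od, 1), 1.2, tolerance = 1e-6)
  expect_true(all(diff(cv$od) >= 0))
  expect_error(simulate_growth_curve(mu = -1, K = 1, od0 = 0.05), "mu > 0")
  expect_error(simulate_growth_curve(mu = 1, K = 0.01, od0 = 0.05), "K > od0")
  # two seeds with noise differ, same trend after smoothing
  c1 <- simulate_growth_curve(0.7, 1, 1.2, 0.05, horizon_h = 12,
                              noise_sd = 0.01, seed = 1)
  c2 <- simulate_growth_curve(0.7, 1, 1.2, 0.05, horizon_h = 12,
                              noise_sd = 0.01, seed = 2)
  expect_false(identical(c1$od, c2$od))
  expect_gt(cor(stats::runmed(c1$od, 9), stats::runmed(c2$od, 9)), 0.99)
})

test_that("early log-slope of a noiseless delayed-logistic equals mu", {
  cv <- simulate_growth_curve(mu = 0.7, lag = 1, K = 100, od0 = 0.05,
                              dt_minutes = 5, horizon_h = 4, noise_sd = 0)
  win <- cv$time > 1.1 & cv$time < 2.1
  slope <- coef(lm(log(cv$od[win]) ~ cv$time[win]))[2]
  expect_equal(unname(slope), 0.7, tolerance = 1e-3)
})
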
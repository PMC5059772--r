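test_that("EM noise model recovers well-separated components", {
  set.seed(8)
  G <- 300; N <- 8
  mat <- matrix(rnorm(G * N, 9, 1), G, N,
                dimnames = list(sprintf("g%03d", 1:G), sprintf("p%d", 1:N)))
  mat[1:30, ] <- rnorm(30 * N, 3, 1)     # noise floor, 6 sd below signal
  res <- remove_noise(mat, rownames(mat)[1:30])
  expect_lt(abs(res$model$mu_noise - 3) / 3, 0.05)
  expect_lt(abs(res$model$mu_signal - 9) / 9, 0.05)
  # noise-reference rows are flagged almost entirely
  expect_gte(mean(res$flagged[1:30, ]), 0.95)
  # flagged entries are floored at the fitted noise mean
  expect_true(all(res$values[res$flagged] == res$model$mu_noise))
  expect_true(all(res$posterior_noise >= 0 & res$posterior_noise <= 1))
})

test_that("a matrix far above the noise floor has nothing flagged", {
  set.seed(9)
  mat <- matrix(rnorm(100 * 6, 12, 0.5), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), sprintf("p%d", 1:6)))
  mat[1:10, ] <- rnorm(60, 2, 0.5)
  res <- remove_noise(mat, rownames(mat)[1:10])
  expect_equal(sum(res$flagged[-(1:10), ]), 0)
})

test_that("degenerate single-component data is an error, not a fit", {
  set.seed(10)
  mat <- matrix(rnorm(600, 5, 1), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), sprintf("p%d", 1:6)))
  expect_error(remove_noise(mat, "g001"), "degenerate|separated")
})

test_that("quantile normalization maps permuted profiles to equality", {
  v <- sort(rnorm(50))
  mat <- cbind(p1 = v, p2 = sample(v), p3 = sample(v))
  rownames(mat) <- sprintf("g%02d", 1:50)
  out <- correct_platform_bias(list(pl = mat), zscore = "per_profile")$pl
  expect_equal(unname(sort(out[, 1])), unname(sort(out[, 2])),
               tolerance = 1e-8)
  expect_equal(unname(sort(out[, 1])), unname(sort(out[, 3])),
               tolerance = 1e-8)
})

test_that("per-gene z-scoring yields exact per-gene moments", {
  mat <- rand_matrix(40, 12, seed = 21)
  out <- correct_platform_bias(list(pl = mat), zscore = "per_gene")$pl
  expect_lt(max(abs(rowMeans(out))), 1e-9)
  expect_lt(max(abs(apply(out, 1, sd) - 1)), 1e-9)
})

test_that("bias correction improves cross-platform agreement with truth", {
  set.seed(31)
  G <- 120
  truth <- exp(matrix(runif(G, log(50), log(5000)), G, 12) +
                 rnorm(G * 12, 0, 0.15))
  dimnames(truth) <- list(sprintf("g%03d", 1:G), sprintf("p%02d", 1:12))
  specs <- list(
    A = list(profiles = colnames(truth)[1:6], a = 2, b = 0.6, warp_amp = 0,
             warp_freq = 1, noise_mean = 0, noise_sd = 1,
             noise_floor = -Inf, noise_rows = character(0)),
    B = list(profiles = colnames(truth)[7:12], a = -1, b = 1.4, warp_amp = 0,
             warp_freq = 1, noise_mean = 0, noise_sd = 1,
             noise_floor = -Inf, noise_rows = character(0)))
  raw <- distort_to_raw(truth, specs, 0, seed = 2)
  corrected <- correct_platform_bias(raw)
  # per-gene correlation with truth across profiles POOLED over platforms:
  # platform-specific affine maps destroy it, correction restores it
  agree <- function(lst) {
    m <- do.call(cbind, unname(lst))
    mean(vapply(seq_len(nrow(m)),
                function(g) cor(m[g, ], log(truth[g, colnames(m)])),
                numeric(1)))
  }
  expect_gt(agree(corrected), agree(raw))
  # cross-platform scale mismatch shrinks after correction
  expect_lt(abs(mean(corrected$A) - mean(corrected$B)),
            abs(mean(raw$A) - mean(raw$B)))
})

test_that("absolute quantification is self-consistent on shared genes", {
  set.seed(12)
  ref <- exp(runif(60, log(100), log(10000)))
  names(ref) <- sprintf("g%03d", 1:60)
  mat <- matrix(log(ref), 60, 3,
                dimnames = list(names(ref), c("p1", "p2", "p3")))
  out <- quantify_absolute(mat, ref, min_shared = 20)
  rel_err <- abs(out - ref) / ref
  expect_lt(median(rel_err), 0.02)
  expect_true(all(out > 0))
})

test_that("absolute quantification preserves within-profile ranks", {
  set.seed(13)
  ref <- exp(runif(40, log(10), log(1e4)))
  names(ref) <- sprintf("g%03d", 1:40)
  rel <- matrix(0.3 * log(ref) + 0.05 * sin(log(ref)) + 1, 40, 2,
                dimnames = list(names(ref), c("p1", "p2")))
  out <- quantify_absolute(rel, ref, min_shared = 20)
  for (j in 1:2)
    expect_equal(cor(rank(out[, j]), rank(rel[, j])), 1, tolerance = 1e-12)
})

test_that("too few shared genes is an error suggesting a fallback", {
  mat <- rand_matrix(30, 2, seed = 14)
  ref <- setNames(exp(rnorm(5, 6)), rownames(mat)[1:5])
  expect_error(quantify_absolute(mat, ref), "fallback|shares only")
})

test_that("missingness filter is strict at the 70% threshold", {
  m <- rand_matrix(3, 10, seed = 15)
  m[1, 1:8] <- NA   # 80% missing -> removed
  m[2, 1:7] <- NA   # exactly 70% -> retained
  out <- filter_and_impute(m, k = 1)
  expect_false("g001" %in% rownames(out))
  expect_true("g002" %in% rownames(out))
  # complete matrices pass through unchanged
  m2 <- rand_matrix(5, 4, seed = 16)
  expect_identical(filter_and_impute(m2), m2)
})

test_that("kNN imputation equals the brute-force oracle", {
  # hand-checkable case: one missing cell, known nearest genes
  m <- matrix(c(1, 2, 3, NA,
                1, 2, 3, 4,
                1.1, 2.1, 3.1, 5,
                5, 6, 7, 8,
                0.9, 1.9, 2.9, 6), 5, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("p", 1:4)))
  out <- filter_and_impute(m, k = 3)
  expect_equal(out["g1", "p4"], mean(c(4, 5, 6)))   # 3 nearest by distance

  # randomized matrices against the exhaustive oracle
  for (s in 1:4) {
    mm <- rand_matrix(15, 8, seed = 100 + s)
    mm[sample(length(mm), 12)] <- NA
    keep <- rowMeans(is.na(mm)) <= 0.7
    expect_equal(filter_and_impute(mm, k = 3),
                 impute_oracle(mm[keep, , drop = FALSE], k = 3))
  }
})

test_that("metabolite conversion applies the 1e6 molecules-per-mM constant", {
  expect_equal(unname(normalize_metabolome(c(m1 = 1))), 1e6)
  expect_equal(unname(normalize_metabolome(c(m1 = 0))), 0)
  expect_equal(unname(normalize_metabolome(c(m1 = 2.5))), 2.5e6)
  expect_error(normalize_metabolome(c(m1 = -1)), "negative")
})

test_that("a direct absolute reference overrides the constant via loess", {
  set.seed(17)
  conc <- sort(runif(30, 0.1, 5))
  names(conc) <- sprintf("m%02d", 1:30)
  truth <- 2e6 * conc            # cells twice the nominal volume factor
  out <- normalize_metabolome(matrix(conc, ncol = 1,
                                     dimnames = list(names(conc), "p1")),
                              reference = truth)
  expect_lt(median(abs(out[, 1] - truth) / truth), 0.05)
})

test_that("flux normalization divides by glucose uptake and inverts", {
  v <- c(glc = 10, r2 = 5)
  expect_equal(normalize_fluxome(v, "glc"), c(glc = 1, r2 = 0.5))
  expect_equal(normalize_fluxome(c(glc = 4, a = 0, b = 0), "glc"),
               c(glc = 1, a = 0, b = 0))
  set.seed(18)
  w <- setNames(runif(10, 0.5, 9), c("glc", paste0("r", 1:9)))
  expect_equal(normalize_fluxome(w, "glc") * w[["glc"]], w)
  expect_error(normalize_fluxome(c(glc = 0, r2 = 1), "glc"), "glucose")
})

test_that("platform correction is idempotent on rank-equivalent profiles", {
  set.seed(19)
  v <- rnorm(40)
  mat <- cbind(p1 = v, p2 = sample(v), p3 = sample(v))
  rownames(mat) <- sprintf("g%02d", 1:40)
  once <- correct_platform_bias(list(pl = mat), zscore = "per_profile")$pl
  twice <- correct_platform_bias(list(pl = once), zscore = "per_profile")$pl
  expect_equal(once, twice, tolerance = 1e-6)
})
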
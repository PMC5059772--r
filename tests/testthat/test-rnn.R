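make_scaler <- function(genes, lmin = 4, lmax = 8) {
  structure(list(log_min = setNames(rep(lmin, length(genes)), genes),
                 log_max = setNames(rep(lmax, length(genes)), genes),
                 lo = 0.05, hi = 0.95, genes = genes),
            class = "expression_scaler")
}

test_that("the scaler is invertible on and beyond the training range", {
  set.seed(1)
  m <- exp(rand_matrix(10, 6, mean = 6, sd = 1, seed = 1))
  sc <- fit_expression_scaler(m)
  s <- scale_expression(sc, m)
  expect_true(all(s >= 0.05 - 1e-12 & s <= 0.95 + 1e-12))
  expect_equal(unscale_expression(sc, s), m, tolerance = 1e-10)
})

test_that("zero weights give the sigmoid midpoint at any depth", {
  genes <- paste0("g", 1:4)
  mod <- rnn_model(matrix(0, 3, 4, dimnames = list(NULL, genes)),
                   matrix(0, 4, 4), rep(0, 4), n = 2,
                   scaler = make_scaler(genes))
  out <- rnn_forward(mod, c(1, 0, 1), rep(0.5, 4), scaled = TRUE)
  expect_equal(unname(out), rep(0.5, 4))
})

test_that("without recurrence the output ignores depth and initialization", {
  set.seed(2)
  genes <- paste0("g", 1:5)
  w_x <- matrix(rnorm(3 * 5), 3, 5, dimnames = list(NULL, genes))
  b <- rnorm(5)
  x <- rnorm(3)
  outs <- lapply(c(1, 2, 5), function(n) {
    mod <- rnn_model(w_x, matrix(0, 5, 5), b, n = n,
                     scaler = make_scaler(genes))
    rnn_forward(mod, x, runif(5), scaled = TRUE)
  })
  direct <- 1 / (1 + exp(-(drop(x %*% w_x) + b)))
  for (o in outs) expect_equal(unname(o), unname(direct), tolerance = 1e-12)
})

test_that("two-gene forward pass equals a hand-unrolled computation", {
  genes <- c("gA", "gB")
  w_x <- matrix(c(0.5, -0.2,
                  0.1, 0.4), 2, 2, byrow = TRUE,
                dimnames = list(NULL, genes))
  w_y <- matrix(c(0, 0.3,
                  -0.6, 0), 2, 2, byrow = TRUE,
                dimnames = list(genes, genes))
  b <- c(0.05, -0.1)
  x <- c(1, 0.5); y0 <- c(0.4, 0.7)
  sig <- function(z) 1 / (1 + exp(-z))
  y1 <- sig(drop(x %*% w_x) + drop(y0 %*% w_y) + b)
  y2 <- sig(drop(x %*% w_x) + drop(y1 %*% w_y) + b)
  mod <- rnn_model(w_x, w_y, b, n = 2, scaler = make_scaler(genes))
  expect_equal(unname(rnn_forward(mod, x, y0, scaled = TRUE)), unname(y2),
               tolerance = 1e-14)
})

test_that("analytic gradients match central finite differences", {
  set.seed(3)
  D <- 4; G <- 3; N <- 5; n <- 2
  w_x <- matrix(rnorm(D * G, 0, 0.5), D, G)
  w_y <- matrix(rnorm(G * G, 0, 0.5), G, G)
  b <- rnorm(G, 0, 0.2)
  X <- matrix(rnorm(N * D), N, D)
  Y <- matrix(runif(N * G, 0.2, 0.8), N, G)
  S0 <- matrix(0.5, N, G)
  g <- omicforge:::rnn_loss_grad(w_x, w_y, b, n, X, Y, S0)
  h <- 1e-5
  fd <- function(get, set) {
    theta <- get()
    out <- array(0, dim = dim(as.matrix(theta)))
    for (i in seq_along(theta)) {
      tp <- theta; tp[i] <- tp[i] + h; set(tp)
      lp <- omicforge:::rnn_loss_grad(w_x, w_y, b, n, X, Y, S0)$loss
      tm <- theta; tm[i] <- tm[i] - h; set(tm)
      lm <- omicforge:::rnn_loss_grad(w_x, w_y, b, n, X, Y, S0)$loss
      set(theta)
      out[i] <- (lp - lm) / (2 * h)
    }
    out
  }
  fd_wx <- fd(function() w_x, function(v) w_x <<- v)
  fd_wy <- fd(function() w_y, function(v) w_y <<- v)
  fd_b <- fd(function() b, function(v) b <<- matrix(v))
  expect_lt(max(abs(g$gWx - fd_wx)), 1e-5)
  expect_lt(max(abs(g$gWy - fd_wy)), 1e-5)
  expect_lt(max(abs(g$gb - as.numeric(fd_b))), 1e-5)
})

test_that("clamped genes never leave their clamp at any depth", {
  set.seed(4)
  genes <- paste0("g", 1:6)
  w_x <- matrix(rnorm(18, 0, 2), 3, 6, dimnames = list(NULL, genes))
  w_y <- matrix(rnorm(36, 0, 2), 6, 6, dimnames = list(genes, genes))
  mod <- rnn_model(w_x, w_y, rnorm(6), n = 4, scaler = make_scaler(genes))
  out <- rnn_forward(mod, rnorm(3), runif(6), clamps = c(g2 = 0.11, g5 = 0.77),
                     scaled = TRUE)
  expect_equal(unname(out[c("g2", "g5")]), c(0.11, 0.77))
  expect_error(rnn_forward(mod, rnorm(3), runif(6), clamps = c(zz = 0.5),
                           scaled = TRUE), "unknown gene")
  expect_error(rnn_forward(mod, rnorm(2), runif(6), scaled = TRUE),
               "dimension")
})

test_that("heavy l1 drives weights to zero and predictions to sigma(b)", {
  sys <- generate_system(10, 12, 6, 4, 0.2, seed = 5)
  comp <- simulate_compendium(sys, 20, 1, 0, seed = 6, include_fluxes = FALSE)
  m <- train_rnn(comp, sys$registry, n = 2, lambda = 50, lr = 0.05,
                 epochs = 60, batch = 20, seed = 1)
  expect_equal(sum(m$w_x != 0) + sum(m$w_y != 0), 0)
  unpert <- comp$conditions$profile_id[comp$conditions$perturbations == ""]
  ids <- head(unpert, 3)
  sig_b <- 1 / (1 + exp(-m$b))
  for (p in ids) {
    pred <- predict_condition(m, profile_condition(comp, p), sys$registry)
    expect_equal(unname(scale_expression(m$scaler, pred)), unname(sig_b),
                 tolerance = 1e-10)
  }
})

test_that("weight sparsity is non-increasing in the l1 strength", {
  sys <- generate_system(10, 12, 6, 4, 0.2, seed = 7)
  comp <- simulate_compendium(sys, 25, 1, 0, seed = 8, include_fluxes = FALSE)
  nnz <- vapply(c(1e-5, 1e-3, 1e-2, 1e-1), function(lam) {
    m <- train_rnn(comp, sys$registry, n = 2, lambda = lam, lr = 0.2,
                   epochs = 150, batch = 25, seed = 2)
    sum(m$w_x != 0) + sum(m$w_y != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
  expect_error(train_rnn(comp, sys$registry, lambda = -1), "lambda")
})

test_that("knockout prediction clamps the gene to its floor", {
  sys <- generate_system(10, 12, 6, 4, 0.2, seed = 9)
  comp <- simulate_compendium(sys, 30, 1, 0, seed = 10,
                              include_fluxes = FALSE)
  m <- train_rnn(comp, sys$registry, n = 2, lambda = 1e-5, lr = 0.2,
                 epochs = 300, batch = 30, seed = 3)
  desc <- profile_condition(comp, colnames(comp$layers$transcript)[1])
  ko_gene <- sys$genes[3]
  pred <- predict_condition(m, desc, sys$registry, knockouts = ko_gene)
  floor_abs <- unscale_expression(m$scaler,
                                  setNames(rep(m$scaler$lo, 12), sys$genes))
  expect_equal(pred[[ko_gene]], floor_abs[[ko_gene]])
  # predictions stay within the scaler's representable range
  s <- scale_expression(m$scaler, pred)
  expect_true(all(s > 0 & s < 1))
})

test_that("a fixed point of the model maps to itself", {
  set.seed(11)
  genes <- paste0("g", 1:4)
  w_x <- matrix(rnorm(8, 0, 0.5), 2, 4, dimnames = list(NULL, genes))
  w_y <- matrix(rnorm(16, 0, 0.3), 4, 4, dimnames = list(genes, genes))
  b <- rnorm(4, 0, 0.2)
  mod <- rnn_model(w_x, w_y, b, n = 3, scaler = make_scaler(genes))
  x <- rnorm(2)
  s <- rep(0.5, 4)
  for (i in 1:200) s <- 1 / (1 + exp(-(drop(x %*% w_x) + drop(s %*% w_y) + b)))
  out <- rnn_forward(mod, x, s, scaled = TRUE)
  expect_equal(unname(out), unname(s), tolerance = 1e-8)
})
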
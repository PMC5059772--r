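# Transcriptome layer: a sigmoid recurrent network mapping condition features
# to genome-wide expression.  The network state is a gene vector in (0,1)
# (sigmoid range); an invertible per-gene min-max scaler on log absolute
# expression bridges sigmoid space and copies-per-cell space.

#' Fit the expression scaler of the recurrent model
#'
#' Per-gene min-max rescaling of log absolute expression into
#' `[lo, hi] = [0.05, 0.95]`: sigmoid outputs cannot reach 0/1, so the
#' training range is mapped strictly inside the unit interval.  Constant
#' genes map to the interval midpoint.
#'
#' @param abs_matrix genes x profiles matrix of absolute expression (> 0).
#' @param lo,hi target interval inside (0,1).
#' @return an `expression_scaler` with `scale`/`unscale` applied via
#'   [scale_expression()] and [unscale_expression()].
#' @export
fit_expression_scaler <- function(abs_matrix, lo = 0.05, hi = 0.95) {
  stopifnot(lo > 0, hi < 1, lo < hi)
  if (any(abs_matrix[!is.na(abs_matrix)] <= 0))
    stop("absolute expression must be positive to fit the log scaler")
  lmat <- log(abs_matrix)
  lmin <- apply(lmat, 1, min, na.rm = TRUE)
  lmax <- apply(lmat, 1, max, na.rm = TRUE)
  structure(list(log_min = lmin, log_max = lmax, lo = lo, hi = hi,
                 genes = rownames(abs_matrix)),
            class = "expression_scaler")
}

#' Map absolute expression into sigmoid space
#' @param scaler an [fit_expression_scaler()] result.
#' @param y absolute-scale vector/matrix aligned to the scaler's genes (rows).
#' @return values in sigmoid space (training range maps into `[lo, hi]`).
#' @export
scale_expression <- function(scaler, y) {
  rng <- scaler$log_max - scaler$log_min
  f <- function(v) {
    s <- ifelse(rng > 0,
                scaler$lo + (scaler$hi - scaler$lo) * (log(v) - scaler$log_min) / rng,
                (scaler$lo + scaler$hi) / 2)
    s
  }
  if (is.matrix(y)) apply(y, 2, f) else f(y)
}

#' Map sigmoid-space expression back to absolute scale
#' @param scaler an [fit_expression_scaler()] result.
#' @param s sigmoid-space vector/matrix aligned to the scaler's genes.
#' @return absolute-scale values (log-linear extrapolation outside `[lo, hi]`).
#' @export
unscale_expression <- function(scaler, s) {
  rng <- scaler$log_max - scaler$log_min
  f <- function(v) exp(scaler$log_min +
                         (v - scaler$lo) / (scaler$hi - scaler$lo) *
                         ifelse(rng > 0, rng, 0))
  if (is.matrix(s)) apply(s, 2, f) else f(s)
}

#' Construct a recurrent expression model
#'
#' @param w_x input-to-gene weight matrix (features x genes).
#' @param w_y gene-to-gene recurrent weight matrix (genes x genes; entry
#'   `[h, g]` couples source gene h to target gene g).
#' @param b per-gene bias.
#' @param n memory depth (number of recurrent iterations, >= 1).
#' @param scaler an [fit_expression_scaler()] result.
#' @param lambda l1 strength used in training (bookkeeping).
#' @param seed training seed (bookkeeping).
#' @return an object of class `rnn_model`.
#' @export
rnn_model <- function(w_x, w_y, b, n, scaler, lambda = 0, seed = NA_integer_) {
  w_x <- as.matrix(w_x); w_y <- as.matrix(w_y)
  G <- length(b)
  if (ncol(w_x) != G || any(dim(w_y) != c(G, G)))
    stop("inconsistent RNN weight dimensions")
  if (n < 1) stop("memory depth n must be >= 1")
  if (!is.null(scaler) && length(scaler$log_min) != G)
    stop("scaler does not match gene count")
  structure(list(w_x = w_x, w_y = w_y, b = as.numeric(b), n = as.integer(n),
                 scaler = scaler, lambda = lambda, seed = seed,
                 features = rownames(w_x),
                 genes = colnames(w_x) %||% scaler$genes),
            class = "rnn_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rnn_model <- function(x, ...) {
  cat("<rnn_model>", nrow(x$w_x), "features ->", ncol(x$w_x),
      "genes, memory depth", x$n, "\n")
  invisible(x)
}

# Core recurrence in sigmoid space.  X: N x D, S0: N x G.  clamp_idx /
# clamp_val: scaled clamp applied to y0 and re-applied after every iteration.
rnn_iterate <- function(w_x, w_y, b, n, X, S0, clamp_idx = integer(0),
                        clamp_val = numeric(0)) {
  S <- S0
  if (length(clamp_idx)) S[, clamp_idx] <- rep(clamp_val, each = nrow(S))
  states <- vector("list", n + 1); states[[1]] <- S
  XW <- X %*% w_x
  for (i in seq_len(n)) {
    S <- sigmoid(sweep(XW + S %*% w_y, 2, b, `+`))
    if (length(clamp_idx)) S[, clamp_idx] <- rep(clamp_val, each = nrow(S))
    states[[i + 1]] <- S
  }
  states
}

#' Run the recurrent network forward
#'
#' Starting from the scaled initial profile `y0`, applies `n` iterations of
#' `y <- sigmoid(w_x' x + w_y' y + b)`.  Clamped genes are overwritten with
#' their clamp value in the initial state and after every iteration, so a
#' clamp is absolute: the gene's trajectory never leaves it.
#'
#' @param model an [rnn_model()].
#' @param x condition feature vector (length = feature dimension).
#' @param y0 initial expression profile; absolute scale unless `scaled = TRUE`.
#' @param clamps named numeric vector gene -> clamp value (same scale as `y0`).
#' @param scaled if `TRUE`, `y0`/`clamps` are already in sigmoid space and the
#'   result is returned in sigmoid space.
#' @return named expression vector after `n` iterations.
#' @export
rnn_forward <- function(model, x, y0, clamps = NULL, scaled = FALSE) {
  if (length(x) != nrow(model$w_x))
    stop("feature vector length ", length(x), " does not match model input ",
         "dimension ", nrow(model$w_x))
  if (length(y0) != ncol(model$w_x))
    stop("initial profile length does not match gene count")
  genes <- model$genes
  clamp_idx <- integer(0); clamp_val <- numeric(0)
  if (!is.null(clamps) && length(clamps)) {
    if (is.null(names(clamps))) stop("clamps must be named by gene id")
    unknown <- setdiff(names(clamps), genes)
    if (length(unknown)) stop("clamp on unknown gene(s): ",
                              paste(unknown, collapse = ", "))
    clamp_idx <- match(names(clamps), genes)
    clamp_val <- as.numeric(clamps)
  }
  s0 <- if (scaled) y0 else scale_expression(model$scaler, y0)
  if (!scaled && length(clamp_idx)) {
    sc <- model$scaler
    rng <- (sc$log_max - sc$log_min)[clamp_idx]
    clamp_val <- ifelse(rng > 0,
                        sc$lo + (sc$hi - sc$lo) *
                          (log(clamp_val) - sc$log_min[clamp_idx]) / rng,
                        (sc$lo + sc$hi) / 2)
  }
  states <- rnn_iterate(model$w_x, model$w_y, model$b, model$n,
                        matrix(x, 1), matrix(s0, 1), clamp_idx, clamp_val)
  out <- drop(states[[model$n + 1]])
  names(out) <- genes
  if (scaled) out else unscale_expression(model$scaler, out)
}

# Loss (mean over samples of squared error summed over genes) and exact
# gradients by backpropagation through time.  Yobs is in sigmoid space.
rnn_loss_grad <- function(w_x, w_y, b, n, X, Yobs, S0,
                          clamp_idx = integer(0), clamp_val = numeric(0)) {
  N <- nrow(X)
  states <- rnn_iterate(w_x, w_y, b, n, X, S0, clamp_idx, clamp_val)
  Sn <- states[[n + 1]]
  R <- Sn - Yobs
  loss <- sum(R * R) / N
  dS <- 2 * R / N
  gWx <- matrix(0, nrow(w_x), ncol(w_x))
  gWy <- matrix(0, nrow(w_y), ncol(w_y))
  gb <- numeric(length(b))
  for (i in seq(n, 1)) {
    Si <- states[[i + 1]]
    if (length(clamp_idx)) dS[, clamp_idx] <- 0   # clamped outputs carry no gradient
    A <- dS * Si * (1 - Si)
    gWx <- gWx + crossprod(X, A)
    gWy <- gWy + crossprod(states[[i]], A)
    gb <- gb + colSums(A)
    dS <- A %*% t(w_y)
  }
  list(loss = loss, gWx = gWx, gWy = gWy, gb = gb)
}

#' Train the recurrent expression model
#'
#' Minimizes the residual sum of squares between observed and predicted
#' (sigmoid-space) expression over all training profiles, plus an l1 penalty
#' on the weights, by mini-batch stochastic gradient descent with a proximal
#' soft-threshold step for the penalty.  The per-epoch mean loss is recorded;
#' a NaN loss aborts with diagnostics.
#'
#' @param comp a [compendium()] whose `transcript` layer is on absolute scale.
#' @param registry a [feature_registry()] for condition encoding.
#' @param n memory depth (default 2).
#' @param lambda l1 strength (>= 0).
#' @param lr SGD learning rate.
#' @param epochs passes over the training profiles.
#' @param batch mini-batch size.
#' @param seed RNG seed controlling weight initialization and shuffling.
#' @param momentum classical momentum coefficient of the SGD updates.
#' @param init_profile optional absolute-scale initial state; default is the
#'   mean unperturbed (wild-type) training profile.
#' @return an [rnn_model()] with `$history` (epoch losses) and `$init_scaled`.
#' @export
train_rnn <- function(comp, registry, n = 2, lambda = 1e-4, lr = 0.5,
                      epochs = 300, batch = 16, seed = 1, momentum = 0.9,
                      init_profile = NULL) {
  if (lambda < 0) stop("lambda must be >= 0")
  Yabs <- comp$layers$transcript
  if (is.null(Yabs)) stop("compendium has no transcript layer")
  prof_ids <- colnames(Yabs)
  if (length(unique(condition_key(
    comp$conditions[comp$conditions$profile_id %in% prof_ids, ]))) < 2)
    stop("need at least 2 training conditions")
  X <- t(vapply(prof_ids, function(p)
    encode_condition(profile_condition(comp, p), registry),
    numeric(length(registry))))
  scaler <- fit_expression_scaler(Yabs)
  Ys <- t(scale_expression(scaler, Yabs))           # N x G
  G <- ncol(Ys); D <- ncol(X); N <- nrow(Ys)
  if (is.null(init_profile)) {
    cond <- comp$conditions[match(prof_ids, comp$conditions$profile_id), ]
    wt <- is.na(cond$perturbations) | cond$perturbations == ""
    init_scaled <- if (any(wt)) colMeans(Ys[wt, , drop = FALSE])
                   else colMeans(Ys)
  } else init_scaled <- scale_expression(scaler, init_profile)

  with_seed(seed, {
    w_x <- matrix(runif(D * G, -1, 1) / sqrt(D), D, G,
                  dimnames = list(registry$features, rownames(Yabs)))
    w_y <- matrix(runif(G * G, -1, 1) / sqrt(G), G, G,
                  dimnames = list(rownames(Yabs), rownames(Yabs)))
    b <- numeric(G)
    vWx <- matrix(0, D, G); vWy <- matrix(0, G, G); vb <- numeric(G)
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0
      for (start in seq(1, N, by = batch)) {
        idx <- ord[start:min(start + batch - 1, N)]
        S0 <- matrix(init_scaled, length(idx), G, byrow = TRUE)
        g <- rnn_loss_grad(w_x, w_y, b, n, X[idx, , drop = FALSE],
                           Ys[idx, , drop = FALSE], S0)
        if (!is.finite(g$loss))
          stop("NaN/Inf training loss at epoch ", ep,
               " (lr too high or degenerate data); last finite epoch losses: ",
               paste(signif(tail(history[seq_len(ep - 1)], 3), 4),
                     collapse = ", "))
        vWx <- momentum * vWx - lr * g$gWx
        vWy <- momentum * vWy - lr * g$gWy
        vb <- momentum * vb - lr * g$gb
        w_x <- soft_threshold(w_x + vWx, lr * lambda)
        w_y <- soft_threshold(w_y + vWy, lr * lambda)
        b <- b + vb
        ep_loss <- ep_loss + g$loss * length(idx)
      }
      history[ep] <- ep_loss / N
    }
    model <- rnn_model(w_x, w_y, b, n, scaler, lambda = lambda, seed = seed)
    model$history <- history
    model$init_scaled <- init_scaled
    model
  })
}

#' Predict genome-wide expression for a condition
#'
#' Encodes the condition, scales the initialization profile, clamps knockout
#' genes to their scaled floor (the minimum of the gene's training range;
#' literal zero has no log-space image) throughout the recurrence and returns
#' the absolute-scale prediction.
#'
#' @param model a trained [rnn_model()].
#' @param descriptor a [condition_descriptor()]; knockout perturbations listed
#'   in it are clamped automatically.
#' @param registry the [feature_registry()] the model was trained with.
#' @param init_profile absolute-scale initial profile; default the model's
#'   stored training initialization.
#' @param knockouts additional gene ids to clamp.
#' @return named absolute-scale expression vector.
#' @export
predict_condition <- function(model, descriptor, registry,
                              init_profile = NULL, knockouts = character(0)) {
  x <- encode_condition(descriptor, registry)
  desc_kos <- sub(":knockout$", "",
                  grep(":knockout$", descriptor$perturbations, value = TRUE))
  kos <- union(knockouts, desc_kos)
  s0 <- if (is.null(init_profile)) {
    if (is.null(model$init_scaled)) stop("model has no stored initialization")
    model$init_scaled
  } else scale_expression(model$scaler, init_profile)
  clamp_idx <- integer(0); clamp_val <- numeric(0)
  if (length(kos)) {
    unknown <- setdiff(kos, model$genes)
    if (length(unknown)) stop("knockout of unknown gene(s): ",
                              paste(unknown, collapse = ", "))
    clamp_idx <- match(kos, model$genes)
    clamp_val <- rep(model$scaler$lo, length(kos))   # scaled floor
  }
  states <- rnn_iterate(model$w_x, model$w_y, model$b, model$n,
                        matrix(x, 1), matrix(s0, 1), clamp_idx, clamp_val)
  out <- drop(states[[model$n + 1]])
  names(out) <- model$genes
  unscale_expression(model$scaler, out)
}

#' @importFrom utils tail
NULL
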
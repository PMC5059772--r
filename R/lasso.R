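# Shared l1-regularized regression helper used by the proteome, metabolome
# and phenome layers.  Wraps glmnet with the edge cases those layers meet:
# empty/singleton predictor sets, constant responses, cross-validated lambda
# with the one-standard-error rule, deterministic folds given a seed.

fit_lasso <- function(x, y, seed = 1, nfolds = 5, one_se = TRUE,
                      lambda = NULL) {
  x <- as.matrix(x)
  keep <- stats::complete.cases(x) & is.finite(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  if (n < 3) stop("fit_lasso: fewer than 3 complete observations")
  if (sd(y) == 0 || ncol(x) == 0) {
    return(structure(list(coef = setNames(numeric(ncol(x)), colnames(x)),
                          intercept = mean(y), lambda = Inf,
                          intercept_only = TRUE),
                     class = "lasso_fit"))
  }
  if (ncol(x) == 1) {
    # glmnet needs >= 2 columns; a single predictor is an ordinary fit
    fit <- stats::lm.fit(cbind(1, x), y)
    cf <- fit$coefficients
    return(structure(list(coef = setNames(ifelse(is.na(cf[2]), 0, cf[2]),
                                          colnames(x)),
                          intercept = cf[1], lambda = 0,
                          intercept_only = FALSE),
                     class = "lasso_fit"))
  }
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(min(nfolds, n)), n))
    cv <- glmnet::cv.glmnet(x, y, foldid = foldid, lambda = lambda,
                            standardize = TRUE)
    lam <- if (one_se) cv$lambda.1se else cv$lambda.min
    beta <- as.numeric(stats::coef(cv, s = lam))
    structure(list(coef = setNames(beta[-1], colnames(x)),
                   intercept = beta[1], lambda = lam,
                   intercept_only = all(beta[-1] == 0)),
              class = "lasso_fit")
  })
}

predict_lasso <- function(fit, x) {
  if (is.null(fit)) return(NULL)
  sup <- names(fit$coef)[fit$coef != 0]
  if (is.matrix(x)) {
    miss <- setdiff(sup, colnames(x))
    if (length(miss)) stop("missing predictor(s): ", paste(miss, collapse = ", "))
    drop(fit$intercept +
           x[, names(fit$coef), drop = FALSE] %*% fit$coef)
  } else {
    miss <- setdiff(sup, names(x))
    if (length(miss)) stop("missing predictor(s): ", paste(miss, collapse = ", "))
    v <- x[names(fit$coef)]
    v[is.na(v)] <- 0
    unname(fit$intercept + sum(v * fit$coef))
  }
}
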
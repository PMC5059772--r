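# Phenome layer: growth rate as a cross-validation-performance-weighted sum
# of per-layer LASSO predictions.  Each layer predicts growth from its own
# molecular values plus the extracellular condition features; weights are
# proportional to each layer's leave-one-condition-out PCC clipped at zero.

#' Train the growth-rate integrator
#'
#' Per layer: LASSO of growth rate on the layer's molecule values plus the
#' encoded condition features; lambda by inner CV; the layer's performance
#' `p` is its leave-one-condition-out PCC (the fold model is refit at the
#' chosen lambda on each fold's training conditions).  Weights are
#' `max(p, 0)` normalized to sum to one; layers with no labeled data get
#' weight 0 and are flagged.
#'
#' @param comp a [compendium()] with growth labels.
#' @param registry a [feature_registry()] (the extracellular "input" layer).
#' @param layers which molecular layers to use (plus the `input` layer).
#' @param min_labeled minimum growth-labeled profiles per layer.
#' @param seed RNG seed.
#' @return object of class `growth_integrator` with `predictors`,
#'   `performance`, `weights`, `flagged`.
#' @export
train_growth_integrator <- function(comp, registry,
                                    layers = c("input", "transcript",
                                               "protein", "metabolite",
                                               "flux"),
                                    min_labeled = 10, seed = 1) {
  if (is.null(comp$growth)) stop("compendium has no growth labels")
  enc <- function(ids) t(vapply(ids, function(p)
    encode_condition(profile_condition(comp, p), registry),
    numeric(length(registry))))
  predictors <- list(); performance <- numeric(0); flagged <- character(0)
  folds <- loco_folds(comp)
  for (ly in layers) {
    if (ly == "input") {
      ids <- intersect(names(comp$growth), comp$conditions$profile_id)
      X <- enc(ids)
    } else {
      m <- comp$layers[[ly]]
      if (is.null(m)) { flagged <- c(flagged, ly); next }
      ids <- intersect(colnames(m), names(comp$growth))
      if (length(ids) < min_labeled) { flagged <- c(flagged, ly); next }
      X <- cbind(t(m[, ids, drop = FALSE]), enc(ids))
    }
    if (length(ids) < min_labeled) { flagged <- c(flagged, ly); next }
    y <- comp$growth[ids]
    fit <- fit_lasso(X, y, seed = seed)
    # LOCO performance at the chosen lambda
    preds <- setNames(rep(NA_real_, length(ids)), ids)
    for (f in folds) {
      te <- intersect(ids, f$test); tr <- setdiff(ids, te)
      if (!length(te) || length(tr) < 3) next
      ffit <- if (ncol(X) >= 2 && sd(y[tr]) > 0 && is.finite(fit$lambda) &&
                  fit$lambda > 0) {
        g <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], lambda = fit$lambda,
                            standardize = TRUE)
        beta <- as.numeric(stats::coef(g))
        structure(list(coef = setNames(beta[-1], colnames(X)),
                       intercept = beta[1], lambda = fit$lambda),
                  class = "lasso_fit")
      } else {
        structure(list(coef = setNames(numeric(ncol(X)), colnames(X)),
                       intercept = mean(y[tr]), lambda = Inf),
                  class = "lasso_fit")
      }
      preds[te] <- predict_lasso(ffit, X[te, , drop = FALSE])
    }
    ok <- is.finite(preds)
    p <- if (sum(ok) >= 3 && sd(preds[ok]) > 0)
      suppressWarnings(pcc(preds[ok], y[ok])) else 0
    fit$molecules <- if (ly == "input") registry$features
                     else rownames(comp$layers[[ly]])
    predictors[[ly]] <- fit
    performance[ly] <- if (is.finite(p)) p else 0
  }
  if (!length(predictors)) stop("no layer had labeled growth data")
  w <- pmax(performance, 0)
  if (sum(w) == 0) w <- rep(1, length(w))
  w <- w / sum(w)
  structure(list(predictors = predictors, performance = performance,
                 weights = w, flagged = flagged, layers = names(predictors),
                 seed = seed),
            class = "growth_integrator")
}

#' @export
print.growth_integrator <- function(x, ...) {
  cat("<growth_integrator>\n")
  for (ly in x$layers)
    cat(sprintf("  %-11s p=%+.3f w=%.3f\n", ly, x$performance[[ly]],
                x$weights[[ly]]))
  if (length(x$flagged)) cat("  flagged (no data):",
                             paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Combine per-layer growth predictions
#'
#' Weighted sum over the available layers, weights renormalized to the
#' available subset; the result is floored at zero (a growth rate).
#'
#' @param integrator a [train_growth_integrator()] result.
#' @param layer_predictions named numeric vector of per-layer growth
#'   predictions (subset of the integrator's layers).
#' @return nonnegative growth rate (1/h).
#' @export
combine_growth_predictions <- function(integrator, layer_predictions) {
  avail <- intersect(names(layer_predictions), integrator$layers)
  if (!length(avail)) stop("no available layer predictions")
  w <- integrator$weights[avail]
  if (sum(w) == 0) w <- rep(1, length(w))
  w <- w / sum(w)
  max(0, sum(w * layer_predictions[avail]))
}

#' Predict growth rate for a condition
#'
#' Applies each layer's LASSO to the supplied molecular values (plus the
#' encoded condition features) and combines the per-layer predictions with
#' [combine_growth_predictions()].
#'
#' @param integrator a [train_growth_integrator()] result.
#' @param descriptor a [condition_descriptor()].
#' @param registry the [feature_registry()] used in training.
#' @param layer_values named list layer -> named molecule vector (e.g.
#'   `list(transcript = ..., protein = ...)`); layers may be missing.
#' @return list with `growth` (1/h) and `per_layer` predictions.
#' @export
predict_growth <- function(integrator, descriptor, registry,
                           layer_values = list()) {
  x <- encode_condition(descriptor, registry)
  per_layer <- numeric(0)
  for (ly in integrator$layers) {
    fit <- integrator$predictors[[ly]]
    inp <- if (ly == "input") x else {
      if (is.null(layer_values[[ly]])) next
      c(layer_values[[ly]], x)
    }
    pred <- tryCatch(predict_lasso(fit, inp), error = function(e) NA_real_)
    if (is.finite(pred)) per_layer[ly] <- pred
  }
  if (!length(per_layer)) stop("no layer could produce a growth prediction")
  list(growth = combine_growth_predictions(integrator, per_layer),
       per_layer = per_layer)
}

#' Report the informative molecules of each layer
#'
#' Features with nonzero LASSO weight, ranked per layer by absolute
#' coefficient.  This report is diagnostic only and never feeds back into
#' prediction (restricting the predictors to a top list collapses
#' performance).
#'
#' @param integrator a [train_growth_integrator()] result.
#' @param top_k rows reported per layer.
#' @return data frame with `layer`, `molecule`, `abs_weight`, `rank`.
#' @export
report_informative_features <- function(integrator, top_k = 10) {
  out <- lapply(integrator$layers, function(ly) {
    cf <- integrator$predictors[[ly]]$coef
    mols <- integrator$predictors[[ly]]$molecules
    if (!is.null(mols)) cf <- cf[names(cf) %in% mols]
    cf <- cf[cf != 0]
    if (!length(cf)) return(NULL)
    cf <- cf[order(-abs(cf))]
    head(data.frame(layer = ly, molecule = names(cf), abs_weight = abs(cf),
                    rank = seq_along(cf), row.names = NULL), top_k)
  })
  do.call(rbind, out)
}
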
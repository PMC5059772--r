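# Phenomics layer: growth features from plate-reader curves and inference of
# missing growth-phase labels from genome-wide expression.

#' Extract growth features from a plate-reader curve
#'
#' The OD series is smoothed with a 3-point running median; the maximum
#' specific growth rate is the largest slope of ln(OD) over sliding windows
#' of width `window_h` advanced every `slide_min` minutes, restricted to
#' windows whose smoothed OD stays within `[density_lo, density_hi]` of the
#' maximum density; the lag is the first time the instantaneous ln(OD) slope
#' reaches `lag_frac` of the maximum rate.  A never-growing curve returns
#' zero rate, lag equal to the horizon and a `degenerate` flag.
#'
#' @param curve list with `time` (hours, strictly increasing) and `od`
#'   (nonnegative), e.g. from [simulate_growth_curve()]; >= 8 points.
#' @param window_h sliding-window width (hours).
#' @param slide_min window advance (minutes).
#' @param density_lo,density_hi eligible OD band as fractions of max density.
#' @param lag_frac fraction of the maximum rate defining the lag.
#' @param linear_slope if `TRUE`, slopes are computed on OD instead of
#'   ln(OD) (units OD/h instead of 1/h).
#' @return list of class `growth_features`: `lag_h`, `mu_max`,
#'   `max_density`, `degenerate`.
#' @export
extract_growth_features <- function(curve, window_h = 1.0, slide_min = 15,
                                    density_lo = 0.10, density_hi = 0.90,
                                    lag_frac = 0.05, linear_slope = FALSE) {
  time <- curve$time; od <- curve$od
  if (length(time) < 8) stop("need >= 8 points for feature extraction")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (any(od < 0)) stop("negative OD")
  if (diff(range(time)) < window_h) stop("curve shorter than the window width")
  sm <- as.numeric(stats::runmed(od, 3))
  max_density <- max(sm)
  lo <- density_lo * max_density; hi <- density_hi * max_density
  horizon <- max(time)

  # instantaneous slope (midpoint series) for lag detection and degeneracy
  dln <- if (linear_slope) diff(sm) / diff(time)
         else diff(log(pmax(sm, 1e-9))) / diff(time)
  tmid <- head(time, -1)

  eps <- 1e-9 * max_density
  starts <- seq(time[1], horizon - window_h, by = slide_min / 60)
  slopes <- rep(NA_real_, length(starts))
  for (w in seq_along(starts)) {
    idx <- which(time >= starts[w] - 1e-9 & time <= starts[w] + window_h + 1e-9)
    if (length(idx) < 2) next
    o <- sm[idx]
    if (any(o < lo - eps) || any(o > hi + eps)) next
    if (!linear_slope && any(o <= 0))
      stop("non-positive OD inside an eligible window")
    y <- if (linear_slope) o else log(o)
    slopes[w] <- stats::cov(time[idx], y) / stats::var(time[idx])
  }
  eligible <- which(is.finite(slopes))
  if (!length(eligible)) {
    if (max(dln) < 0.01) {  # flat curve: no measurable growth
      return(structure(list(lag_h = horizon, mu_max = 0,
                            max_density = max_density, degenerate = TRUE),
                       class = "growth_features"))
    }
    stop("no eligible window with >= 2 points inside the density band")
  }
  mu_max <- max(slopes[eligible])
  if (mu_max <= 0) {
    return(structure(list(lag_h = horizon, mu_max = max(0, mu_max),
                          max_density = max_density, degenerate = TRUE),
                     class = "growth_features"))
  }
  reached <- which(dln >= lag_frac * mu_max)
  lag_h <- if (length(reached)) tmid[reached[1]] else horizon
  structure(list(lag_h = lag_h, mu_max = mu_max, max_density = max_density,
                 degenerate = FALSE),
            class = "growth_features")
}

#' @export
print.growth_features <- function(x, ...) {
  cat(sprintf("<growth_features> mu_max=%.3f/h lag=%.2fh max_density=%.3f%s\n",
              x$mu_max, x$lag_h, x$max_density,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Mutual information between a numeric feature and a binary label, with
# equal-frequency discretization of the feature.
mutual_information <- function(x, y, bins = 8) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        na.rm = TRUE))
  if (length(br) < 2) return(0)
  xb <- cut(x, breaks = br, include.lowest = TRUE)
  tab <- table(xb, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  mi
}

#' Train a growth-phase classifier from expression
#'
#' Genes are ranked by mutual information with the binary phase label
#' (equal-frequency discretization); features are then added greedily in MI
#' order while stratified cross-validated accuracy of an RBF-kernel SVM
#' improves, stopping after `max_stall` consecutive non-improving additions.
#' The final classifier is refit on all data.
#'
#' @param expr genes x profiles expression matrix.
#' @param labels factor/character phase labels aligned to the profiles
#'   (exactly two classes).
#' @param n_folds stratified CV folds.
#' @param seed RNG seed (fold assignment).
#' @param max_genes cap on candidate genes considered.
#' @param max_stall greedy stop rule.
#' @param bins MI discretization bins.
#' @return object of class `phase_classifier` with `features`, `cv_accuracy`,
#'   `cv_record`, the fitted SVM and training means.
#' @export
train_phase_classifier <- function(expr, labels, n_folds = 10, seed = 1,
                                   max_genes = 50, max_stall = 5, bins = 8) {
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("need exactly two phase classes, got ", nlevels(labels))
  if (ncol(expr) != length(labels)) stop("labels must align to profiles")
  mi <- apply(expr, 1, mutual_information, y = labels, bins = bins)
  ranked <- rownames(expr)[order(-mi, seq_along(mi))]
  ranked <- head(ranked, max_genes)

  with_seed(seed, {
    folds <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(min(n_folds, length(idx))),
                                   length(idx)))
    }
    cv_acc <- function(genes) {
      X <- t(expr[genes, , drop = FALSE])
      correct <- 0
      for (f in unique(folds)) {
        tr <- folds != f
        if (length(unique(labels[tr])) < 2) next
        fit <- e1071::svm(X[tr, , drop = FALSE], labels[tr], kernel = "radial")
        correct <- correct + sum(predict(fit, X[!tr, , drop = FALSE]) ==
                                   labels[!tr])
      }
      correct / length(labels)
    }
    selected <- character(0); best <- -Inf; stall <- 0
    record <- data.frame(gene = character(0), cv_accuracy = numeric(0),
                         kept = logical(0))
    for (g in ranked) {
      acc <- cv_acc(c(selected, g))
      keep <- acc > best
      record <- rbind(record, data.frame(gene = g, cv_accuracy = acc,
                                         kept = keep))
      if (keep) { selected <- c(selected, g); best <- acc; stall <- 0 }
      else { stall <- stall + 1; if (stall >= max_stall) break }
      if (best >= 1) break
    }
    if (!length(selected)) selected <- ranked[1]
    X <- t(expr[selected, , drop = FALSE])
    fit <- e1071::svm(X, labels, kernel = "radial", probability = TRUE)
    structure(list(features = selected, cv_accuracy = max(best, 0),
                   cv_record = record, svm = fit,
                   training_means = rowMeans(expr[selected, , drop = FALSE]),
                   classes = levels(labels), seed = seed),
              class = "phase_classifier")
  })
}

#' @export
print.phase_classifier <- function(x, ...) {
  cat("<phase_classifier>", length(x$features), "genes, CV accuracy",
      sprintf("%.3f", x$cv_accuracy), "\n")
  invisible(x)
}

#' Infer growth phase for unlabeled profiles
#'
#' @param classifier a [train_phase_classifier()] result.
#' @param profiles genes x profiles matrix containing the selected genes
#'   (missing selected genes are imputed by training means with a warning;
#'   all-missing profiles are an error).
#' @return data frame with `profile`, `label` and decision `score`.
#' @export
infer_phase <- function(classifier, profiles) {
  sel <- classifier$features
  X <- matrix(NA_real_, ncol(profiles), length(sel),
              dimnames = list(colnames(profiles), sel))
  present <- intersect(sel, rownames(profiles))
  if (!length(present)) stop("all selected genes missing from profiles")
  X[, present] <- t(profiles[present, , drop = FALSE])
  if (anyNA(X)) {
    warning("missing selected gene values imputed by training means")
    for (g in sel) X[is.na(X[, g]), g] <- classifier$training_means[[g]]
  }
  if (anyNA(X)) {
    bad <- rowSums(is.na(X)) > 0
    stop("profiles with no usable selected genes: ",
         paste(rownames(X)[bad], collapse = ", "))
  }
  pred <- predict(classifier$svm, X, decision.values = TRUE)
  data.frame(profile = rownames(X), label = as.character(pred),
             score = as.numeric(attr(pred, "decision.values")),
             stringsAsFactors = FALSE)
}
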
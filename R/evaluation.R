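# Leave-one-condition-out evaluation, Pearson scoring and the three
# reference baselines every layer is compared against.

#' Pearson correlation over co-observed entries
#'
#' @param predicted,observed numeric vectors of equal length; entries missing
#'   in either are dropped.
#' @return Pearson correlation; `NaN` (with a warning) when either vector has
#'   zero variance over the co-observed entries.
#' @export
pcc <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("pcc: length mismatch")
  ok <- is.finite(predicted) & is.finite(observed)
  if (sum(ok) < 3) stop("pcc: fewer than 3 co-observed entries")
  x <- predicted[ok]; y <- observed[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("pcc undefined: zero variance")
    return(NaN)
  }
  cor(x, y)
}

#' Leave-one-condition-out folds
#'
#' One fold per unique condition tuple (strain, medium, stresses,
#' perturbations); all replicates and layer profiles of the held-out
#' condition go to the test side, so no condition ever appears on both sides.
#'
#' @param comp a [compendium()].
#' @return list of folds, each `list(key, train, test)` of profile ids.
#' @export
loco_folds <- function(comp) {
  keys <- condition_key(comp$conditions)
  uniq <- unique(keys)
  if (length(uniq) < 2) stop("leave-one-condition-out needs >= 2 conditions")
  lapply(uniq, function(k) {
    test <- comp$conditions$profile_id[keys == k]
    list(key = k, train = setdiff(comp$conditions$profile_id, test),
         test = test)
  })
}

#' Baseline expression predictions
#'
#' `mean`: mean profile over all training profiles.  `random`: mean over a
#' seeded random subset of training profiles.  `wildtype`: mean over
#' unperturbed training profiles (error when none exist).
#'
#' @param kind `"random"`, `"mean"` or `"wildtype"`.
#' @param training molecules x profiles matrix of training values.
#' @param conditions condition table covering the training profiles
#'   (required for `wildtype`).
#' @param seed RNG seed for the random subset.
#' @param subset_size number of profiles the random baseline draws.
#' @return named baseline profile vector.
#' @export
baseline_predict <- function(kind = c("random", "mean", "wildtype"), training,
                             conditions = NULL, seed = 1, subset_size = 10) {
  kind <- match.arg(kind)
  if (ncol(training) == 0) stop("empty training set")
  cols <- switch(kind,
    mean = seq_len(ncol(training)),
    random = with_seed(seed, sample.int(ncol(training),
                                        min(subset_size, ncol(training)))),
    wildtype = {
      if (is.null(conditions)) stop("wildtype baseline needs the condition table")
      idx <- match(colnames(training), conditions$profile_id)
      wt <- which(is.na(conditions$perturbations[idx]) |
                    conditions$perturbations[idx] == "")
      if (!length(wt)) stop("no wild-type (unperturbed) training profiles")
      wt
    })
  rowMeans(training[, cols, drop = FALSE], na.rm = TRUE)
}

#' Leave-one-condition-out evaluation harness
#'
#' For every fold: fits the supplied model on the training profiles only,
#' predicts each held-out profile, and scores model and baselines by
#' per-profile Pearson correlation.  Refitting inside the fold guarantees no
#' leakage of held-out profiles.
#'
#' @param comp a [compendium()].
#' @param layer layer to evaluate.
#' @param fit_fun `function(train_comp)` returning a fitted object.
#' @param predict_fun `function(fit, descriptor, train_comp)` returning a
#'   named molecule vector for a held-out condition.
#' @param baselines subset of `c("random", "mean", "wildtype")`.
#' @param seed seed for the random baseline.
#' @param subset_size random-baseline subset size.
#' @param molecules optional molecule subset to score (e.g. TF-only reports).
#' @param score_transform transform applied to predictions and observations
#'   before correlation (default identity; `log` is the convention for
#'   absolute expression levels).
#' @return an `evaluation_report`: list with `per_profile` (data frame of
#'   per-profile PCCs), `summary` (mean ± sd per method, NaN profiles
#'   excluded with count), `folds`, `seed`.
#' @export
evaluate_loco <- function(comp, layer = "transcript", fit_fun, predict_fun,
                          baselines = c("random", "mean", "wildtype"),
                          seed = 1, subset_size = 10, molecules = NULL,
                          score_transform = identity) {
  folds <- loco_folds(comp)
  mat <- comp$layers[[layer]]
  if (is.null(mat)) stop("compendium has no '", layer, "' layer")
  rows <- list()
  for (f in folds) {
    train_ids <- intersect(f$train, colnames(mat))
    test_ids <- intersect(f$test, colnames(mat))
    if (!length(test_ids) || !length(train_ids)) next
    train_comp <- compendium(
      lapply(comp$layers, function(m)
        m[, intersect(colnames(m), f$train), drop = FALSE]),
      comp$conditions[comp$conditions$profile_id %in% f$train, , drop = FALSE],
      growth = comp$growth[names(comp$growth) %in% f$train])
    fit <- fit_fun(train_comp)
    desc <- profile_condition(comp, test_ids[1])
    pred <- predict_fun(fit, desc, train_comp)
    bl <- lapply(setNames(baselines, baselines), function(k)
      tryCatch(baseline_predict(k, mat[, train_ids, drop = FALSE],
                                comp$conditions, seed = seed,
                                subset_size = subset_size),
               error = function(e) NULL))
    for (p in test_ids) {
      obs <- mat[, p]
      sub <- if (is.null(molecules)) names(obs) else molecules
      row <- data.frame(fold = f$key, profile = p,
                        model = suppressWarnings(
                          pcc(score_transform(pred[sub]),
                              score_transform(obs[sub]))))
      for (k in baselines)
        row[[k]] <- if (is.null(bl[[k]])) NA_real_ else
          suppressWarnings(pcc(score_transform(bl[[k]][sub]),
                               score_transform(obs[sub])))
      rows[[length(rows) + 1]] <- row
    }
  }
  per_profile <- do.call(rbind, rows)
  methods <- setdiff(names(per_profile), c("fold", "profile"))
  summary <- do.call(rbind, lapply(methods, function(m) {
    v <- per_profile[[m]]
    data.frame(method = m, mean_pcc = mean(v[is.finite(v)]),
               sd_pcc = sd(v[is.finite(v)]), n = sum(is.finite(v)),
               n_undefined = sum(!is.finite(v)))
  }))
  structure(list(per_profile = per_profile, summary = summary,
                 folds = folds, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", nrow(x$per_profile), "profiles over",
      length(x$folds), "folds\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Wilcoxon rank-sum comparison of two performance samples
#'
#' Thin wrapper around the exact two-sample Wilcoxon rank-sum test, used to
#' compare per-profile performance distributions between methods.
#'
#' @param x,y numeric samples (e.g. per-profile PCCs of two methods).
#' @param alternative passed to [stats::wilcox.test()].
#' @return list with `statistic` (W), `p_value`.
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided") {
  ht <- stats::wilcox.test(x, y, alternative = alternative, exact = TRUE,
                           correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
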
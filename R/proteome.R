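# Proteome layer: four network-conditioned LASSO modules (TRN, PPI, CPN,
# pathway membership) and their unweighted ensemble mean.  A module can only
# predict a protein whose neighbourhood in its network is non-empty, so each
# module has its own coverage; the ensemble covers the union.

#' Build the co-expressed protein network
#'
#' Undirected edges between all protein pairs whose Pearson correlation
#' across the core proteome profiles strictly exceeds `r_min`.
#'
#' @param core_profiles proteins x profiles matrix.
#' @param r_min correlation threshold (strict `>`).
#' @return a CPN [interaction_network()].
#' @export
build_cpn <- function(core_profiles, r_min = 0.7) {
  if (ncol(core_profiles) < 3) stop("build_cpn needs >= 3 profiles")
  if (nrow(core_profiles) < 2) stop("build_cpn needs >= 2 proteins")
  cc <- suppressWarnings(cor(t(core_profiles), use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  idx <- which(upper.tri(cc) & cc > r_min, arr.ind = TRUE)
  interaction_network("CPN", edges = data.frame(
    from = rownames(cc)[idx[, 1]], to = rownames(cc)[idx[, 2]],
    weight = cc[idx], stringsAsFactors = FALSE))
}

# Predictor id set of one target under one network kind.  id_map maps a
# protein id to its gene id (and back via names) where the module regresses
# on gene expression.
module_neighborhood <- function(network, target, id_map = NULL) {
  gene_of <- function(p) if (is.null(id_map)) p else unname(id_map[p])
  switch(network$kind,
    TRN = network_regulators(network, gene_of(target)),
    PPI = {
      nb <- network_neighbors(network, target)   # neighbour proteins
      if (is.null(id_map)) nb else unname(id_map[nb[nb %in% names(id_map)]])
    },
    pathway = network_neighbors(network, gene_of(target)),
    CPN = network_neighbors(network, target))
}

#' Train one network module's LASSO predictors
#'
#' Per target: LASSO regression of the target's level on the expression of
#' its neighbourhood in the given network, with lambda chosen by inner
#' cross-validation (one-standard-error rule).  Targets with an empty
#' neighbourhood are reported as uncovered by this module; constant targets
#' get an intercept-only predictor and are flagged.
#'
#' @param targets character vector of target ids (rows of `response`).
#' @param network an [interaction_network()] (TRN / PPI / CPN / pathway).
#' @param predictors molecules x profiles training matrix the neighbourhood
#'   ids index into (gene expression for TRN/PPI/pathway, protein levels for
#'   CPN).
#' @param response targets x profiles training matrix.
#' @param id_map named vector protein id -> gene id, for modules whose
#'   neighbourhood lives in gene space.
#' @param seed seed for the inner CV folds.
#' @param nfolds inner CV folds.
#' @return a `module_predictors` object: list with per-target `fits`,
#'   `coverage` (covered target ids) and `uncovered`.
#' @export
train_module_predictors <- function(targets, network, predictors, response,
                                    id_map = NULL, seed = 1, nfolds = 5) {
  fits <- list(); uncovered <- character(0)
  for (tg in targets) {
    nb <- intersect(module_neighborhood(network, tg, id_map),
                    setdiff(rownames(predictors), tg))
    if (!length(nb) || !tg %in% rownames(response)) {
      uncovered <- c(uncovered, tg)
      next
    }
    fits[[tg]] <- fit_lasso(t(predictors[nb, , drop = FALSE]),
                            response[tg, ], seed = seed, nfolds = nfolds)
    fits[[tg]]$neighborhood <- nb
  }
  structure(list(kind = network$kind, fits = fits,
                 coverage = names(fits), uncovered = uncovered,
                 id_map = id_map),
            class = "module_predictors")
}

#' @export
print.module_predictors <- function(x, ...) {
  cat("<module_predictors>", x$kind, "- covers", length(x$coverage),
      "targets,", length(x$uncovered), "uncovered\n")
  invisible(x)
}

#' Predict protein levels with one module
#'
#' @param module a [train_module_predictors()] result.
#' @param inputs named vector (or molecules x 1 matrix) of predictor levels.
#' @return named vector of predictions for the module's covered targets.
#' @export
predict_module <- function(module, inputs) {
  if (is.matrix(inputs)) inputs <- inputs[, 1]
  vapply(module$fits, predict_lasso, numeric(1), x = inputs)
}

#' Ensemble protein prediction
#'
#' The ensemble level of each target is the unweighted mean of the
#' predictions of the modules that cover it; coverage is the union of module
#' coverages.  Targets covered by no module are reported in `uncovered`,
#' never as a number.
#'
#' @param module_predictions named list (one entry per module) of named
#'   prediction vectors.
#' @param targets optional full target universe to report coverage against.
#' @return list with `values` (named vector over covered targets),
#'   `provenance` (list target -> contributing modules), `uncovered`.
#' @export
ensemble_predict <- function(module_predictions, targets = NULL) {
  covered <- sort(unique(unlist(lapply(module_predictions, names))))
  values <- vapply(covered, function(tg) {
    v <- vapply(module_predictions, function(mp)
      if (tg %in% names(mp)) mp[[tg]] else NA_real_, numeric(1))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  provenance <- lapply(setNames(covered, covered), function(tg)
    names(module_predictions)[vapply(module_predictions,
                                     function(mp) tg %in% names(mp),
                                     logical(1))])
  uncovered <- if (is.null(targets)) character(0) else setdiff(targets, covered)
  list(values = values, provenance = provenance, uncovered = uncovered)
}
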
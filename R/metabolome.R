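# Metabolome layer: l1-regularized prediction of metabolite levels.  Core
# metabolism is predicted from protein levels of known enzymes; metabolites
# without enzyme-substrate information are fit from all genes with LASSO
# variable selection.

#' Train metabolite predictors
#'
#' Per metabolite: if an enzyme mapping exists, a regression restricted to
#' the mapped enzymes; otherwise LASSO over all rows of the predictor matrix
#' (variable selection).  Lambda is chosen by inner cross-validation.
#'
#' @param metabolome metabolites x profiles training matrix.
#' @param predictors molecules x profiles training matrix (proteins for the
#'   core scope, transcripts for non-core), sharing >= 10 profiles with the
#'   metabolome.
#' @param enzyme_map named list metabolite -> enzyme/gene id vector, or
#'   `NULL` when no mapping is available.
#' @param scope `"core"` or `"noncore"`, recorded on each predictor.
#' @param metabolites subset to train (default all rows of `metabolome`).
#' @param seed,nfolds inner cross-validation controls.
#' @return list of `metabolite_predictor` objects keyed by metabolite.
#' @export
train_metabolite_predictors <- function(metabolome, predictors,
                                        enzyme_map = NULL,
                                        scope = c("noncore", "core"),
                                        metabolites = rownames(metabolome),
                                        seed = 1, nfolds = 5) {
  scope <- match.arg(scope)
  shared <- intersect(colnames(metabolome), colnames(predictors))
  if (length(shared) < 10)
    stop("need >= 10 shared profiles between metabolome and predictors, got ",
         length(shared))
  out <- list()
  for (m in metabolites) {
    if (!m %in% rownames(metabolome)) {
      warning("metabolite absent from training matrix, skipped: ", m)
      next
    }
    ids <- if (!is.null(enzyme_map) && m %in% names(enzyme_map))
      intersect(enzyme_map[[m]], rownames(predictors))
    else rownames(predictors)
    fit <- fit_lasso(t(predictors[ids, shared, drop = FALSE]),
                     metabolome[m, shared], seed = seed, nfolds = nfolds)
    fit$metabolite <- m
    fit$scope <- scope
    fit$mapped <- !is.null(enzyme_map) && m %in% names(enzyme_map)
    out[[m]] <- fit
  }
  out
}

#' Predict metabolite levels from layer outputs
#'
#' Core-scope predictors consume the proteome layer's output, non-core
#' predictors the transcriptome layer's; predictions are floored at zero
#' molecules per cell.  A metabolite whose support is not covered by the
#' supplied inputs is reported as uncovered, not as a number.
#'
#' @param predictor_list result of [train_metabolite_predictors()] (both
#'   scopes may be concatenated).
#' @param transcriptome named vector of gene-level inputs.
#' @param proteome named vector of protein-level inputs.
#' @param floor lower bound applied to predictions.
#' @return list with `values` (named vector) and `uncovered` (character).
#' @export
predict_metabolome <- function(predictor_list, transcriptome = NULL,
                               proteome = NULL, floor = 0) {
  values <- numeric(0); uncovered <- character(0)
  for (m in names(predictor_list)) {
    fit <- predictor_list[[m]]
    inp <- if (fit$scope == "core") proteome else transcriptome
    sup <- names(fit$coef)[fit$coef != 0]
    if (length(sup) && (is.null(inp) || !all(sup %in% names(inp)))) {
      uncovered <- c(uncovered, m)
      next
    }
    if (is.null(inp)) inp <- numeric(0)
    values[m] <- max(floor, predict_lasso(fit, inp[names(fit$coef)] |>
                                            setNames(names(fit$coef))))
  }
  list(values = values, uncovered = uncovered)
}
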
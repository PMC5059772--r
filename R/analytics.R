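# Analytics over a compendium: expression-effect ontologies (clustering
# strains/media/stresses by their effect on genome-wide expression) and
# functional-coverage-driven selection of new knockout experiments.

#' Mean expression-effect profile per condition group
#'
#' Groups profiles by strain, medium or stress, after an optional control
#' filter (e.g. restrict to one medium, no stress, no perturbation), and
#' returns the mean expression profile of each group.
#'
#' @param comp a [compendium()].
#' @param group_by `"strain"`, `"medium"` or `"stress"` (stress grouping uses
#'   profiles carrying exactly one stress).
#' @param layer layer to average.
#' @param control_filter `function(conditions_df) logical` selecting the
#'   profiles to use; default keeps everything.
#' @param min_profiles groups with fewer profiles are dropped with a message.
#' @return genes x groups matrix of group means.
#' @export
condition_effect_profiles <- function(comp,
                                      group_by = c("strain", "medium",
                                                   "stress"),
                                      layer = "transcript",
                                      control_filter = NULL,
                                      min_profiles = 1) {
  group_by <- match.arg(group_by)
  mat <- comp$layers[[layer]]
  cond <- comp$conditions[match(colnames(mat), comp$conditions$profile_id), ]
  keep <- if (is.null(control_filter)) rep(TRUE, nrow(cond))
          else control_filter(cond)
  cond <- cond[keep, , drop = FALSE]; mat <- mat[, keep, drop = FALSE]
  groups <- switch(group_by,
    strain = cond$strain, medium = cond$medium,
    stress = ifelse(grepl(";", cond$stresses) | cond$stresses == "",
                    NA, cond$stresses))
  ok <- !is.na(groups)
  groups <- groups[ok]; mat <- mat[, ok, drop = FALSE]
  if (!length(groups)) stop("no profiles survive the control filter")
  tab <- table(groups)
  small <- names(tab)[tab < min_profiles]
  if (length(small))
    message("dropping group(s) with < ", min_profiles, " profiles: ",
            paste(small, collapse = ", "))
  use <- setdiff(names(tab), small)
  if (length(use) < 2) stop("fewer than 2 groups survive filtering")
  out <- vapply(use, function(g)
    rowMeans(mat[, groups == g, drop = FALSE], na.rm = TRUE),
    numeric(nrow(mat)))
  rownames(out) <- rownames(mat)
  out
}

#' Build an expression-effect ontology
#'
#' Hierarchical agglomerative clustering (average linkage) of condition
#' groups with distance `1 - PCC` between group mean profiles.  Deterministic
#' given input order (ties resolved by \code{\link[stats]{hclust}}'s
#' first-pair rule).
#'
#' @param group_profiles genes x groups matrix (>= 3 groups).
#' @param method linkage, default `"average"` (`"complete"`/`"ward.D2"`
#'   available).
#' @return an [stats::hclust] tree with the groups as leaves.
#' @export
build_ontology <- function(group_profiles, method = "average") {
  if (ncol(group_profiles) < 3) stop("need >= 3 groups to build an ontology")
  sds <- apply(group_profiles, 2, sd, na.rm = TRUE)
  if (any(sds == 0))
    stop("constant group profile(s) — pairwise correlation undefined: ",
         paste(colnames(group_profiles)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - cor(group_profiles, use = "pairwise.complete.obs"))
  stats::hclust(d, method = method)
}

#' Cophenetic correlation between two trees
#'
#' Pearson correlation between the upper triangles of the two trees'
#' cophenetic distance matrices, aligned by leaf label.  Symmetric in its
#' arguments and invariant to consistent leaf relabeling.
#'
#' @param tree_a,tree_b [stats::hclust] or [ape] `phylo` trees over the same
#'   leaf set.
#' @return cophenetic correlation in [-1, 1].
#' @export
cophenetic_correlation <- function(tree_a, tree_b) {
  coph <- function(tr) {
    if (inherits(tr, "phylo")) as.matrix(ape::cophenetic.phylo(tr))
    else as.matrix(stats::cophenetic(tr))
  }
  A <- coph(tree_a); B <- coph(tree_b)
  la <- sort(rownames(A)); lb <- sort(rownames(B))
  if (!identical(la, lb))
    stop("leaf sets differ: ",
         paste(c(setdiff(la, lb), setdiff(lb, la)), collapse = ", "))
  A <- A[la, la]; B <- B[la, la]
  cor(A[upper.tri(A)], B[upper.tri(B)])
}

#' Export a tree as newick
#' @param tree an [stats::hclust] tree.
#' @param path output file.
#' @export
write_ontology_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Functional-term coverage of a perturbation set
#'
#' A term is represented when at least one gene annotated with it has been
#' perturbed.  Coverage is reported per namespace as the fraction of the
#' namespace's terms that are represented.
#'
#' @param perturbed_genes character vector of perturbed gene ids.
#' @param annotations data frame with columns `gene`, `namespace`, `term`.
#' @return named numeric vector of coverage fractions per namespace.
#' @export
go_coverage <- function(perturbed_genes, annotations) {
  stopifnot(all(c("gene", "namespace", "term") %in% names(annotations)))
  if (!nrow(annotations)) stop("empty annotation map")
  unannotated <- setdiff(perturbed_genes, annotations$gene)
  if (length(unannotated))
    message("perturbed gene(s) without annotation (count toward nothing): ",
            paste(unannotated, collapse = ", "))
  vapply(split(annotations, annotations$namespace), function(a) {
    terms_all <- unique(a$term)
    covered <- unique(a$term[a$gene %in% perturbed_genes])
    length(covered) / length(terms_all)
  }, numeric(1))
}

#' Rank knockout candidates by marginal coverage gain
#'
#' Greedy selection: repeatedly pick the gene whose perturbation would
#' represent the largest number of currently-unrepresented terms (all
#' namespaces pooled); ties are broken by gene order of first appearance in
#' the annotation map.  Stops early when no gene adds coverage.
#'
#' @param annotations data frame with `gene`, `namespace`, `term`.
#' @param current_perturbed genes already perturbed in the compendium.
#' @param k number of knockouts requested.
#' @return data frame with `gene` and `gain` (newly covered terms), at most
#'   `k` rows (shorter with a message when fewer genes have positive gain).
#' @export
rank_knockouts_by_coverage_gain <- function(annotations, current_perturbed,
                                            k) {
  if (k < 1) stop("k must be >= 1")
  key <- paste(annotations$namespace, annotations$term, sep = "\r")
  gene_terms <- split(key, annotations$gene)
  gene_terms <- lapply(gene_terms, unique)
  registry_order <- unique(annotations$gene)
  covered <- unique(unlist(gene_terms[intersect(current_perturbed,
                                                names(gene_terms))]))
  picks <- data.frame(gene = character(0), gain = integer(0))
  candidates <- setdiff(registry_order, current_perturbed)
  for (i in seq_len(k)) {
    gains <- vapply(candidates, function(g)
      length(setdiff(gene_terms[[g]], covered)), integer(1))
    if (!length(gains) || max(gains) == 0) {
      if (i == 1 || nrow(picks) < k)
        message("only ", nrow(picks), " gene(s) with positive coverage gain")
      break
    }
    best <- candidates[which.max(gains)]   # first max = registry order
    picks <- rbind(picks, data.frame(gene = best,
                                     gain = max(gains)))
    covered <- union(covered, gene_terms[[best]])
    candidates <- setdiff(candidates, best)
  }
  picks
}
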
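#' @importFrom stats sd cor median quantile rnorm runif rbinom dnorm predict loess
#'   loess.control setNames approx cophenetic hclust as.dist var cov
#' @importFrom utils head tail read.delim write.table count.fields
NULL

LAYERS <- c("transcript", "protein", "metabolite", "flux")

#' Molecule registry for one omics layer
#'
#' An ordered, unique set of molecule identifiers for a single layer
#' (transcripts, proteins, metabolites or fluxes).  All profile vectors of
#' that layer are aligned to the registry order, which is stable across
#' save/load.
#'
#' @param layer one of `"transcript"`, `"protein"`, `"metabolite"`, `"flux"`.
#' @param ids character vector of molecule identifiers, unique within the layer.
#' @return an object of class `molecule_registry`.
#' @export
molecule_registry <- function(layer, ids) {
  layer <- match.arg(layer, LAYERS)
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate molecule ids in ", layer, " registry: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(layer = layer, ids = ids), class = "molecule_registry")
}

#' @export
length.molecule_registry <- function(x) length(x$ids)

#' @export
print.molecule_registry <- function(x, ...) {
  cat("<molecule_registry>", x$layer, "with", length(x$ids), "ids\n")
  invisible(x)
}

#' Describe an experimental condition
#'
#' A condition is the tuple (strain, medium, stress set, perturbation set).
#' Growth phase is carried as metadata but excluded from condition identity,
#' so that leave-one-condition-out folds group replicates and phases together.
#'
#' @param strain strain identifier.
#' @param medium medium identifier.
#' @param stresses character vector of stress identifiers (a set; order ignored).
#' @param perturbations character vector of `"gene:type"` entries with type
#'   `knockout` or `overexpression`, e.g. `"lacZ:knockout"`.
#' @param phase `"exponential"`, `"stationary"` or `"unknown"`.
#' @return an object of class `condition_descriptor`.
#' @export
condition_descriptor <- function(strain, medium, stresses = character(0),
                                 perturbations = character(0),
                                 phase = "unknown") {
  phase <- match.arg(phase, c("exponential", "stationary", "unknown"))
  perturbations <- as.character(perturbations)
  if (length(perturbations)) {
    ok <- grepl("^[^:]+:(knockout|overexpression)$", perturbations)
    if (!all(ok))
      stop("malformed perturbation(s): ",
           paste(perturbations[!ok], collapse = ", "),
           " (expected 'gene:knockout' or 'gene:overexpression')")
  }
  structure(list(strain = as.character(strain), medium = as.character(medium),
                 stresses = sort(unique(as.character(stresses))),
                 perturbations = sort(unique(perturbations)),
                 phase = phase),
            class = "condition_descriptor")
}

#' Canonical identity key of a condition
#'
#' Equal keys identify equal conditions; phase and replicate never enter the key.
#'
#' @param desc a [condition_descriptor()] or a row-wise conditions data frame.
#' @return character key(s).
#' @export
condition_key <- function(desc) {
  if (inherits(desc, "condition_descriptor")) {
    paste(desc$strain, desc$medium,
          paste(desc$stresses, collapse = ";"),
          paste(desc$perturbations, collapse = ";"), sep = "|")
  } else if (is.data.frame(desc)) {
    canon <- function(s) vapply(strsplit(ifelse(is.na(s) | s == "", "", s), ";",
                                         fixed = TRUE),
                                function(v) paste(sort(unique(v)), collapse = ";"),
                                character(1))
    paste(desc$strain, desc$medium, canon(desc$stresses),
          canon(desc$perturbations), sep = "|")
  } else stop("condition_key: unsupported input")
}

#' @export
print.condition_descriptor <- function(x, ...) {
  cat("<condition>", condition_key(x), "phase:", x$phase, "\n")
  invisible(x)
}

#' Feature registry for condition encoding
#'
#' Defines the fixed-order feature space that [encode_condition()] maps a
#' condition into: a genetic block (strain indicators), an
#' experimental-setting block (stress indicators), a medium block (real-valued
#' nutrient composition when a composition table is given, otherwise medium
#' indicators) and a perturbation block (gene-by-type indicators).
#'
#' @param strains,media,stresses,perturbations character vectors enumerating
#'   the training vocabulary of each attribute.  `perturbations` entries use
#'   the `"gene:type"` form.
#' @param medium_composition optional numeric matrix (media x nutrients,
#'   rownames = media) of nutrient concentrations; when provided the medium
#'   block encodes composition instead of identity.
#' @return an object of class `feature_registry` with a `$features` name vector.
#' @export
feature_registry <- function(strains, media, stresses = character(0),
                             perturbations = character(0),
                             medium_composition = NULL) {
  strains <- unique(as.character(strains)); media <- unique(as.character(media))
  stresses <- unique(as.character(stresses))
  perturbations <- unique(as.character(perturbations))
  if (!is.null(medium_composition)) {
    medium_composition <- as.matrix(medium_composition)
    if (is.null(rownames(medium_composition)))
      stop("medium_composition must have media as rownames")
    missing_media <- setdiff(media, rownames(medium_composition))
    if (length(missing_media))
      stop("media without composition rows: ",
           paste(missing_media, collapse = ", "))
    medium_block <- paste0("nutrient:", colnames(medium_composition))
  } else {
    medium_block <- paste0("medium:", media)
  }
  features <- c(paste0("strain:", strains),
                paste0("stress:", stresses),
                medium_block,
                paste0("pert:", perturbations))
  structure(list(strains = strains, media = media, stresses = stresses,
                 perturbations = perturbations,
                 medium_composition = medium_composition,
                 features = features),
            class = "feature_registry")
}

#' @export
length.feature_registry <- function(x) length(x$features)

#' Encode a condition into its feature vector
#'
#' Deterministic encoding of a condition descriptor into the fixed feature
#' space of a registry: one-hot blocks for strain, stresses and perturbations;
#' the medium encoded by its nutrient composition when the registry carries a
#' composition table, otherwise one-hot.  Any attribute value absent from the
#' registry raises an error — predictions are only defined for attribute
#' values seen in at least one training entry.
#'
#' @param descriptor a [condition_descriptor()].
#' @param registry a [feature_registry()].
#' @return named numeric vector of length `length(registry)`.
#' @export
encode_condition <- function(descriptor, registry) {
  stopifnot(inherits(descriptor, "condition_descriptor"),
            inherits(registry, "feature_registry"))
  bad <- function(kind, vals) {
    stop("attribute not in training vocabulary (", kind, "): ",
         paste(vals, collapse = ", "), call. = FALSE)
  }
  if (!descriptor$strain %in% registry$strains) bad("strain", descriptor$strain)
  if (!descriptor$medium %in% registry$media) bad("medium", descriptor$medium)
  unk <- setdiff(descriptor$stresses, registry$stresses)
  if (length(unk)) bad("stress", unk)
  unk <- setdiff(descriptor$perturbations, registry$perturbations)
  if (length(unk)) bad("perturbation", unk)

  x <- setNames(numeric(length(registry$features)), registry$features)
  x[paste0("strain:", descriptor$strain)] <- 1
  if (length(descriptor$stresses))
    x[paste0("stress:", descriptor$stresses)] <- 1
  if (is.null(registry$medium_composition)) {
    x[paste0("medium:", descriptor$medium)] <- 1
  } else {
    comp <- registry$medium_composition[descriptor$medium, ]
    x[paste0("nutrient:", colnames(registry$medium_composition))] <- comp
  }
  if (length(descriptor$perturbations))
    x[paste0("pert:", descriptor$perturbations)] <- 1
  x
}

#' Assemble a multi-omics compendium
#'
#' A compendium bundles per-layer profile matrices (molecules x profiles,
#' `NA` marking unobserved entries), a condition table with one row per
#' profile, and optional per-profile growth rates.
#'
#' @param layers named list of numeric matrices, names among
#'   `transcript`, `protein`, `metabolite`, `flux`; rows are molecules
#'   (rownames required), columns are profile ids (colnames required).
#' @param conditions data frame with columns `profile_id`, `layer`,
#'   `platform`, `strain`, `medium`, `stresses`, `perturbations`, `phase`,
#'   `replicate` (stress/perturbation sets semicolon-joined).
#' @param growth optional named numeric vector of growth rates (1/h) keyed by
#'   profile id.
#' @return an object of class `compendium`.
#' @export
compendium <- function(layers, conditions, growth = NULL) {
  stopifnot(is.list(layers), is.data.frame(conditions))
  if (!all(names(layers) %in% LAYERS))
    stop("unknown layer name(s): ",
         paste(setdiff(names(layers), LAYERS), collapse = ", "))
  need <- c("profile_id", "layer", "platform", "strain", "medium",
            "stresses", "perturbations", "phase", "replicate")
  miss <- setdiff(need, names(conditions))
  if (length(miss)) stop("conditions table lacks column(s): ",
                         paste(miss, collapse = ", "))
  conditions$profile_id <- as.character(conditions$profile_id)
  for (ly in names(layers)) {
    m <- layers[[ly]]
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop("layer '", ly, "' matrix needs molecule rownames and profile colnames")
    if (anyDuplicated(rownames(m)))
      stop("layer '", ly, "' has duplicated molecule ids")
    unknown <- setdiff(colnames(m), conditions$profile_id)
    if (length(unknown))
      stop("layer '", ly, "' profiles missing from condition table: ",
           paste(head(unknown, 5), collapse = ", "))
  }
  if (!is.null(growth)) {
    if (is.null(names(growth))) stop("growth must be named by profile id")
    growth <- growth[!is.na(growth)]
  }
  structure(list(layers = layers, conditions = conditions, growth = growth),
            class = "compendium")
}

#' @export
print.compendium <- function(x, ...) {
  cat("<compendium>\n")
  for (ly in names(x$layers))
    cat(sprintf("  %-10s %4d molecules x %4d profiles (%.1f%% missing)\n",
                ly, nrow(x$layers[[ly]]), ncol(x$layers[[ly]]),
                100 * mean(is.na(x$layers[[ly]]))))
  cat("  conditions:", length(unique(condition_key(x$conditions))),
      "unique over", nrow(x$conditions), "profiles\n")
  if (!is.null(x$growth)) cat("  growth rates for", length(x$growth), "profiles\n")
  invisible(x)
}

#' Condition descriptor of a profile
#'
#' @param comp a [compendium()].
#' @param profile_id a profile id present in the condition table.
#' @return a [condition_descriptor()].
#' @export
profile_condition <- function(comp, profile_id) {
  row <- comp$conditions[comp$conditions$profile_id == profile_id, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown profile id: ", profile_id)
  row <- row[1, ]
  split_set <- function(s) if (is.na(s) || s == "") character(0)
                           else strsplit(s, ";", fixed = TRUE)[[1]]
  condition_descriptor(row$strain, row$medium, split_set(row$stresses),
                       split_set(row$perturbations),
                       if (row$phase %in% c("exponential", "stationary"))
                         row$phase else "unknown")
}

#' Build the condition-encoding vocabulary observed in a compendium
#'
#' @param comp a [compendium()].
#' @param medium_composition optional media x nutrients matrix, passed through
#'   to [feature_registry()].
#' @return a [feature_registry()] spanning all attribute values in the table.
#' @export
compendium_feature_registry <- function(comp, medium_composition = NULL) {
  cond <- comp$conditions
  split_all <- function(s) unique(unlist(strsplit(s[!is.na(s) & s != ""],
                                                  ";", fixed = TRUE)))
  feature_registry(strains = unique(cond$strain), media = unique(cond$medium),
                   stresses = split_all(cond$stresses),
                   perturbations = split_all(cond$perturbations),
                   medium_composition = medium_composition)
}
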
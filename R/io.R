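# TSV / JSON plumbing.  Dialect: tab-separated, UTF-8, "NA" for missing,
# molecule ids in the first column, profile ids in the header.

#' Read an expression/abundance matrix from TSV
#'
#' @param path TSV file: first column molecule ids, remaining columns one per
#'   profile; blank or `NA` cells mark missing values.
#' @param layer layer name recorded in the returned registry.
#' @return list with `values` (numeric matrix, `NA` = missing) and
#'   `registry` (a [molecule_registry()]).
#' @export
read_expression_matrix <- function(path, layer = "transcript") {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "",
                     blank.lines.skip = FALSE)
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged TSV '", path, "': line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), quote = "", comment.char = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate molecule id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  list(values = values, registry = molecule_registry(layer, ids))
}

#' Write an expression/abundance matrix to TSV
#'
#' Finite values are printed with 17 significant digits so that a
#' write-then-read round trip reproduces them bit-identically.
#'
#' @param values numeric matrix with molecule rownames and profile colnames.
#' @param path output file.
#' @export
write_expression_matrix <- function(values, path) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  chr <- matrix("NA", nrow(values), ncol(values))
  fin <- !is.na(values)
  chr[fin] <- formatC(values[fin], digits = 17, format = "g")
  out <- cbind(id = rownames(values), chr)
  colnames(out) <- c("id", colnames(values))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a profile condition table from TSV
#'
#' One row per profile with columns `profile_id`, `layer`, `platform`,
#' `strain`, `medium`, `stresses`, `perturbations`, `phase`, `replicate`;
#' stress and perturbation sets are semicolon-joined.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_condition_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "NA", quote = "", comment.char = "")
  df$profile_id <- as.character(df$profile_id)
  for (col in c("stresses", "perturbations"))
    if (col %in% names(df)) df[[col]][is.na(df[[col]])] <- ""
  df
}

#' Write a profile condition table to TSV
#'
#' @param conditions data frame as in [read_condition_table()].
#' @param path output file.
#' @export
write_condition_table <- function(conditions, path) {
  write.table(conditions, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an interaction network or pathway membership file
#'
#' Edge-list TSV (`from`, `to`, optional `weight`) for TRN/PPI/CPN kinds, or a
#' two-column membership TSV (`pathway`, `gene`) for the pathway kind.
#'
#' @param path TSV file without header.
#' @param kind `"TRN"` (directed), `"PPI"`, `"CPN"` (undirected) or `"pathway"`.
#' @return an [interaction_network()].
#' @export
read_network <- function(path, kind = c("TRN", "PPI", "CPN", "pathway")) {
  kind <- match.arg(kind)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (any(nf < 2))
    stop("malformed network line ", which(nf < 2)[1], " in '", path,
         "': fewer than 2 fields")
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  if (kind == "pathway") {
    memberships <- split(as.character(df[[2]]), as.character(df[[1]]))
    memberships <- lapply(memberships, unique)
    interaction_network(kind, memberships = memberships)
  } else {
    edges <- data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]),
                        weight = if (ncol(df) >= 3) as.numeric(df[[3]]) else NA_real_,
                        stringsAsFactors = FALSE)
    interaction_network(kind, edges = edges)
  }
}

#' Read a metabolic model from JSON
#'
#' Expected schema: `reactions` is an array of objects with `id`,
#' `stoichiometry` (map metabolite -> coefficient), `lb`, `ub`, optional
#' `gpr` (string like `"(g1 and g2) or g3"`); top-level `objective` and
#' `glucose_exchange` give reaction ids.
#'
#' @param path JSON file.
#' @return a [metabolic_model()].
#' @export
read_metabolic_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  rxn_ids <- vapply(j$reactions, `[[`, character(1), "id")
  mets <- unique(unlist(lapply(j$reactions, function(r) names(r$stoichiometry))))
  S <- matrix(0, length(mets), length(rxn_ids), dimnames = list(mets, rxn_ids))
  for (r in j$reactions)
    for (m in names(r$stoichiometry))
      S[m, r$id] <- as.numeric(r$stoichiometry[[m]])
  gpr <- setNames(vapply(j$reactions,
                         function(r) if (is.null(r$gpr)) NA_character_
                                     else as.character(r$gpr),
                         character(1)), rxn_ids)
  metabolic_model(reactions = rxn_ids, metabolites = mets, S = S,
                  lb = setNames(vapply(j$reactions, function(r) as.numeric(r$lb),
                                       numeric(1)), rxn_ids),
                  ub = setNames(vapply(j$reactions, function(r) as.numeric(r$ub),
                                       numeric(1)), rxn_ids),
                  gpr = gpr, objective = j$objective,
                  glucose_exchange = j$glucose_exchange)
}

#' Write a metabolic model to JSON
#'
#' @param model a [metabolic_model()].
#' @param path output file.
#' @export
write_metabolic_model <- function(model, path) {
  rxns <- lapply(model$reactions, function(r) {
    sto <- model$S[, r]
    sto <- sto[sto != 0]
    out <- list(id = r, stoichiometry = as.list(sto),
                lb = model$lb[[r]], ub = model$ub[[r]])
    if (!is.na(model$gpr[[r]])) out$gpr <- model$gpr[[r]]
    out
  })
  jsonlite::write_json(list(reactions = rxns, objective = model$objective,
                            glucose_exchange = model$glucose_exchange),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
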
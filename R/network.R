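# Typed interaction networks: directed TRN, undirected PPI/CPN, pathway sets.

#' Construct a typed interaction network
#'
#' TRN edges are directed (regulator -> target); PPI and CPN edges are
#' undirected, stored once and queried symmetrically; the pathway kind holds
#' pathway -> gene membership sets instead of edges.  Self-loops in CPN are
#' dropped with a warning (a protein is trivially co-expressed with itself).
#'
#' @param kind `"TRN"`, `"PPI"`, `"CPN"` or `"pathway"`.
#' @param edges data frame with columns `from`, `to` and optionally `weight`.
#' @param memberships named list of gene-id vectors (pathway kind only).
#' @return an object of class `interaction_network`.
#' @export
interaction_network <- function(kind = c("TRN", "PPI", "CPN", "pathway"),
                                edges = NULL, memberships = NULL) {
  kind <- match.arg(kind)
  directed <- kind == "TRN"
  if (kind == "pathway") {
    if (is.null(memberships)) memberships <- list()
    stopifnot(is.list(memberships))
    edges <- NULL
  } else {
    if (is.null(edges))
      edges <- data.frame(from = character(0), to = character(0),
                          weight = numeric(0))
    edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
    if (is.null(edges$weight)) edges$weight <- NA_real_
    if (kind == "CPN" && any(self <- edges$from == edges$to)) {
      warning("dropping ", sum(self), " self-loop(s) in CPN")
      edges <- edges[!self, , drop = FALSE]
    }
    if (!directed && nrow(edges)) {
      a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
      keep <- !duplicated(paste(a, b, sep = "\r"))
      edges <- data.frame(from = a[keep], to = b[keep],
                          weight = edges$weight[keep],
                          stringsAsFactors = FALSE)
    } else if (nrow(edges)) {
      keep <- !duplicated(paste(edges$from, edges$to, sep = "\r"))
      edges <- edges[keep, , drop = FALSE]
    }
    rownames(edges) <- NULL
  }
  structure(list(kind = kind, directed = directed, edges = edges,
                 memberships = memberships),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  if (x$kind == "pathway")
    cat("<interaction_network> pathway:", length(x$memberships), "pathways\n")
  else
    cat("<interaction_network>", x$kind, if (x$directed) "(directed)"
        else "(undirected)", "with", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Neighbourhood of a node
#'
#' For undirected kinds, the symmetric neighbour set; for TRN, the union of
#' regulators and targets; for the pathway kind, all genes sharing at least
#' one pathway with the query gene (the query itself excluded).
#'
#' @param net an [interaction_network()].
#' @param node node identifier.
#' @return character vector of neighbour ids (may be empty).
#' @export
network_neighbors <- function(net, node) {
  if (net$kind == "pathway") {
    in_pw <- vapply(net$memberships, function(g) node %in% g, logical(1))
    return(setdiff(sort(unique(unlist(net$memberships[in_pw]))), node))
  }
  e <- net$edges
  sort(unique(c(e$to[e$from == node], e$from[e$to == node])))
}

#' Regulators of a target gene (TRN)
#' @param net a TRN [interaction_network()].
#' @param gene target gene id.
#' @return character vector of regulator ids.
#' @export
network_regulators <- function(net, gene) {
  stopifnot(net$kind == "TRN")
  sort(unique(net$edges$from[net$edges$to == gene]))
}

#' Targets of a regulator (TRN)
#' @param net a TRN [interaction_network()].
#' @param tf regulator gene id.
#' @return character vector of target ids.
#' @export
network_targets <- function(net, tf) {
  stopifnot(net$kind == "TRN")
  sort(unique(net$edges$to[net$edges$from == tf]))
}

#' Degree of a node
#' @param net an [interaction_network()].
#' @param node node identifier.
#' @return integer neighbour count.
#' @export
network_degree <- function(net, node) length(network_neighbors(net, node))
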
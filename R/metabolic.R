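# Stoichiometric model container and gene-reaction rule parsing.

#' Construct a stoichiometric metabolic model
#'
#' @param reactions character vector of reaction ids.
#' @param metabolites character vector of metabolite ids.
#' @param S stoichiometric matrix (metabolite x reaction).
#' @param lb,ub named numeric flux bounds per reaction, `lb <= ub`.
#' @param gpr named character vector of gene-reaction rules
#'   (`"g1 and g2 or g3"`, parentheses allowed; `NA` = no rule).
#' @param objective reaction id whose flux is maximized.
#' @param glucose_exchange id of the glucose exchange reaction (used for flux
#'   normalization).
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, metabolites, S, lb, ub, gpr = NULL,
                            objective, glucose_exchange) {
  reactions <- as.character(reactions); metabolites <- as.character(metabolites)
  S <- as.matrix(S)
  if (ncol(S) != length(reactions))
    stop("S must have one column per reaction")
  if (nrow(S) != length(metabolites))
    stop("S must have one row per metabolite")
  dimnames(S) <- list(metabolites, reactions)
  lb <- setNames(as.numeric(lb[reactions]), reactions)
  ub <- setNames(as.numeric(ub[reactions]), reactions)
  if (any(is.na(lb)) || any(is.na(ub)))
    stop("bounds must be provided for every reaction")
  if (any(lb > ub)) stop("lb > ub for reaction(s): ",
                         paste(reactions[lb > ub], collapse = ", "))
  if (is.null(gpr)) gpr <- setNames(rep(NA_character_, length(reactions)),
                                    reactions)
  gpr <- setNames(as.character(gpr[reactions]), reactions)
  if (!objective %in% reactions) stop("objective reaction not in model")
  if (!glucose_exchange %in% reactions)
    stop("glucose_exchange reaction not in model")
  structure(list(reactions = reactions, metabolites = metabolites, S = S,
                 lb = lb, ub = ub, gpr = gpr, objective = objective,
                 glucose_exchange = glucose_exchange),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", length(x$reactions), "reactions,",
      length(x$metabolites), "metabolites; objective:", x$objective, "\n")
  invisible(x)
}

#' Parse a gene-reaction rule into disjunctive normal form
#'
#' `and` binds tighter than `or`; parentheses override.  The result is a list
#' of enzyme complexes, each a character vector of gene ids: the reaction can
#' be catalysed if all genes of at least one complex are available.
#'
#' @param rule rule string, e.g. `"(g1 and g2) or g3"`.
#' @return list of character vectors (complexes); empty list for `NA`/empty rule.
#' @export
parse_gpr <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(list())
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^\\s()]+", rule, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    terms <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); terms <- c(terms, list(parse_and()))
    }
    unlist(terms, recursive = FALSE)          # union of complex lists
  }
  parse_and <- function() {
    res <- parse_atom()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); rhs <- parse_atom()
      # cartesian AND of two DNF complex lists
      res <- unlist(lapply(res, function(a)
        lapply(rhs, function(b) sort(unique(c(a, b))))), recursive = FALSE)
    }
    res
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("malformed gene-reaction rule: ", rule)
    if (t == "(") {
      inner <- parse_or()
      if (is.na(peek()) || take() != ")")
        stop("unbalanced parentheses in rule: ", rule)
      return(inner)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed gene-reaction rule: ", rule)
    list(t)
  }
  out <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens in rule: ", rule)
  lapply(out, function(cx) sort(unique(as.character(cx))))
}
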
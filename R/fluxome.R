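# Flux prediction: FBA with reaction bounds capped by enzyme expression.
# A reaction's activity follows standard gene-reaction-rule semantics
# (complex = min over subunits, isozymes = max over alternatives); bounds are
# shrunk proportionally when activity falls below the calibrated threshold.

#' Reaction activities from gene/protein expression
#'
#' For every reaction with a gene-reaction rule, activity is the max over
#' isozyme alternatives of the min over complex subunits of the expression
#' levels.  Genes referenced by a rule but absent from `expression` are
#' treated as absent (level 0) with a warning.
#'
#' @param expression named nonnegative vector of gene (or protein) levels.
#' @param gpr named character vector of rules per reaction (`NA` = no rule).
#' @return named numeric vector of activities for reactions with a rule.
#' @export
expression_to_activity <- function(expression, gpr) {
  if (any(expression < 0, na.rm = TRUE))
    stop("expression levels must be nonnegative")
  rules <- gpr[!is.na(gpr)]
  missing_seen <- character(0)
  act <- vapply(rules, function(rule) {
    complexes <- parse_gpr(rule)
    if (!length(complexes)) return(NA_real_)
    vals <- vapply(complexes, function(cx) {
      lev <- expression[cx]
      if (anyNA(lev)) {
        missing_seen <<- union(missing_seen, cx[is.na(lev)])
        lev[is.na(lev)] <- 0
      }
      min(lev)
    }, numeric(1))
    max(vals)
  }, numeric(1))
  if (length(missing_seen))
    warning("gene(s) in gene-reaction rules absent from expression, ",
            "treated as absent: ", paste(missing_seen, collapse = ", "))
  act[!is.na(act)]
}

#' Cap reaction bounds by expression activity and medium composition
#'
#' For each reaction with activity `l`, the feasible interval is shrunk
#' toward zero by `s = min(1, l / t)`: `lb' = s * lb`, `ub' = s * ub`.  A
#' fully unexpressed reaction (`l = 0`) is blocked; a reaction at or above
#' the threshold keeps its bounds.  When a medium composition is supplied,
#' exchange reactions (single-metabolite columns) of absent nutrients have
#' their uptake direction closed.
#'
#' @param model a [metabolic_model()].
#' @param activities named activity vector from [expression_to_activity()].
#' @param t activity threshold (> 0).
#' @param medium optional character vector of metabolite ids present in the
#'   medium.
#' @return the bounded [metabolic_model()].
#' @export
constrain_bounds <- function(model, activities, t, medium = NULL) {
  if (t <= 0) stop("threshold t must be > 0")
  lb <- model$lb; ub <- model$ub
  for (r in intersect(names(activities), model$reactions)) {
    s <- min(1, activities[[r]] / t)
    lb[r] <- s * lb[r]; ub[r] <- s * ub[r]
  }
  if (!is.null(medium)) {
    n_sub <- colSums(model$S != 0)
    for (r in model$reactions[n_sub == 1]) {
      m <- rownames(model$S)[model$S[, r] != 0]
      if (!m %in% medium) {
        if (model$S[m, r] > 0) ub[r] <- min(ub[r], 0)   # import blocked
        else lb[r] <- max(lb[r], 0)
      }
    }
  }
  model$lb <- lb; model$ub <- ub
  model
}

#' Solve flux balance analysis
#'
#' Maximizes the objective reaction's flux subject to steady state
#' (`S v = 0`) and flux bounds, by the simplex method (variables are shifted
#' by their lower bounds so negative bounds are supported).
#'
#' @param model a [metabolic_model()].
#' @param normalize_glucose if `TRUE`, the returned flux vector is divided by
#'   the glucose-exchange flux (see [normalize_fluxome()]).
#' @param big replacement for infinite bounds.
#' @return list with `fluxes` (named), `objective`, `status`
#'   (`"optimal"`, `"infeasible"` or `"maxiter"`).
#' @export
solve_fba <- function(model, normalize_glucose = FALSE, big = 1e6) {
  lb <- pmax(model$lb, -big); ub <- pmin(model$ub, big)
  if (any(lb > ub)) {
    return(list(fluxes = setNames(rep(NA_real_, length(lb)), model$reactions),
                objective = NA_real_, status = "infeasible"))
  }
  n <- length(model$reactions)
  cc <- numeric(n); cc[match(model$objective, model$reactions)] <- 1
  S <- model$S
  # eliminate variables fixed by their bounds (the simplex implementation
  # cannot handle zero-width bound rows)
  fixed <- (ub - lb) < 1e-12
  free <- which(!fixed)
  rhs <- as.numeric(-S %*% lb)
  v <- lb
  if (!length(free)) {
    if (max(abs(S %*% lb)) > 1e-9)
      return(list(fluxes = setNames(rep(NA_real_, n), model$reactions),
                  objective = NA_real_, status = "infeasible"))
  } else {
    Sf <- S[, free, drop = FALSE]
    keep <- rowSums(Sf != 0) > 0
    if (any(!keep) && max(abs(rhs[!keep])) > 1e-9)
      return(list(fluxes = setNames(rep(NA_real_, n), model$reactions),
                  objective = NA_real_, status = "infeasible"))
    A3 <- Sf[keep, , drop = FALSE]; b3 <- rhs[keep]
    # the simplex implementation needs nonnegative rhs and at least one
    # positive coefficient per equality row; equalities may be re-oriented
    for (i in seq_along(b3)) {
      if (b3[i] < 0 || (b3[i] == 0 && max(A3[i, ]) <= 0)) {
        A3[i, ] <- -A3[i, ]; b3[i] <- -b3[i]
      }
      if (b3[i] > 0 && max(A3[i, ]) <= 0)
        return(list(fluxes = setNames(rep(NA_real_, n), model$reactions),
                    objective = NA_real_, status = "infeasible"))
    }
    sol <- boot::simplex(a = cc[free], A1 = diag(length(free)),
                         b1 = (ub - lb)[free],
                         A3 = A3, b3 = b3,
                         maxi = TRUE, eps = 1e-10)
    status <- c("infeasible", "maxiter", "optimal")[sol$solved + 2]
    if (status != "optimal")
      return(list(fluxes = setNames(rep(NA_real_, n), model$reactions),
                  objective = NA_real_, status = status))
    v[free] <- as.numeric(sol$soln) + lb[free]
  }
  names(v) <- model$reactions
  objective <- sum(cc * v)
  if (normalize_glucose) v <- normalize_fluxome(v, model$glucose_exchange)
  list(fluxes = v, objective = objective, status = "optimal")
}

#' Calibrate the activity threshold on measured fluxes
#'
#' For each candidate threshold, predicts fluxes for every training condition
#' by expression-capped FBA and scores the mean Pearson correlation against
#' the measured fluxes; returns the grid maximizer (ties -> smallest t).
#'
#' @param model a [metabolic_model()].
#' @param activities list (one per condition) of activity vectors.
#' @param measured matrix of measured fluxes (reactions x conditions).
#' @param t_grid candidate thresholds (> 0).
#' @param medium optional medium composition passed to [constrain_bounds()].
#' @return list with `t_star` and `scores` (mean PCC per grid point).
#' @export
calibrate_t <- function(model, activities, measured, t_grid, medium = NULL) {
  if (!length(t_grid)) stop("empty threshold grid")
  if (length(activities) < 2) stop("need >= 2 training conditions")
  t_grid <- sort(t_grid)
  rxns <- intersect(rownames(measured), model$reactions)
  scores <- vapply(t_grid, function(tt) {
    pccs <- vapply(seq_along(activities), function(i) {
      sol <- solve_fba(constrain_bounds(model, activities[[i]], tt, medium))
      if (sol$status != "optimal") return(NA_real_)
      pcc(sol$fluxes[rxns], measured[rxns, i])
    }, numeric(1))
    mean(pccs, na.rm = TRUE)
  }, numeric(1))
  list(t_star = t_grid[which.max(scores)], scores = setNames(scores, t_grid))
}
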
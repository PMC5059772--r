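# Shared fixture builders; everything is generated in code at test time.

# A small registry covering two strains/media, two stresses, one knockout.
tiny_registry <- function() {
  feature_registry(strains = c("wt", "mut"), media = c("M9", "LB"),
                   stresses = c("heat", "acid"),
                   perturbations = c("gA:knockout"))
}

# Random expression matrix with molecule/profile names.
rand_matrix <- function(n_mol, n_prof, mean = 5, sd = 1, prefix = "g",
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n_mol * n_prof, mean, sd), n_mol, n_prof,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(n_mol)),
                         sprintf("p%03d", seq_len(n_prof))))
}

# Minimal condition table for a matrix of profiles.
tiny_conditions <- function(profile_ids, strain = "wt", medium = "M9",
                            perturbations = "") {
  data.frame(profile_id = profile_ids, layer = "transcript",
             platform = "sim", strain = strain, medium = medium,
             stresses = "", perturbations = perturbations,
             phase = "exponential", replicate = 1,
             stringsAsFactors = FALSE)
}

# Three-reaction linear chain: uptake (cap 10) -> conversion (cap 5)
# -> biomass (uncapped).  Optimal biomass flux is 5 by hand.
chain_model <- function() {
  rx <- c("upt", "conv", "bio")
  metabolic_model(
    reactions = rx, metabolites = c("glc", "X"),
    S = matrix(c(1, -1, 0,
                 0, 1, -1), 2, 3, byrow = TRUE),
    lb = setNames(c(0, 0, 0), rx), ub = setNames(c(10, 5, 1e6), rx),
    gpr = setNames(c(NA, "gA and gB", NA), rx),
    objective = "bio", glucose_exchange = "upt")
}

# Independent LP oracle: all-inequality encoding solved by pracma::linprog.
lp_oracle <- function(model, big = 1e6) {
  lb <- pmax(model$lb, -big); ub <- pmin(model$ub, big)
  n <- length(lb)
  cc <- numeric(n); cc[match(model$objective, model$reactions)] <- 1
  # shift x = v - lb >= 0 (pracma assumes nonnegative variables)
  S <- model$S
  A <- rbind(S, -S, diag(n))
  b <- c(as.numeric(-S %*% lb), as.numeric(S %*% lb), ub - lb)
  sol <- pracma::linprog(cc = -cc, A = A, b = b, maxiter = 500)
  list(objective = sum(cc * (sol$x + lb)), fluxes = sol$x + lb)
}

# Brute-force kNN imputation oracle following the declared rules exactly.
impute_oracle <- function(mat, k = 3) {
  out <- mat
  for (g in seq_len(nrow(mat))) for (j in seq_len(ncol(mat))) {
    if (!is.na(mat[g, j])) next
    ds <- c()
    for (h in seq_len(nrow(mat))) {
      if (h == g || is.na(mat[h, j])) next
      co <- which(!is.na(mat[g, ]) & !is.na(mat[h, ]))
      if (!length(co)) next
      ds <- rbind(ds, c(h, sqrt(sum((mat[g, co] - mat[h, co])^2) / length(co))))
    }
    if (is.null(ds)) next
    ds <- ds[order(ds[, 2], ds[, 1]), , drop = FALSE]
    nb <- ds[seq_len(min(k, nrow(ds))), 1]
    out[g, j] <- mean(mat[nb, j])
  }
  out
}

# Exhaustive greedy oracle for coverage-driven knockout ranking.
greedy_oracle <- function(annotations, current, k) {
  key <- paste(annotations$namespace, annotations$term)
  terms_of <- lapply(split(key, annotations$gene), unique)
  order_of <- unique(annotations$gene)
  covered <- unique(unlist(terms_of[intersect(current, names(terms_of))]))
  picks <- character(0); gains <- integer(0)
  cands <- setdiff(order_of, current)
  for (i in seq_len(k)) {
    g_best <- NULL; best <- 0
    for (g in cands) {                       # first-in-order max
      gain <- length(setdiff(terms_of[[g]], covered))
      if (gain > best) { best <- gain; g_best <- g }
    }
    if (is.null(g_best)) break
    picks <- c(picks, g_best); gains <- c(gains, best)
    covered <- union(covered, terms_of[[g_best]])
    cands <- setdiff(cands, g_best)
  }
  data.frame(gene = picks, gain = gains)
}
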
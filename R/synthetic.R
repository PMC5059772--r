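# Ground-truth system generator: every downstream estimator in the package is
# exercised against data simulated from the generative structure it assumes
# (recurrent transcript dynamics on condition features, network-supported
# sparse linear maps for proteins/metabolites, expression-capped FBA fluxes,
# per-layer additive growth signal).

#' Generate a ground-truth multi-omics system
#'
#' Creates the fixed "biology" that [simulate_compendium()] samples from: a
#' recurrent transcript network whose regulatory graph contains feedback
#' cycles of length <= 2, protein and metabolite sparse linear maps whose
#' supports are embedded in the corresponding interaction networks, a toy
#' stoichiometric model with gene-reaction rules, and per-layer growth
#' weights.  Coefficient magnitudes are drawn uniformly from ±[0.5, 1.5]
#' (scaled by support size to keep responses bounded).  Deterministic given
#' `seed`.
#'
#' @param n_features dimension of the condition feature space.
#' @param n_genes,n_proteins,n_metabolites layer sizes
#'   (`n_genes >= n_proteins >= 1`).
#' @param sparsity probability that a gene enters a target's predictor set
#'   (in (0, 1)).
#' @param seed RNG seed.
#' @return an object of class `ground_truth_system`.
#' @export
generate_system <- function(n_features = 10, n_genes = 20, n_proteins = 10,
                            n_metabolites = 8, sparsity = 0.2, seed = 1) {
  if (n_genes < n_proteins || n_proteins < 1)
    stop("need n_genes >= n_proteins >= 1")
  if (n_features < 4 || n_genes < 2 || n_metabolites < 2)
    stop("degenerate system sizes")
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must be in (0, 1)")
  with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    prots <- paste0("P_", genes[seq_len(n_proteins)])
    mets <- sprintf("m%03d", seq_len(n_metabolites))

    # condition vocabulary filling the feature budget:
    # strains + media one-hot, the rest split between stresses and knockouts
    n_strain <- max(2, round(n_features * 0.2))
    n_medium <- max(2, round(n_features * 0.2))
    n_stress <- max(1, floor((n_features - n_strain - n_medium) / 2))
    n_pert <- n_features - n_strain - n_medium - n_stress
    registry <- feature_registry(
      strains = sprintf("st%02d", seq_len(n_strain)),
      media = sprintf("md%02d", seq_len(n_medium)),
      stresses = if (n_stress) sprintf("sx%02d", seq_len(n_stress)) else character(0),
      perturbations = if (n_pert) paste0(genes[seq_len(n_pert)], ":knockout")
                      else character(0))
    D <- length(registry)

    coef_mag <- function(k) (0.5 + runif(k)) * sign(runif(k) - 0.5)

    # input weights: dense enough that every gene responds to the condition
    w_x <- matrix(0, D, n_genes, dimnames = list(registry$features, genes))
    for (g in seq_len(n_genes)) {
      k <- max(2, rbinom(1, D, 0.5))
      idx <- sample.int(D, k)
      w_x[idx, g] <- coef_mag(k) * 2 / sqrt(k)
    }
    # recurrent weights on a TRN with 1- and 2-cycles among a TF subset
    tfs <- genes[seq_len(max(2, round(n_genes * 0.3)))]
    trn_edges <- do.call(rbind, lapply(genes, function(g) {
      regs <- tfs[runif(length(tfs)) < sparsity]
      if (!length(regs)) regs <- sample(tfs, 1)
      data.frame(from = regs, to = g, stringsAsFactors = FALSE)
    }))
    # guarantee feedback cycles of length <= 2
    trn_edges <- rbind(trn_edges,
                       data.frame(from = c(tfs[1], tfs[2], tfs[1]),
                                  to = c(tfs[2], tfs[1], tfs[1])))
    trn <- interaction_network("TRN", edges = trn_edges)
    w_y <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
    for (i in seq_len(nrow(trn$edges))) {
      e <- trn$edges[i, ]
      w_y[e$from, e$to] <- coef_mag(1) * 0.8
    }
    b <- runif(n_genes, -0.5, 0.5)
    lmin <- runif(n_genes, log(50), log(500))
    lmax <- lmin + runif(n_genes, 1.5, 3)
    scaler <- structure(list(log_min = setNames(lmin, genes),
                             log_max = setNames(lmax, genes),
                             lo = 0.05, hi = 0.95, genes = genes),
                        class = "expression_scaler")
    rnn_true <- rnn_model(w_x, w_y, b, n = 2, scaler = scaler)

    # protein layer: support drawn per gene with the stated sparsity
    protein_coefs <- lapply(setNames(prots, prots), function(p) {
      sup <- genes[runif(n_genes) < sparsity]
      if (!length(sup)) sup <- sample(genes, 1)
      list(support = sup,
           coef = setNames(coef_mag(length(sup)) / sqrt(length(sup)), sup),
           intercept = runif(1, log(100), log(1000)))
    })
    # embed supports in PPI (protein-protein) and TRN-style links, plus noise edges
    ppi_edges <- do.call(rbind, lapply(prots, function(p) {
      sup <- protein_coefs[[p]]$support
      partner <- paste0("P_", sup)
      partner <- partner[partner %in% prots & partner != p]
      if (!length(partner)) partner <- sample(setdiff(prots, p), 1)
      data.frame(from = p, to = partner, stringsAsFactors = FALSE)
    }))
    extra <- data.frame(from = sample(prots, max(2, n_proteins)),
                        to = sample(prots, max(2, n_proteins)))
    extra <- extra[extra$from != extra$to, , drop = FALSE]
    ppi <- interaction_network("PPI", edges = rbind(ppi_edges, extra))
    # pathways: random overlapping gene sets
    n_pw <- max(2, round(n_genes / 6))
    pathways <- interaction_network("pathway", memberships = setNames(
      lapply(seq_len(n_pw), function(i) sample(genes, max(3, rbinom(1, n_genes, 0.3)))),
      sprintf("pw%02d", seq_len(n_pw))))

    # metabolite layer: first half "core" (protein-driven), rest gene-driven
    n_core <- floor(n_metabolites / 2)
    metabolite_coefs <- lapply(seq_len(n_metabolites), function(j) {
      if (j <= n_core) {
        sup <- prots[runif(n_proteins) < max(sparsity, 2 / n_proteins)]
        if (!length(sup)) sup <- sample(prots, 1)
        list(scope = "core", support = sup,
             coef = setNames(coef_mag(length(sup)) / (2 * sqrt(length(sup))), sup),
             intercept = runif(1, log(1e4), log(1e5)))
      } else {
        sup <- genes[runif(n_genes) < sparsity]
        if (!length(sup)) sup <- sample(genes, 1)
        list(scope = "noncore", support = sup,
             coef = setNames(coef_mag(length(sup)) / sqrt(length(sup)), sup),
             intercept = runif(1, log(1e4), log(1e5)))
      }
    })
    names(metabolite_coefs) <- mets
    enzyme_map <- lapply(metabolite_coefs[seq_len(n_core)], `[[`, "support")

    # toy stoichiometric model: uptake -> two expression-capped branches ->
    # biomass, plus a fixed maintenance drain (keeps the optimal flux vector
    # from being proportional to a single scalar, so threshold calibration
    # is identifiable from per-profile flux shapes)
    gp <- genes[seq_len(min(4, n_genes))]
    rx <- c("upt", "r1", "r2", "maint", "biomass")
    toy <- metabolic_model(
      reactions = rx,
      metabolites = c("glc", "A", "B"),
      S = matrix(c( 1, -1, -1, -1,  0,     # glc
                    0,  1,  0,  0, -1,     # A
                    0,  0,  1,  0, -1),    # B
                 3, 5, byrow = TRUE),
      lb = setNames(c(0, 0, 0, 2, 0), rx),
      ub = setNames(c(30, 10, 10, 2, 100), rx),
      gpr = setNames(c(NA, paste(gp[1], "and", gp[2]),
                       paste(gp[3], "or", gp[4]), NA, NA), rx),
      objective = "biomass", glucose_exchange = "upt")

    growth_weights <- list(
      input = setNames(coef_mag(3) * 0.1, sample(registry$features, 3)),
      transcript = setNames(coef_mag(3) * 0.3, sample(genes, 3)),
      protein = setNames(coef_mag(3) * 0.2, sample(prots, 3)),
      metabolite = setNames(coef_mag(3) * 0.2, sample(mets, 3)),
      flux = setNames(0.05, "biomass"))

    structure(list(registry = registry, genes = genes, proteins = prots,
                   metabolites = mets, rnn_true = rnn_true, trn = trn,
                   ppi = ppi, pathways = pathways,
                   protein_coefs = protein_coefs,
                   metabolite_coefs = metabolite_coefs,
                   enzyme_map = enzyme_map, toy_model = toy,
                   flux_threshold = 0.5, growth_weights = growth_weights,
                   seed = seed),
              class = "ground_truth_system")
  })
}

#' @export
print.ground_truth_system <- function(x, ...) {
  cat("<ground_truth_system>", length(x$genes), "genes,", length(x$proteins),
      "proteins,", length(x$metabolites), "metabolites,",
      length(x$registry), "features\n")
  invisible(x)
}

# Fixed point of the true recurrence for one encoded condition.  Knocked-out
# genes are clamped to the scaled floor throughout (a deleted gene carries no
# transcript), matching the prediction-time clamping protocol.
rnn_fixed_point <- function(model, x, clamp_genes = character(0),
                            iters = 100) {
  s <- rep(0.5, ncol(model$w_x))
  clamp_idx <- match(clamp_genes, model$genes)
  clamp_val <- rep(model$scaler$lo, length(clamp_idx))
  states <- rnn_iterate(model$w_x, model$w_y, model$b, iters,
                        matrix(x, 1), matrix(s, 1), clamp_idx, clamp_val)
  drop(states[[iters + 1]])
}

#' Simulate a multi-layer compendium from a ground-truth system
#'
#' Transcript (sigmoid-space) values are the fixed point of the true
#' recurrent network for the condition's feature vector plus Gaussian noise,
#' mapped to absolute scale; protein and metabolite values come from the true
#' network-supported sparse linear maps (on the log scale) plus noise; fluxes
#' from expression-capped FBA on the toy model; growth from the per-layer
#' weights.  All layers share all conditions so cross-layer training is
#' testable.
#'
#' @param system a [generate_system()] result.
#' @param n_conditions number of distinct conditions (>= 2).
#' @param n_replicates replicates per condition.
#' @param noise_sd Gaussian noise sd applied in sigmoid/log space.
#' @param seed RNG seed.
#' @param include_fluxes simulate the flux layer via FBA (slower).
#' @return a [compendium()]; the truth used per profile is attached as
#'   `attr(, "truth")` (list with `s_true`, encoded `X`, growth centers).
#' @export
simulate_compendium <- function(system, n_conditions, n_replicates = 1,
                                noise_sd = 0, seed = 1,
                                include_fluxes = TRUE) {
  if (n_conditions < 2) stop("need n_conditions >= 2")
  reg <- system$registry
  with_seed(seed, {
    descs <- list(); keys <- character(0); guard <- 0
    while (length(descs) < n_conditions && guard < 50 * n_conditions) {
      guard <- guard + 1
      d <- condition_descriptor(
        strain = sample(reg$strains, 1), medium = sample(reg$media, 1),
        stresses = reg$stresses[runif(length(reg$stresses)) < 0.3],
        perturbations = reg$perturbations[runif(length(reg$perturbations)) < 0.1],
        phase = "exponential")
      k <- condition_key(d)
      if (!k %in% keys) { descs <- c(descs, list(d)); keys <- c(keys, k) }
    }
    if (length(descs) < n_conditions)
      stop("condition space too small for ", n_conditions, " distinct conditions")
    X <- t(vapply(descs, encode_condition, numeric(length(reg)),
                  registry = reg))
    S_true <- t(vapply(seq_len(n_conditions), function(c) {
      kos <- sub(":knockout$", "",
                 grep(":knockout$", descs[[c]]$perturbations, value = TRUE))
      rnn_fixed_point(system$rnn_true, X[c, ], clamp_genes = kos)
    }, numeric(length(system$genes))))
    colnames(S_true) <- system$genes

    nprof <- n_conditions * n_replicates
    prof_ids <- sprintf("prof%04d", seq_len(nprof))
    cond_of <- rep(seq_len(n_conditions), each = n_replicates)

    S_rep <- S_true[cond_of, , drop = FALSE] +
      matrix(rnorm(nprof * length(system$genes), 0, noise_sd),
             nprof, length(system$genes))
    S_rep <- pmin(pmax(S_rep, 0.001), 0.999)
    T_abs <- t(unscale_expression(system$rnn_true$scaler, t(S_rep)))

    logP <- vapply(system$proteins, function(p) {
      pc <- system$protein_coefs[[p]]
      pc$intercept + S_rep[, pc$support, drop = FALSE] %*% pc$coef +
        rnorm(nprof, 0, noise_sd)
    }, numeric(nprof))
    colnames(logP) <- system$proteins

    logM <- vapply(system$metabolites, function(m) {
      mc <- system$metabolite_coefs[[m]]
      base <- if (mc$scope == "core")
        logP[, mc$support, drop = FALSE] %*% mc$coef
      else S_rep[, mc$support, drop = FALSE] %*% mc$coef
      mc$intercept + base + rnorm(nprof, 0, noise_sd)
    }, numeric(nprof))
    colnames(logM) <- system$metabolites

    flux_mat <- NULL
    if (include_fluxes) {
      V <- vapply(seq_len(nprof), function(i) {
        act <- expression_to_activity(setNames(S_rep[i, ], system$genes),
                                      system$toy_model$gpr)
        cm <- constrain_bounds(system$toy_model, act, t = system$flux_threshold)
        sol <- solve_fba(cm)
        sol$fluxes
      }, numeric(length(system$toy_model$reactions)))
      flux_mat <- V * (1 + matrix(rnorm(length(V), 0, noise_sd),
                                  nrow(V), ncol(V)))
      rownames(flux_mat) <- system$toy_model$reactions
      colnames(flux_mat) <- prof_ids
    }

    gw <- system$growth_weights
    ctr <- function(M) sweep(M, 2, colMeans(M))
    growth <- 0.7 +
      drop(ctr(X[cond_of, names(gw$input), drop = FALSE]) %*% gw$input) +
      drop(ctr(S_rep[, names(gw$transcript), drop = FALSE]) %*% gw$transcript) +
      drop(ctr(logP[, names(gw$protein), drop = FALSE]) %*% gw$protein) +
      drop(ctr(logM[, names(gw$metabolite), drop = FALSE]) %*% gw$metabolite)
    if (include_fluxes)
      growth <- growth +
        drop(ctr(t(flux_mat)[, names(gw$flux), drop = FALSE]) %*% gw$flux)
    growth <- pmax(growth + rnorm(nprof, 0, noise_sd), 0.01)
    names(growth) <- prof_ids

    conditions <- do.call(rbind, lapply(seq_len(nprof), function(i) {
      d <- descs[[cond_of[i]]]
      data.frame(profile_id = prof_ids[i], layer = "multi", platform = "sim",
                 strain = d$strain, medium = d$medium,
                 stresses = paste(d$stresses, collapse = ";"),
                 perturbations = paste(d$perturbations, collapse = ";"),
                 phase = d$phase,
                 replicate = (i - 1) %% n_replicates + 1,
                 stringsAsFactors = FALSE)
    }))
    layers <- list(transcript = t(T_abs), protein = t(exp(logP)),
                   metabolite = t(exp(logM)))
    for (ly in names(layers)) colnames(layers[[ly]]) <- prof_ids
    if (include_fluxes) layers$flux <- flux_mat
    comp <- compendium(layers, conditions, growth = growth)
    attr(comp, "truth") <- list(X = X, S_true = S_true, cond_of = cond_of,
                                S_rep = S_rep, logP = logP, logM = logM,
                                descs = descs)
    comp
  })
}

#' Distort a true compendium layer into per-platform raw matrices
#'
#' Emulates the artifacts the normalization pipeline removes: a
#' strictly monotone per-platform distortion of log values (affine plus a
#' bounded smooth warp), a platform noise floor below which entries are
#' replaced by draws from the noise component, designated noise-reference
#' rows drawn purely from noise, and missing entries at a fixed rate.
#'
#' @param values true absolute-scale matrix (molecules x profiles).
#' @param platform_specs named list; each platform entry is a list with
#'   `profiles` (column ids), `a`, `b` (affine in log, `b > 0`), `warp_amp`,
#'   `warp_freq` (monotonicity requires `b > warp_amp * warp_freq`),
#'   `noise_mean`, `noise_sd`, `noise_floor` (log units) and `noise_rows`
#'   (row ids drawn purely from noise).
#' @param missing_rate fraction of entries masked at random, in [0, 1).
#' @param seed RNG seed.
#' @return named list of raw matrices (log scale) per platform.
#' @export
distort_to_raw <- function(values, platform_specs, missing_rate = 0,
                           seed = 1) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  with_seed(seed, {
    lapply(platform_specs, function(sp) {
      stopifnot(sp$b > 0)
      if ((sp$warp_amp %||% 0) * (sp$warp_freq %||% 1) >= sp$b)
        stop("distortion is not strictly monotone: need b > warp_amp * warp_freq")
      lv <- log(values[, sp$profiles, drop = FALSE])
      raw <- sp$a + sp$b * lv +
        (sp$warp_amp %||% 0) * sin((sp$warp_freq %||% 1) * lv)
      if (length(sp$noise_rows))
        raw[sp$noise_rows, ] <- rnorm(length(sp$noise_rows) * ncol(raw),
                                      sp$noise_mean, sp$noise_sd)
      low <- raw < (sp$noise_floor %||% -Inf)
      raw[low] <- rnorm(sum(low), sp$noise_mean, sp$noise_sd)
      if (missing_rate > 0)
        raw[runif(length(raw)) < missing_rate] <- NA
      raw
    })
  })
}

#' Simulate a delayed-logistic growth curve
#'
#' OD stays at `od0` until `lag`, then follows a logistic trajectory with
#' maximum specific growth rate `mu` and carrying capacity `K`; Gaussian
#' noise is added to the OD readings.
#'
#' @param mu maximum specific growth rate (1/h, > 0).
#' @param lag lag time (h, >= 0).
#' @param K carrying capacity (OD units, > od0).
#' @param od0 inoculum OD (> 0).
#' @param dt_minutes sampling interval.
#' @param horizon_h total duration (h).
#' @param noise_sd additive OD noise sd.
#' @param seed RNG seed.
#' @return list with `time` (h) and `od`, class `growth_curve`.
#' @export
simulate_growth_curve <- function(mu, lag = 0, K = 1, od0 = 0.05,
                                  dt_minutes = 5, horizon_h = 12,
                                  noise_sd = 0, seed = 1) {
  if (mu <= 0 || od0 <= 0 || K <= od0 || lag < 0 || horizon_h <= 0)
    stop("growth parameters must satisfy mu > 0, K > od0 > 0, lag >= 0")
  time <- seq(0, horizon_h, by = dt_minutes / 60)
  g <- pmax(time - lag, 0)
  od <- K * od0 * exp(mu * g) / (K + od0 * (exp(mu * g) - 1))
  if (noise_sd > 0)
    od <- with_seed(seed, pmax(od + rnorm(length(od), 0, noise_sd), 1e-6))
  structure(list(time = time, od = od), class = "growth_curve")
}
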
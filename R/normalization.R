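# Semi-supervised normalization pipeline: mixture-model noise removal ->
# platform-bias correction (quantile normalization + loess smoothing +
# z-scoring) -> loess absolute quantification against a shared-gene
# reference -> missingness filtering and kNN imputation.  Stage order is
# fixed; each stage keeps the matrix shape stable.

#' Two-component noise model of log intensities
#' @param mu_noise,sd_noise,mu_signal,sd_signal component parameters
#'   (`mu_signal > mu_noise`).
#' @param weight mixing weight of the noise component, in (0, 1).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(mu_noise, sd_noise, mu_signal, sd_signal, weight) {
  if (mu_signal <= mu_noise) stop("noise model requires mu_signal > mu_noise")
  if (weight <= 0 || weight >= 1) stop("mixing weight must be in (0,1)")
  structure(list(mu_noise = mu_noise, sd_noise = sd_noise,
                 mu_signal = mu_signal, sd_signal = sd_signal,
                 weight = weight),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> noise N(%.3f, %.3f) w=%.2f | signal N(%.3f, %.3f)\n",
              x$mu_noise, x$sd_noise, x$weight, x$mu_signal, x$sd_signal))
  invisible(x)
}

#' Remove the noise component from a log-intensity matrix
#'
#' Fits a two-component Gaussian mixture to all observed log intensities by
#' EM, initialized from the designated noise-reference rows (phantom-gene /
#' negative-control analogues): entries below the mean reference intensity
#' start in the noise component.  Entries whose posterior noise probability
#' exceeds 0.5 are flagged and floored at the fitted noise mean, so the
#' matrix shape is stable and the update is reversible via the returned
#' posteriors.
#'
#' @param mat log-scale matrix (molecules x profiles).
#' @param noise_reference_rows row ids (or indices) of noise references.
#' @param max_iter,tol EM controls.
#' @return list with `values` (updated matrix), `model` (a [noise_model()]),
#'   `flagged` (logical matrix), `posterior_noise` (numeric matrix).
#' @export
remove_noise <- function(mat, noise_reference_rows, max_iter = 1000,
                         tol = 1e-8) {
  if (!length(noise_reference_rows))
    stop("at least one noise-reference row is required")
  if (is.character(noise_reference_rows)) {
    missing_rows <- setdiff(noise_reference_rows, rownames(mat))
    if (length(missing_rows))
      stop("noise-reference row(s) not in matrix: ",
           paste(missing_rows, collapse = ", "))
    noise_reference_rows <- match(noise_reference_rows, rownames(mat))
  }
  x <- as.numeric(mat)
  obs <- is.finite(x)
  ref_mean <- mean(mat[noise_reference_rows, ], na.rm = TRUE)
  z <- cbind(as.numeric(x[obs] < ref_mean), as.numeric(x[obs] >= ref_mean))
  if (!any(z[, 1] == 1) || !any(z[, 2] == 1))
    stop("degenerate initialization: all entries on one side of the ",
         "noise-reference mean (single-component data?)")
  em <- mclust::meV(data = x[obs], z = z,
                    control = mclust::emControl(itmax = max_iter, tol = tol))
  if (is.null(em) || !is.finite(em$loglik))
    stop("EM did not converge; trace: loglik=",
         if (is.null(em)) "NULL" else em$loglik)
  mu <- em$parameters$mean
  sdc <- sqrt(em$parameters$variance$sigmasq)
  if (length(sdc) == 1) sdc <- rep(sdc, 2)
  pro <- em$parameters$pro
  noise_comp <- which.min(mu); signal_comp <- which.max(mu)
  # degeneracy check: the two-component fit must beat one Gaussian by a
  # material margin, otherwise the data carry no separable noise floor
  ll1 <- sum(dnorm(x[obs], mean(x[obs]), sd(x[obs]), log = TRUE))
  gain <- 2 * (em$loglik - ll1) / sum(obs)
  if (gain < 0.1)
    stop("degenerate mixture: two components are not supported by the data ",
         "(per-observation LR gain = ", signif(gain, 3), ")")
  post <- mclust::estepV(data = x[obs], parameters = em$parameters)$z
  pn <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  pn[obs] <- post[, noise_comp]
  flagged <- !is.na(pn) & pn > 0.5
  values <- mat
  values[flagged] <- mu[noise_comp]
  list(values = values,
       model = noise_model(mu[noise_comp], sdc[noise_comp],
                           mu[signal_comp], sdc[signal_comp],
                           pro[noise_comp]),
       flagged = flagged, posterior_noise = pn)
}

#' Correct platform biases
#'
#' Per platform: (1) quantile-normalize the profiles onto a common
#' distribution; (2) smooth the implied per-profile mapping with a loess fit
#' of post- on pre-normalization values and apply the smoothed map; (3)
#' z-score the platform data set.  All three steps are monotone within each
#' profile, so within-profile ranks are preserved.
#'
#' @param matrices_by_platform named list of log-scale matrices
#'   (molecules x profiles), one per platform.
#' @param zscore `"global"` (one mean/sd per platform data set; the default —
#'   it preserves the cross-gene abundance ordering the downstream absolute
#'   quantification relies on), `"per_gene"` (each gene centred/scaled across
#'   the platform's profiles) or `"per_profile"`.
#' @param span loess span of the smoothing step.
#' @return named list of corrected matrices.
#' @export
correct_platform_bias <- function(matrices_by_platform,
                                  zscore = c("global", "per_gene",
                                             "per_profile"),
                                  span = 0.75) {
  zscore <- match.arg(zscore)
  lapply(matrices_by_platform, function(mat) {
    if (ncol(mat) == 0) stop("platform with no profiles")
    if (ncol(mat) == 1) {
      warning("platform with a single profile: quantile step is the identity")
      qn <- mat
    } else {
      qn <- limma::normalizeQuantiles(mat)
    }
    out <- mat
    for (j in seq_len(ncol(mat))) {
      ok <- is.finite(mat[, j]) & is.finite(qn[, j])
      if (sum(ok) >= 10 && sd(mat[ok, j]) > 0) {
        lo <- loess(post ~ pre, data.frame(pre = mat[ok, j], post = qn[ok, j]),
                    span = span, degree = 2,
                    control = loess.control(surface = "direct"))
        out[ok, j] <- monotone_predict(lo, mat[ok, j])
      } else {
        out[, j] <- qn[, j]
      }
    }
    switch(zscore,
      global = {
        m <- mean(out, na.rm = TRUE); s <- sd(as.numeric(out), na.rm = TRUE)
        if (s == 0) stop("constant platform data set")
        (out - m) / s
      },
      per_gene = {
        m <- rowMeans(out, na.rm = TRUE)
        s <- apply(out, 1, sd, na.rm = TRUE)
        sweep(sweep(out, 1, m), 1, ifelse(s > 0, s, 1), `/`)
      },
      per_profile = {
        m <- colMeans(out, na.rm = TRUE)
        s <- apply(out, 2, sd, na.rm = TRUE)
        sweep(sweep(out, 2, m), 2, ifelse(s > 0, s, 1), `/`)
      })
  })
}

# Evaluate a loess fit as a monotone non-decreasing map: predictions on a
# sorted grid are rearranged by a running maximum, queries outside the fitted
# range clamp to the endpoint values.
monotone_predict <- function(lo, x) {
  grid <- sort(unique(lo$x))
  fx <- cummax(predict(lo, data.frame(pre = grid)))
  xq <- pmin(pmax(x, grid[1]), grid[length(grid)])
  stats::approx(grid, fx, xout = xq, ties = "ordered")$y
}

#' Absolute-level quantification by loess against shared references
#'
#' Per profile: fits a loess regression of log absolute reference levels on
#' the profile's relative values over the shared molecules, applies the
#' (monotone-rearranged) fit to all molecules, clamps extrapolation to the
#' fitted range endpoints and returns strictly positive absolute values.
#'
#' @param mat relative-scale matrix (molecules x profiles).
#' @param reference named positive vector of absolute levels (copies or
#'   molecules per cell) for the shared molecules.
#' @param min_shared minimum shared molecules per profile (loess support).
#' @param span loess span.
#' @return matrix of absolute-scale values (same shape as `mat`).
#' @export
quantify_absolute <- function(mat, reference, min_shared = 20, span = 0.75) {
  if (any(reference <= 0, na.rm = TRUE))
    stop("absolute reference values must be positive")
  out <- mat
  for (j in seq_len(ncol(mat))) {
    shared <- intersect(rownames(mat)[is.finite(mat[, j])], names(reference))
    if (length(shared) < min_shared)
      stop("profile '", colnames(mat)[j], "' shares only ", length(shared),
           " molecules with the absolute reference (need >= ", min_shared,
           "); consider a global affine fallback")
    lo <- loess(post ~ pre,
                data.frame(pre = mat[shared, j],
                           post = log(reference[shared])),
                span = span, degree = 2,
                control = loess.control(surface = "direct"))
    ok <- is.finite(mat[, j])
    out[ok, j] <- exp(monotone_predict(lo, mat[ok, j]))
  }
  out
}

#' Filter high-missingness molecules/profiles and impute the rest
#'
#' Molecules with strictly more than `gene_missing_max` of their values
#' missing are removed, then profiles likewise (so an exactly-70%-missing
#' gene is retained under the default).  Remaining missing entries are
#' imputed per gene as the mean of its `k` nearest genes (Euclidean distance
#' over co-observed profiles, scaled by the co-observation count; distance
#' ties broken by row order) that are observed in the target profile.
#'
#' @param mat molecules x profiles matrix with `NA` for missing entries.
#' @param gene_missing_max,profile_missing_max missingness thresholds in
#'   (0, 1].
#' @param k neighbours used for imputation (shrunk with a warning when fewer
#'   eligible neighbours exist).
#' @return imputed matrix (possibly fewer rows/columns).
#' @export
filter_and_impute <- function(mat, gene_missing_max = 0.70,
                              profile_missing_max = 0.70, k = 3) {
  stopifnot(gene_missing_max > 0, gene_missing_max <= 1,
            profile_missing_max > 0, profile_missing_max <= 1, k >= 1)
  gene_miss <- rowMeans(is.na(mat))
  mat <- mat[gene_miss <= gene_missing_max, , drop = FALSE]
  prof_miss <- colMeans(is.na(mat))
  mat <- mat[, prof_miss <= profile_missing_max, drop = FALSE]
  if (!anyNA(mat)) return(mat)
  out <- mat
  for (g in which(rowSums(is.na(mat)) > 0)) {
    for (j in which(is.na(mat[g, ]))) {
      cand <- setdiff(which(!is.na(mat[, j])), g)
      d <- vapply(cand, function(h) {
        co <- !is.na(mat[g, ]) & !is.na(mat[h, ])
        if (!any(co)) return(Inf)
        sqrt(sum((mat[g, co] - mat[h, co])^2) / sum(co))
      }, numeric(1))
      cand <- cand[is.finite(d)]; d <- d[is.finite(d)]
      if (!length(cand)) next
      kk <- min(k, length(cand))
      if (kk < k)
        warning("gene '", rownames(mat)[g], "': only ", kk,
                " eligible neighbours (k shrunk from ", k, ")")
      nb <- cand[order(d, cand)][seq_len(kk)]   # ties -> row order
      out[g, j] <- mean(mat[nb, j])
    }
  }
  out
}

#' Metabolite concentrations to molecules per cell
#'
#' Concentrations in mM are converted with the cell-volume constant 10^6
#' molecules per mM (1 nM in the cell corresponds to one molecule).  When a
#' reference of directly measured absolute molecule numbers is available for
#' some metabolites of a profile, a loess curve fitted on the
#' (concentration, absolute) pairs overrides the constant for that profile.
#'
#' @param conc_mM nonnegative concentration matrix (metabolites x profiles)
#'   or vector, in mM.
#' @param reference optional named vector of absolute molecule numbers.
#' @param min_shared minimum pairs needed to fit the loess override.
#' @return molecules-per-cell values, same shape as the input.
#' @export
normalize_metabolome <- function(conc_mM, reference = NULL, min_shared = 5) {
  if (any(conc_mM < 0, na.rm = TRUE)) stop("negative concentration")
  vec_in <- !is.matrix(conc_mM)
  m <- if (vec_in) matrix(conc_mM, ncol = 1,
                          dimnames = list(names(conc_mM), "p1"))
       else conc_mM
  out <- m * 1e6
  if (!is.null(reference)) {
    for (j in seq_len(ncol(m))) {
      shared <- intersect(rownames(m)[is.finite(m[, j])], names(reference))
      if (length(shared) < min_shared) {
        warning("profile ", colnames(m)[j], ": fewer than ", min_shared,
                " metabolites with absolute reference; constant conversion kept")
        next
      }
      lo <- loess(post ~ pre,
                  data.frame(pre = m[shared, j],
                             post = log(reference[shared])),
                  span = 0.75, degree = 2,
                  control = loess.control(surface = "direct"))
      ok <- is.finite(m[, j])
      out[ok, j] <- exp(monotone_predict(lo, m[ok, j]))
    }
  }
  if (vec_in) setNames(out[, 1], rownames(m)) else out
}

#' Normalize a flux profile by glucose uptake
#'
#' Every reaction rate is divided by the profile's glucose uptake rate, so
#' the glucose exchange maps to 1 by construction.
#'
#' @param flux_profile named flux vector (or reactions x profiles matrix).
#' @param glucose_exchange_id id of the glucose uptake reaction.
#' @return relative fluxes, same shape.
#' @export
normalize_fluxome <- function(flux_profile, glucose_exchange_id) {
  if (is.matrix(flux_profile)) {
    if (!glucose_exchange_id %in% rownames(flux_profile))
      stop("glucose uptake reaction '", glucose_exchange_id, "' missing")
    g <- flux_profile[glucose_exchange_id, ]
    if (any(!is.finite(g) | g == 0))
      stop("zero or missing glucose uptake rate")
    sweep(flux_profile, 2, g, `/`)
  } else {
    g <- flux_profile[[glucose_exchange_id]]
    if (is.null(g) || !is.finite(g) || g == 0)
      stop("zero or missing glucose uptake rate")
    flux_profile / g
  }
}

#' Run the full normalization pipeline on raw platform matrices
#'
#' Noise removal (optional, when noise-reference rows are given) ->
#' platform-bias correction -> loess absolute quantification ->
#' missingness filter and kNN imputation.
#'
#' @param raw_by_platform named list of raw log-scale matrices.
#' @param reference named absolute reference for [quantify_absolute()].
#' @param noise_rows optional noise-reference row ids (enables noise removal).
#' @param zscore passed to [correct_platform_bias()].
#' @param k imputation neighbours.
#' @param drop_noise_rows drop the noise-reference rows from the output.
#' @return absolute-scale molecules x profiles matrix over all platforms.
#' @export
normalize_pipeline <- function(raw_by_platform, reference, noise_rows = NULL,
                               zscore = "global", k = 3,
                               drop_noise_rows = TRUE) {
  step1 <- lapply(raw_by_platform, function(m) {
    if (is.null(noise_rows)) m else remove_noise(m, noise_rows)$values
  })
  step2 <- correct_platform_bias(step1, zscore = zscore)
  step3 <- lapply(step2, quantify_absolute, reference = reference)
  combined <- do.call(cbind, unname(step3))
  if (drop_noise_rows && !is.null(noise_rows))
    combined <- combined[setdiff(rownames(combined), noise_rows), ,
                         drop = FALSE]
  filter_and_impute(combined, k = k)
}
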
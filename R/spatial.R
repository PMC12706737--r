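# Spatial statistics for airborne concentrations: distance-decay regression,
# Moran's I with permutation inference, empirical variogram + ordinary
# kriging with leave-one-out cross-validation, and rank-sum group comparison.

#' Distance-decay regression
#'
#' Ordinary least squares of a concentration on log10 distance to the water,
#' the distance being the sole covariate.
#'
#' @param obs Data frame with `distance_to_water` (m, > 0) and `value`
#'   (concentration).
#' @return List with `slope` (per decade of distance), `intercept`, `r2`,
#'   `p` (slope t-test), and the fitted `model`.
#' @export
distance_regression <- function(obs) {
  if (nrow(obs) < 3L) stop("need at least 3 observations")
  if (any(obs$distance_to_water <= 0)) stop("distances must be positive")
  ld <- log10(obs$distance_to_water)
  if (length(unique(ld)) < 2L) stop("singular design: distances not distinct")
  fit <- stats::lm(value ~ ld, data = data.frame(value = obs$value, ld = ld))
  res <- stats::residuals(fit)
  sst <- sum((obs$value - mean(obs$value))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 0
  # degenerate (perfect or constant) fits make the slope test meaningless;
  # summary.lm warns about them, but the r2/p conventions below already
  # handle both cases
  cf <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(cf) >= 2L && sst > 0) cf[2, 4] else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2, p = p, model = fit)
}

# row-standardized spatial weights
spatial_weights <- function(x, y, scheme = c("inv_dist", "binary"),
                            cutoff = NULL) {
  scheme <- match.arg(scheme)
  d <- as.matrix(stats::dist(cbind(x, y)))
  if (any(d[upper.tri(d)] == 0)) {
    stop("coincident points: jitter coordinates or supply weights")
  }
  w <- if (scheme == "inv_dist") 1 / d else (d <= cutoff) * 1
  diag(w) <- 0
  rs <- rowSums(w)
  if (any(rs == 0)) stop("isolated point(s): no positive weights")
  w / rs
}

#' Moran's I spatial autocorrelation with permutation inference
#'
#' Standard Moran's I with row-standardized weights (inverse-distance by
#' default, or a user weight matrix). Expectation under spatial randomness
#' is `-1/(n-1)`; the p-value comes from random relabelings of the values
#' over the locations (two-sided).
#'
#' @param obs Data frame with `x`, `y`, `value`; or supply `weights`.
#' @param weights Optional n x n weight matrix (row-standardized internally).
#' @param scheme Weight scheme when `weights` is NULL.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return List with `i`, `expected_i`, `p_perm`, `n`, `n_perm`.
#' @export
morans_i <- function(obs, weights = NULL, scheme = "inv_dist", n_perm = 999,
                     seed = 1) {
  z0 <- obs$value
  n <- length(z0)
  if (n < 5L) stop("need at least 5 observations")
  w <- if (is.null(weights)) {
    spatial_weights(obs$x, obs$y, scheme)
  } else {
    if (any(weights < 0)) stop("weights must be nonnegative")
    rs <- rowSums(weights)
    if (any(rs == 0)) stop("zero-weight row in weight matrix")
    weights / rs
  }
  s0 <- sum(w)
  stat <- function(v) {
    z <- v - mean(v)
    (n / s0) * sum(w * outer(z, z)) / sum(z^2)
  }
  i_obs <- stat(z0)
  e_i <- -1 / (n - 1)
  set.seed(seed)
  i_perm <- vapply(seq_len(n_perm), function(k) stat(sample(z0)), 0)
  p <- (1 + sum(abs(i_perm - e_i) >= abs(i_obs - e_i))) / (n_perm + 1)
  list(i = i_obs, expected_i = e_i, p_perm = p, n = n, n_perm = n_perm)
}

#' Empirical semivariogram
#'
#' Method-of-moments estimator on distance bins:
#' `gamma(h) = mean(0.5 * (z_i - z_j)^2)` over pairs in each bin.
#'
#' @param obs Data frame with `x`, `y`, `value`.
#' @param n_bins Number of distance bins.
#' @param cutoff Maximum pair distance (default: half the maximum distance).
#' @return Data frame with `dist` (bin center), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(obs, n_bins = 12, cutoff = NULL) {
  d <- as.matrix(stats::dist(cbind(obs$x, obs$y)))
  g <- 0.5 * outer(obs$value, obs$value, "-")^2
  iu <- upper.tri(d)
  dv <- d[iu]; gv <- g[iu]
  if (is.null(cutoff)) cutoff <- max(dv) / 2
  keep <- dv > 0 & dv <= cutoff
  dv <- dv[keep]; gv <- gv[keep]
  if (length(dv) == 0L) stop("no pairs within cutoff")
  br <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- cut(dv, br, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    dist = vapply(seq_len(n_bins), function(b) mean(dv[bin == b]), 0),
    gamma = vapply(seq_len(n_bins), function(b) mean(gv[bin == b]), 0),
    n_pairs = vapply(seq_len(n_bins), function(b) sum(bin == b), 0L)
  )
  out[out$n_pairs > 0, , drop = FALSE]
}

# exponential semivariogram model
vgm_exponential <- function(h, nugget, psill, range) {
  ifelse(h == 0, 0, nugget + psill * (1 - exp(-h / range)))
}

#' Fit an exponential variogram model by weighted least squares
#'
#' Minimizes `sum N_j (gamma_emp_j - gamma_mod_j)^2 / gamma_mod_j^2`
#' (Cressie weights) over nonnegative nugget, partial sill, and range.
#'
#' @param emp Empirical variogram from [empirical_variogram()].
#' @param model Model family; only "exponential" is implemented.
#' @return List of class `variogram_model` with `nugget`, `psill`, `range`,
#'   `model`, and the objective value.
#' @export
fit_variogram <- function(emp, model = "exponential") {
  if (model != "exponential") stop("only the exponential model is implemented")
  obj <- function(par) {
    gm <- vgm_exponential(emp$dist, par[1], par[2], par[3])
    if (any(gm <= 0)) return(1e12)
    sum(emp$n_pairs * (emp$gamma - gm)^2 / gm^2)
  }
  sill0 <- max(emp$gamma)
  # multi-start: the nugget/partial-sill split is weakly identified, so try
  # several initial decompositions and range scales and keep the best fit
  starts <- expand.grid(
    nug_frac = c(0, 0.25, 0.5),
    range0 = max(emp$dist) * c(0.1, 0.3, 0.6)
  )
  fit <- NULL
  for (s in seq_len(nrow(starts))) {
    init <- c(nugget = starts$nug_frac[s] * sill0,
              psill = max(sill0 * (1 - starts$nug_frac[s]), 1e-8),
              range = starts$range0[s])
    # range bounded by the largest binned lag and sill by three times the
    # largest empirical semivariance: beyond those an exponential is
    # indistinguishable from a linear ramp and the parameters are
    # unidentified
    cand <- stats::optim(init, obj, method = "L-BFGS-B",
                         lower = c(0, 1e-10, max(emp$dist) * 1e-4),
                         upper = c(3 * sill0, 3 * sill0, max(emp$dist)))
    if (is.null(fit) || cand$value < fit$value) fit <- cand
  }
  structure(list(nugget = unname(fit$par[1]), psill = unname(fit$par[2]),
                 range = unname(fit$par[3]), model = "exponential",
                 objective = fit$value),
            class = "variogram_model")
}

# solve the ordinary kriging system for one target location
krige_point <- function(x0, y0, obs, vg, gamma_mat_inv_aug) {
  h0 <- sqrt((obs$x - x0)^2 + (obs$y - y0)^2)
  g0 <- c(vgm_exponential(h0, vg$nugget, vg$psill, vg$range), 1)
  sol <- gamma_mat_inv_aug %*% g0
  w <- sol[seq_len(nrow(obs))]
  list(pred = sum(w * obs$value), weights = w)
}

#' Ordinary kriging with leave-one-out cross-validation
#'
#' Fits an exponential variogram (unless one is supplied), solves the
#' ordinary kriging system (weights constrained to sum to one) at each
#' prediction point, and reports leave-one-out r2 and RMSE.
#'
#' @param obs Data frame with `x`, `y`, `value` (>= 5 rows).
#' @param grid Data frame of prediction locations (`x`, `y`). Defaults to the
#'   observation locations.
#' @param variogram A `variogram_model`, or NULL to fit one.
#' @param n_bins Bins for the empirical variogram when fitting.
#' @param return_weights Attach the kriging weight vectors.
#' @return List with `predictions` (grid plus `pred`), `variogram`, `loo`
#'   (data frame of held-out predictions), `loo_r2`, `loo_rmse`, and
#'   optionally `weights`.
#' @export
ordinary_kriging <- function(obs, grid = NULL, variogram = NULL, n_bins = 12,
                             return_weights = FALSE) {
  if (nrow(obs) < 5L) stop("need at least 5 observations")
  if (is.null(grid)) grid <- obs[, c("x", "y")]
  if (stats::var(obs$value) == 0) {
    # constant field: the semivariogram is identically zero and the kriging
    # system is singular; the best linear unbiased predictor is the constant
    out <- list(
      predictions = cbind(grid, pred = rep(obs$value[1], nrow(grid))),
      variogram = structure(list(nugget = 0, psill = 0, range = NA_real_,
                                 model = "constant", objective = 0),
                            class = "variogram_model"),
      loo = data.frame(observed = obs$value, predicted = obs$value),
      loo_r2 = 0, loo_rmse = 0
    )
    if (return_weights) {
      out$weights <- matrix(1 / nrow(obs), nrow(grid), nrow(obs))
    }
    return(out)
  }
  if (is.null(variogram)) {
    variogram <- fit_variogram(empirical_variogram(obs, n_bins))
  }
  if (variogram$nugget < 0 || variogram$psill < 0 || variogram$range <= 0) {
    stop("variogram parameters must be nonnegative with positive range")
  }
  build_system <- function(o) {
    n <- nrow(o)
    d <- as.matrix(stats::dist(cbind(o$x, o$y)))
    gm <- vgm_exponential(d, variogram$nugget, variogram$psill, variogram$range)
    a <- rbind(cbind(gm, 1), c(rep(1, n), 0))
    inv <- tryCatch(solve(a), error = function(e) {
      stop("kriging system not invertible (condition estimate ",
           format(kappa(a), digits = 3), "): ", conditionMessage(e))
    })
    inv
  }
  inv_full <- build_system(obs)
  preds <- numeric(nrow(grid))
  wts <- if (return_weights) matrix(NA_real_, nrow(grid), nrow(obs)) else NULL
  for (i in seq_len(nrow(grid))) {
    kp <- krige_point(grid$x[i], grid$y[i], obs, variogram, inv_full)
    preds[i] <- kp$pred
    if (return_weights) wts[i, ] <- kp$weights
  }
  loo <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    o <- obs[-i, , drop = FALSE]
    inv_i <- build_system(o)
    loo[i] <- krige_point(obs$x[i], obs$y[i], o, variogram, inv_i)$pred
  }
  sst <- sum((obs$value - mean(obs$value))^2)
  ssr <- sum((obs$value - loo)^2)
  out <- list(
    predictions = cbind(grid, pred = preds),
    variogram = variogram,
    loo = data.frame(observed = obs$value, predicted = loo),
    loo_r2 = if (sst > 0) 1 - ssr / sst else 0,
    loo_rmse = sqrt(mean((obs$value - loo)^2))
  )
  if (return_weights) out$weights <- wts
  out
}

#' Two-sided rank-sum comparison of two groups
#'
#' Wilcoxon rank-sum (Mann-Whitney) test: exact enumeration for combined
#' sample sizes up to 12 without ties, normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param group_a,group_b Numeric vectors (each >= 2 values).
#' @return List with `statistic` (Mann-Whitney U for group_a), `p`, and
#'   `method`.
#' @export
ranksum_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("both groups need at least 2 values")
  }
  n <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- n <= 12 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}
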
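#' Patch-level species richness and community totals from the posterior
#'
#' For every posterior draw, patch richness is the number of species with a
#' positive latent state (`z_ij > 0`) and the community total is
#' `sum_i z_ij`; both are summarized by the median and a central credible
#' interval.  For abundance fits the monitored latent abundance draws are
#' used directly (conditional on the sampled patches).  For frequency fits
#' the patch-level frequency over the full tessellation is reconstructed
#' posterior-predictively as `z = y + Binomial(tp - ap, psi) * w`, so species
#' never seen in the sampled plots can still contribute.
#'
#' @param post a `community_posterior`.
#' @param prob credible-interval mass.
#' @param seed optional seed for the frequency-mode reconstruction.
#' @return Data frame with one row per patch: `patch_id`, `area_ha`,
#'   `richness_lo/med/hi`, `total_lo/med/hi`.  The per-draw matrices are
#'   attached as attributes `"richness_draws"` and `"total_draws"`
#'   (draws x patches), and `"z_draws"` holds the (reconstructed) latent
#'   states.
#' @export
derive_patch_summaries <- function(post, prob = 0.95, seed = NULL) {
  stopifnot(inherits(post, "community_posterior"))
  z <- posterior_patch_states(post, seed = seed)
  rich <- apply(z > 0, c(1, 3), sum)
  tot <- apply(z, c(1, 3), sum)
  alpha <- (1 - prob) / 2
  qs <- function(m) apply(m, 2, stats::quantile, c(alpha, 0.5, 1 - alpha))
  qr <- qs(rich); qt <- qs(tot)
  out <- data.frame(patch_id = post$patches$patch_id,
                    area_ha = post$patches$area_ha,
                    richness_lo = qr[1, ], richness_med = qr[2, ],
                    richness_hi = qr[3, ],
                    total_lo = qt[1, ], total_med = qt[2, ], total_hi = qt[3, ])
  rownames(out) <- NULL
  structure(out, richness_draws = rich, total_draws = tot, z_draws = z)
}

# Latent patch-level state draws (draws x species x patches); reconstructs
# the full-tessellation frequency for frequency fits.
posterior_patch_states <- function(post, seed = NULL) {
  if (post$mode == "abundance") return(extract_draws(post, "z"))
  if (isTRUE(post$constant_psi))
    stop_invalid("mode", "patch states are not defined for constant_psi fits")
  psi <- extract_draws(post, "psi")
  w <- if (isTRUE(post$augmented)) extract_draws(post, "w") else
    matrix(1, dim(psi)[1], dim(psi)[2])
  y <- occurrence_matrix(post$data)
  rem <- as.integer(post$patches$tp - post$patches$ap)
  d <- dim(psi)
  with_seed(seed, {
    z <- array(0, d, dimnames = dimnames(psi))
    for (j in seq_len(d[3])) {
      unsurv <- matrix(stats::rbinom(d[1] * d[2], rem[j], as.vector(psi[, , j])),
                       d[1], d[2]) * w
      z[, , j] <- unsurv + rep(y[, j], each = d[1])
    }
    z
  })
}

#' Predict the species-area relationship over an area grid
#'
#' For each retained posterior draw and each grid area, a latent state is
#' simulated for every community member (`w = 1` in that draw): abundance
#' mode draws `z_i ~ Poisson(exp(beta0_i + beta1_i log A + b_i))`, frequency
#' mode draws `z_i ~ Binomial(tp(A), plogis(beta0_i + beta1_i A + b_i))`
#' with `tp(A)` from [total_plots()].  Richness (number of species with at
#' least one individual / occupied plot) and the community total are then
#' summarized across draws.  Site effects for these new, unsampled patches
#' are either drawn fresh from `Normal(0, sd.site^2)` per draw
#' (`"marginalize"`, the default — setting them to zero would understate
#' predictive spread) or fixed at zero (`"zero"`).  Grid points below the
#' smallest sampled patch area are marked as extrapolations.
#'
#' @param post a `community_posterior`.
#' @param area_grid positive, increasing vector of areas (ha).
#' @param ndraws number of posterior draws to use (subsampled evenly).
#' @param site_effects `"marginalize"` or `"zero"`.
#' @param prob credible-interval mass.
#' @param seed optional seed for the predictive simulation.
#' @return A data frame of class `sar_curve`: `area_ha`, `richness_lo/med/hi`,
#'   `total_lo/med/hi`, `extrapolated`, `model` (`"fitted"` or `"null"`).
#'   Attribute `"richness_draws"` holds the draws x areas matrix.
#' @export
predict_sar_curve <- function(post, area_grid, ndraws = 400,
                              site_effects = c("marginalize", "zero"),
                              prob = 0.95, seed = NULL) {
  stopifnot(inherits(post, "community_posterior"))
  site_effects <- match.arg(site_effects)
  if (length(area_grid) < 1 || any(!is.finite(area_grid)) || any(area_grid <= 0))
    stop_invalid("grid", "area_grid must be positive and nonempty")
  if (isTRUE(post$constant_psi))
    stop_invalid("mode", "SAR prediction is not defined for constant_psi fits")
  beta0 <- extract_draws(post, "beta0")
  beta1 <- extract_draws(post, "beta1")
  if (is.null(dim(beta1)))  # null model: constant node collapses per species
    beta1 <- matrix(beta1, nrow(beta0), ncol(beta0))
  sd_site <- extract_draws(post, "sd.site")
  w <- if (isTRUE(post$augmented)) extract_draws(post, "w") else NULL
  ntot <- nrow(beta0)
  keep <- unique(round(seq(1, ntot, length.out = min(ndraws, ntot))))
  S <- ncol(beta0)
  alpha <- (1 - prob) / 2
  rich <- tot <- matrix(0, length(keep), length(area_grid))
  with_seed(seed, {
    for (a in seq_along(area_grid)) {
      A <- area_grid[a]
      tp <- if (post$mode == "frequency") total_plots(A, post$data$plot_area_m2)
      for (d in seq_along(keep)) {
        k <- keep[d]
        b <- if (site_effects == "marginalize")
          stats::rnorm(S, 0, sd_site[k]) else 0
        memb <- if (is.null(w)) rep(1, S) else w[k, ]
        z <- if (post$mode == "abundance") {
          lam <- exp(beta0[k, ] + beta1[k, ] * log(A) + b) * memb
          stats::rpois(S, lam)
        } else {
          psi <- inv_logit(beta0[k, ] + beta1[k, ] * A + b) * memb
          stats::rbinom(S, tp, psi)
        }
        rich[d, a] <- sum(z > 0)
        tot[d, a] <- sum(z)
      }
    }
  })
  qs <- function(m) apply(m, 2, stats::quantile, c(alpha, 0.5, 1 - alpha))
  qr <- qs(rich); qt <- qs(tot)
  out <- data.frame(area_ha = area_grid,
                    richness_lo = qr[1, ], richness_med = qr[2, ],
                    richness_hi = qr[3, ],
                    total_lo = qt[1, ], total_med = qt[2, ], total_hi = qt[3, ],
                    extrapolated = area_grid < min(post$patches$area_ha),
                    model = if (isTRUE(post$null_model)) "null" else "fitted")
  rownames(out) <- NULL
  structure(out, richness_draws = rich,
            class = c("sar_curve", "data.frame"))
}

#' Fit the constant-density / constant-occurrence null model
#'
#' Refits the community model with the area-scaling coefficient fixed for
#' every species — `beta1_i = 1` for the abundance model (density
#' independent of area) or `beta1_i = 0` for the frequency model (occurrence
#' probability independent of area) — and its hyper-sd at zero, while
#' retaining random site effects so the null is strictly comparable to the
#' free-slope fit.  Comparing [predict_sar_curve()] bands between the two
#' fits tests whether species-level density-area relationships are strong
#' enough to alter the SAR's form.
#'
#' @param data a `comm_data` object.
#' @param config a [fit_config()].
#' @param mode survey mode; defaults to the dataset's.
#' @param ... passed to the underlying fitting function.
#' @return A `community_posterior` with `null_model = TRUE`.
#' @export
fit_null_model <- function(data, config = fit_config(), mode = data$mode, ...) {
  if (mode == "abundance")
    fit_abundance_model(data, config, null_model = TRUE, ...)
  else
    fit_frequency_model(data, config, null_model = TRUE, ...)
}

#' Expected richness under the random placement model
#'
#' Closed form for the SAR when individuals are placed independently at
#' constant density: if species `i` has `lambda_i` individuals per unit
#' area, a patch of area `A` misses it with probability `exp(-lambda_i A)`,
#' so \deqn{E[S(A)] = \sum_i (1 - e^{-\lambda_i A}).}  This is the special
#' case of the Poisson abundance model with every `beta1_i = 1` and no site
#' effects (`lambda_i = exp(beta0_i)`), and is the analytic oracle for the
#' null-model SAR curve.
#'
#' @param unit_area_lambdas positive per-species densities at unit area.
#' @param area_ha positive area (vectorized).
#' @return Expected richness for each area.
#' @examples
#' random_placement_expected_richness(c(1, 2), 1)  # (1-e^-1) + (1-e^-2)
#' @export
random_placement_expected_richness <- function(unit_area_lambdas, area_ha) {
  if (any(!is.finite(unit_area_lambdas)) || any(unit_area_lambdas <= 0))
    stop_invalid("lambda", "densities must be positive")
  if (any(!is.finite(area_ha)) || any(area_ha <= 0))
    stop_invalid("area", "area_ha must be positive")
  vapply(area_ha, function(a) sum(1 - exp(-unit_area_lambdas * a)), 0)
}
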
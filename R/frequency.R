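#' Plot-level occurrence probability under the logit-linear area model
#'
#' The ecological process model for plot-based frequency surveys: a patch is
#' tessellated into `tp` equal plots and the patch-level frequency of a
#' species is `z_ij ~ Binomial(tp_j, psi_ij)` with
#' \deqn{\mathrm{logit}(\psi_{ij}) = \beta_{0i} + \beta_{1i} A_j + x_j'\beta_i + b_{ij}.}
#' Area enters *linearly* (not log-transformed); `beta1 = 0` is the
#' constant-occurrence-probability case.
#'
#' @param beta0,beta1 species-level logit-scale intercept and area slope.
#' @param area_ha patch area in hectares (> 0).
#' @param covar_term,site_effect optional additional logit-scale terms.
#' @return Occurrence probability `psi` in (0, 1) (vectorized).
#' @examples
#' occurrence_probability(0, 0, 3)        # 0.5
#' occurrence_probability(0, -0.1, 10)    # plogis(-1)
#' @export
occurrence_probability <- function(beta0, beta1, area_ha, covar_term = 0,
                                   site_effect = 0) {
  if (any(!is.finite(area_ha)) || any(area_ha <= 0))
    stop_invalid("area", "area_ha must be positive")
  inv_logit(beta0 + beta1 * area_ha + covar_term + site_effect)
}

#' Community hyperparameters for the frequency model
#'
#' Group-aware container: species-level logit-scale intercepts and area
#' slopes are normal with group-specific means and sds, e.g.
#' `beta1_i ~ N(mu_beta1[g_i], sigma_beta1[g_i]^2)` (early-successional,
#' mature-forest, exotic, ...).  With a single group this reduces to the
#' shared hyperdistribution of the abundance model.  `group_props` are the
#' community proportions used by the simulator to assign species to groups.
#'
#' @param mu_beta0,sigma_beta0,mu_beta1,sigma_beta1 per-group vectors (all
#'   the same length).
#' @param sigma_b sd of the random site effects (shared by all species).
#' @param group_names optional group labels.
#' @param group_props simulator group proportions (sum to 1).
#' @return A named list of class `frequency_hyperparams`.
#' @export
frequency_hyperparams <- function(mu_beta0 = -4.5, sigma_beta0 = 1.5,
                                  mu_beta1 = 0, sigma_beta1 = 0.2,
                                  sigma_b = 0.3, group_names = NULL,
                                  group_props = NULL) {
  G <- length(mu_beta0)
  if (length(sigma_beta0) != G || length(mu_beta1) != G || length(sigma_beta1) != G)
    stop_invalid("groups", "hyperparameter vectors must share one length per group")
  if (any(c(sigma_beta0, sigma_beta1, sigma_b) < 0))
    stop_invalid("sigma", "standard deviations must be nonnegative")
  group_names <- group_names %||% (if (G == 1) "community" else paste0("g", seq_len(G)))
  group_props <- group_props %||% rep(1 / G, G)
  if (length(group_props) != G || abs(sum(group_props) - 1) > 1e-8)
    stop_invalid("group_props", "group_props must sum to 1 (one entry per group)")
  structure(list(mu_beta0 = mu_beta0, sigma_beta0 = sigma_beta0,
                 mu_beta1 = mu_beta1, sigma_beta1 = sigma_beta1,
                 sigma_b = sigma_b, group_names = group_names,
                 group_props = group_props),
            class = c("frequency_hyperparams", "list"))
}

#' Draw a patch-level occurrence frequency
#'
#' `z ~ Binomial(tp, psi)`: the number of plots, among the `tp` tessellating
#' the patch, in which the species occurs.
#'
#' @param psi plot-level occurrence probability in \[0, 1\] (vectorized).
#' @param tp total plot count (recycled against `psi`).
#' @param seed optional seed.
#' @return Integer vector of frequencies.
#' @export
sample_patch_frequency <- function(psi, tp, seed = NULL) {
  if (any(!is.finite(psi)) || any(psi < 0) || any(psi > 1))
    stop_invalid("psi", "psi must lie in [0, 1]")
  if (!all(is_count(tp)) || any(tp < 1))
    stop_invalid("tp", "tp must be a positive integer")
  n <- max(length(psi), length(tp))
  with_seed(seed, stats::rbinom(n, rep_len(tp, n), rep_len(psi, n)))
}

#' Observed-frequency log likelihood
#'
#' Sampling process model for frequency surveys: of the `ap` plots actually
#' sampled in a patch, the species is recorded in
#' `y ~ Binomial(ap, psi)` of them (detection within a plot assumed perfect,
#' as is usual in plant surveys).
#'
#' @param y observed number of occupied sampled plots (`0 <= y <= ap`).
#' @param ap number of sampled plots.
#' @param psi plot-level occurrence probability.
#' @return Log likelihood (natural log).
#' @export
observed_frequency_loglik <- function(y, ap, psi) {
  if (!all(is_count(y)) || !all(is_count(ap)) || any(y > ap))
    stop_invalid("y", "need integer 0 <= y <= ap")
  if (any(psi < 0) || any(psi > 1))
    stop_invalid("psi", "psi must lie in [0, 1]")
  stats::dbinom(y, ap, psi, log = TRUE)
}

#' Predict occurrence frequency in the unsurveyed plots of a patch
#'
#' The unsurveyed portion of a patch holds `tp - ap` plots; the species'
#' frequency there is `z_unsurveyed ~ Binomial(tp - ap, psi)`, and the
#' patch-level frequency is reconstructed as `z = y + z_unsurveyed`.  A
#' species with `y = 0` can still have `z_unsurveyed > 0` — species can occur
#' only in the unsampled area.
#'
#' @param psi plot-level occurrence probability (vectorized).
#' @param tp,ap total and sampled plot counts (`ap <= tp`).
#' @param seed optional seed.
#' @return Integer vector of unsurveyed-plot frequencies.
#' @export
predict_unsurveyed_frequency <- function(psi, tp, ap, seed = NULL) {
  if (any(!is.finite(psi)) || any(psi < 0) || any(psi > 1))
    stop_invalid("psi", "psi must lie in [0, 1]")
  if (!all(is_count(tp)) || !all(is_count(ap)) || any(ap > tp))
    stop_invalid("ap_gt_tp", "need integer 0 <= ap <= tp")
  n <- max(length(psi), length(tp), length(ap))
  with_seed(seed, stats::rbinom(n, rep_len(tp, n) - rep_len(ap, n),
                                rep_len(psi, n)))
}

#' Assign augmented species to groups via a Dirichlet-categorical draw
#'
#' Species added by data augmentation have no observed group; they are
#' assigned to groups by first drawing community group proportions from
#' `Dirichlet(counts + prior)` (a flat all-ones prior by default) given the
#' observed per-group species counts, then assigning each augmented species
#' categorically.  Within an MCMC run this assignment is resampled each
#' sweep; this function performs one such draw.
#'
#' @param observed_group_counts named integer vector of detected species per
#'   group.
#' @param n_augmented number of augmented species to assign.
#' @param prior Dirichlet prior concentration added to each count.
#' @param seed optional seed.
#' @return Character vector of group labels (length `n_augmented`) with the
#'   drawn proportions in attribute `"proportions"`.
#' @export
assign_augmented_groups <- function(observed_group_counts, n_augmented,
                                    prior = 1, seed = NULL) {
  if (length(observed_group_counts) < 1)
    stop_invalid("groups", "need at least one group")
  if (!all(is_count(observed_group_counts)))
    stop_invalid("count", "group counts must be nonnegative integers")
  if (!is_count(n_augmented))
    stop_invalid("n_augmented", "n_augmented must be a nonnegative integer")
  labels <- names(observed_group_counts) %||%
    paste0("g", seq_along(observed_group_counts))
  with_seed(seed, {
    gam <- stats::rgamma(length(observed_group_counts),
                         shape = observed_group_counts + prior, rate = 1)
    props <- gam / sum(gam)
    out <- if (n_augmented > 0)
      sample(labels, n_augmented, replace = TRUE, prob = props)
    else character(0)
    structure(out, proportions = stats::setNames(props, labels))
  })
}
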
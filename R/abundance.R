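#' Expected patch-level abundance under the log-link area model
#'
#' The ecological process model for abundance surveys places a Poisson
#' distribution on the latent abundance `z_ij` of species `i` in patch `j`
#' with mean
#' \deqn{\log \lambda_{ij} = \beta_{0i} + \beta_{1i} \log A_j + x_j'\beta_i + b_{ij},}
#' so `beta0` is log abundance in a 1-ha patch and `beta1` is the area-scaling
#' exponent: `beta1 = 1` is the constant-density case (abundance proportional
#' to area), `beta1 < 1` a negative density-area relationship.
#'
#' @param beta0,beta1 species-level intercept and area-scaling coefficient.
#' @param area_ha patch area in hectares (> 0).
#' @param covar_term optional covariate contribution `x_j' beta_i`.
#' @param site_effect optional random site effect `b_ij`.
#' @return Expected abundance `lambda` (vectorized over any argument).
#' @examples
#' expected_abundance(0, 1, 1)        # 1
#' expected_abundance(0, 0.5, 4)      # 2
#' expected_abundance(log(2), 1, 5)   # 10 = density 2/ha x 5 ha
#' @export
expected_abundance <- function(beta0, beta1, area_ha, covar_term = 0,
                               site_effect = 0) {
  if (any(!is.finite(area_ha)) || any(area_ha <= 0))
    stop_invalid("area", "area_ha must be positive")
  exp(beta0 + beta1 * log(area_ha) + covar_term + site_effect)
}

#' Community hyperparameters for the abundance model
#'
#' Container for the community-level normal hyperdistributions that share
#' strength across species: `beta0_i ~ N(mu_beta0, sigma_beta0^2)`,
#' `beta1_i ~ N(mu_beta1, sigma_beta1^2)`, `logit(p_i) ~ N(mu_lp, sigma_lp^2)`
#' (detection on the logit scale, so `p` stays in (0,1)), and random site
#' effects `b_ij ~ N(0, sigma_b^2)` with a single `sigma_b` shared by all
#' species.
#'
#' @param mu_beta0,sigma_beta0 mean and sd of the log-abundance intercepts.
#' @param mu_beta1,sigma_beta1 mean and sd of the area-scaling coefficients.
#' @param mu_lp,sigma_lp mean and sd of logit-scale detection.
#' @param sigma_b sd of the random site effects.
#' @return A named list of class `abundance_hyperparams`.
#' @export
abundance_hyperparams <- function(mu_beta0 = 0, sigma_beta0 = 1,
                                  mu_beta1 = 1, sigma_beta1 = 0.2,
                                  mu_lp = 0, sigma_lp = 0.5,
                                  sigma_b = 0.2) {
  h <- list(mu_beta0 = mu_beta0, sigma_beta0 = sigma_beta0,
            mu_beta1 = mu_beta1, sigma_beta1 = sigma_beta1,
            mu_lp = mu_lp, sigma_lp = sigma_lp, sigma_b = sigma_b)
  sds <- unlist(h[grep("^sigma", names(h))])
  if (any(!is.finite(sds)) || any(sds < 0))
    stop_invalid("sigma", "standard deviations must be nonnegative")
  structure(h, class = c("abundance_hyperparams", "list"))
}

#' Draw species-level parameters from the community hyperdistributions
#'
#' @param hyper an [abundance_hyperparams()] object.
#' @param n_species number of species to draw.
#' @param n_patches if supplied, also draws the `n_species x n_patches`
#'   matrix of random site effects `b_ij ~ N(0, sigma_b^2)`.
#' @param seed optional seed for reproducible draws (global RNG untouched).
#' @return List with vectors `beta0`, `beta1`, `lp`, `p = plogis(lp)` and,
#'   when `n_patches` is given, matrix `b`.
#' @export
sample_species_params <- function(hyper, n_species, n_patches = NULL,
                                  seed = NULL) {
  stopifnot(inherits(hyper, "abundance_hyperparams") || is.list(hyper))
  if (!is_count(n_species) || n_species < 1)
    stop_invalid("n_species", "n_species must be a positive integer")
  with_seed(seed, {
    out <- list(
      beta0 = stats::rnorm(n_species, hyper$mu_beta0, hyper$sigma_beta0),
      beta1 = stats::rnorm(n_species, hyper$mu_beta1, hyper$sigma_beta1),
      lp    = stats::rnorm(n_species, hyper$mu_lp, hyper$sigma_lp))
    out$p <- inv_logit(out$lp)
    if (!is.null(n_patches))
      out$b <- matrix(stats::rnorm(n_species * n_patches, 0, hyper$sigma_b),
                      n_species, n_patches)
    out
  })
}

#' Draw latent patch-level abundances
#'
#' `z_ij ~ Poisson(lambda_ij)` with `lambda` from [expected_abundance()].
#'
#' @param params list with `beta0`, `beta1` and optionally `b` (site-effect
#'   matrix), as returned by [sample_species_params()].
#' @param area_ha vector of patch areas (ha), or a patch data frame with an
#'   `area_ha` column.
#' @param seed optional seed.
#' @return Integer matrix `z` (species x patches).
#' @export
sample_latent_abundance <- function(params, area_ha, seed = NULL) {
  if (is.data.frame(area_ha)) area_ha <- area_ha$area_ha
  S <- length(params$beta0)
  J <- length(area_ha)
  b <- params$b %||% matrix(0, S, J)
  lam <- exp(outer(params$beta0, rep(1, J)) +
               outer(params$beta1, log(area_ha)) + b)
  with_seed(seed,
            matrix(stats::rpois(S * J, lam), S, J,
                   dimnames = dimnames(params$b)))
}

#' Thin latent abundance to the sampled fraction of each patch
#'
#' Incomplete spatial coverage: only a fraction `phi_j` of patch `j` is
#' covered by sampling, so the abundance exposed to sampling is
#' `N_ij ~ Binomial(z_ij, phi_j)`.  Composed with a Poisson `z`, the marginal
#' of `N` is Poisson with mean `lambda * phi`.
#'
#' @param z integer matrix of latent abundances (species x patches).
#' @param phi per-patch sampled fractions in (0, 1] (recycled if scalar).
#' @param seed optional seed.
#' @return Integer matrix `N` with `N <= z` elementwise.
#' @export
thin_to_sampled <- function(z, phi, seed = NULL) {
  z <- as.matrix(z)
  if (any(!is.finite(phi)) || any(phi <= 0) || any(phi > 1))
    stop_invalid("phi", "phi must lie in (0, 1]")
  phi <- rep(phi, length.out = ncol(z))
  with_seed(seed, {
    N <- z
    for (j in seq_len(ncol(z)))
      N[, j] <- stats::rbinom(nrow(z), z[, j], phi[j])
    N
  })
}

#' Multinomial encounter-frequency cell probabilities
#'
#' With per-visit detection probability `p` and `t` independent visits, the
#' number of visits `H` on which one individual is detected is
#' `Binomial(t, p)`; the encounter-frequency vector of a species is
#' multinomial over cells `H = 0, ..., t` with these probabilities.  The
#' `H = 0` cell is the probability an individual escapes detection entirely.
#'
#' @param p per-visit individual detection probability in (0, 1).
#' @param t number of visits (>= 1).
#' @return Named numeric vector `(pi_0, ..., pi_t)` summing to 1.
#' @examples
#' multinomial_cell_probs(0.5, 2)          # 0.25 0.50 0.25
#' 1 - multinomial_cell_probs(0.66, 5)[1]  # P(detected at least once) > 0.99
#' @export
multinomial_cell_probs <- function(p, t) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop_invalid("p", "p must lie strictly in (0, 1)")
  if (!is_count(t) || t < 1)
    stop_invalid("t", "t must be a positive integer")
  stats::setNames(stats::dbinom(0:t, t, p), paste0("H", 0:t))
}

#' Encounter-history log likelihood, conditioned on encounter
#'
#' The full multinomial encounter model over cells `H = 0..t` is
#' reparameterized in terms of the observed frequencies only: the total
#' number of detected individuals follows
#' `n ~ Binomial(N, p*)` with `p* = 1 - (1 - p)^t`, and given `n` the
#' frequencies over `H = 1..t` are multinomial with the conditional cell
#' probabilities `pi_H / (1 - pi_0)`.  The sum of the two log terms equals
#' the full multinomial log likelihood with `y_0 = N - n`.
#'
#' @param y_freqs integer vector of counts of individuals detected exactly
#'   `H = 1, ..., t` times.
#' @param N number of individuals exposed to sampling (`>= sum(y_freqs)`).
#' @param p per-visit detection probability in (0, 1).
#' @param n_detected total detected; defaults to `sum(y_freqs)` and must
#'   equal it.
#' @param t number of visits; defaults to `length(y_freqs)`.
#' @return Log likelihood (natural log), with attributes `"binomial"` and
#'   `"multinomial"` holding the two components.
#' @examples
#' ll <- conditional_encounter_loglik(c(2, 1), N = 5, p = 0.5)
#' exp(attr(ll, "multinomial"))   # 4/9: conditional multinomial probability
#' @export
conditional_encounter_loglik <- function(y_freqs, N, p,
                                         n_detected = sum(y_freqs),
                                         t = length(y_freqs)) {
  if (!all(is_count(y_freqs)))
    stop_invalid("y_freqs", "y_freqs must be nonnegative integers")
  if (length(y_freqs) != t)
    stop_invalid("t", "length(y_freqs) must equal t")
  if (n_detected != sum(y_freqs))
    stop_invalid("n_detected", "n_detected (%d) != sum(y_freqs) (%d)",
                 n_detected, sum(y_freqs))
  if (!is_count(N) || n_detected > N)
    stop_invalid("N", "need integer N >= n_detected (N = %s, n = %d)",
                 format(N), n_detected)
  if (p <= 0 || p >= 1) stop_invalid("p", "p must lie strictly in (0, 1)")
  pstar <- 1 - (1 - p)^t
  ll_bin <- stats::dbinom(n_detected, N, pstar, log = TRUE)
  ll_mult <- if (n_detected > 0) {
    cond <- stats::dbinom(seq_len(t), t, p) / pstar
    stats::dmultinom(y_freqs, size = n_detected, prob = cond, log = TRUE)
  } else 0
  structure(ll_bin + ll_mult, binomial = ll_bin, multinomial = ll_mult)
}

#' Binomial count-survey log likelihood
#'
#' Detection model for the simple-count alternative to encounter histories:
#' the count on one visit is `y ~ Binomial(N, p)` given `N` individuals
#' exposed to sampling.
#'
#' @param y observed count (`0 <= y <= N`).
#' @param N abundance exposed to sampling.
#' @param p individual detection probability in (0, 1].
#' @return Log likelihood (natural log).
#' @export
binomial_count_loglik <- function(y, N, p) {
  if (!all(is_count(y)) || !all(is_count(N)) || any(y > N))
    stop_invalid("y", "need integer 0 <= y <= N")
  if (any(p < 0) || any(p > 1)) stop_invalid("p", "p must lie in [0, 1]")
  stats::dbinom(y, N, p, log = TRUE)
}
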
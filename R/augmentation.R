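#' Augment a dataset with all-zero potential species
#'
#' Parameter-expanded data augmentation: `M` artificial species with all-zero
#' observation histories are appended to the dataset.  During fitting each
#' species carries a community-membership indicator `w_i ~ Bernoulli(Omega)`,
#' and the ecological process becomes zero-inflated
#' (`z_ij ~ Poisson(w_i * lambda_ij)` or `Binomial(tp_j, w_i * psi_ij)`), so
#' the regional species richness `S = sum(w_i)` is estimable up to the ceiling
#' `n_detected + M`.  `M` must exceed the plausible number of undetected
#' species; the fit warns when the posterior of `Omega` presses against 1
#' (see [fit_frequency_model()]).
#'
#' @param data a `comm_data` object.
#' @param M number of augmented species (>= 0).
#' @param prefix identifier prefix for the appended pseudo-species.
#' @return The augmented `comm_data` object; appended species have
#'   `augmented = TRUE` in `data$species` and no observation rows (their
#'   histories are implicitly all zero).
#' @export
augment_dataset <- function(data, M, prefix = "zz_aug_") {
  stopifnot(inherits(data, "comm_data"))
  if (!is_count(M)) stop_invalid("M", "M must be a nonnegative integer")
  if (M == 0) return(data)
  ids <- sprintf("%s%05d", prefix, seq_len(M))
  if (any(ids %in% data$species$species_id))
    stop_invalid("augment_clash", "augmented ids would clash with existing species")
  data$species <- rbind(data$species,
                        data.frame(species_id = ids, group = NA_character_,
                                   augmented = TRUE, stringsAsFactors = FALSE))
  data
}

#' Zero-inflated ecological process distribution
#'
#' The membership indicator `w` switches the patch-level state distribution
#' between a structural zero (`w = 0`: the species is not in the community,
#' `z = 0` with probability 1) and the base Poisson or binomial process
#' (`w = 1`: zeros are *sampling* zeros, possible but not certain).
#'
#' @param w membership indicator, 0 or 1.
#' @param theta base-distribution parameter: Poisson mean `lambda`, or
#'   occurrence probability `psi` for the binomial.
#' @param distribution `"poisson"` or `"binomial"`.
#' @param size binomial trial count `tp` (required for `"binomial"`).
#' @return A list of class `zi_dist` with elements `pmf(x)`, `sample(n, seed)`
#'   and `mean`.
#' @examples
#' zero_inflated_process(0, 2, "poisson")$pmf(0)   # 1: structural zero
#' zero_inflated_process(1, 2, "poisson")$pmf(0)   # exp(-2)
#' @export
zero_inflated_process <- function(w, theta,
                                  distribution = c("poisson", "binomial"),
                                  size = NULL) {
  distribution <- match.arg(distribution)
  if (!w %in% c(0, 1)) stop_invalid("w", "w must be 0 or 1")
  if (distribution == "binomial") {
    if (is.null(size) || !is_count(size))
      stop_invalid("size", "binomial process needs an integer size (tp)")
    if (theta < 0 || theta > 1) stop_invalid("psi", "psi must lie in [0, 1]")
  } else if (theta < 0) stop_invalid("lambda", "lambda must be nonnegative")
  pmf <- function(x) {
    if (w == 0) as.numeric(x == 0)
    else if (distribution == "poisson") stats::dpois(x, theta)
    else stats::dbinom(x, size, theta)
  }
  rnd <- function(n, seed = NULL) {
    if (w == 0) rep(0L, n)
    else with_seed(seed, if (distribution == "poisson") stats::rpois(n, theta)
                         else stats::rbinom(n, size, theta))
  }
  structure(list(pmf = pmf, sample = rnd,
                 mean = if (w == 0) 0
                        else if (distribution == "poisson") theta
                        else size * theta,
                 w = w, distribution = distribution),
            class = "zi_dist")
}

#' Posterior summary of regional species richness
#'
#' Regional richness is the derived parameter `S = sum_i w_i` per posterior
#' draw.  When latent-state draws are supplied, the undetected community
#' members in each draw are further partitioned into (a) species present on
#' at least one sampled patch (`z_ij > 0` somewhere) but undetected, and (b)
#' species in the community absent from every sampled patch; the two classes
#' sum to `S - n_detected` in every draw.
#'
#' @param w_draws binary matrix of membership draws (draws x species).
#' @param z_draws optional latent-state array (draws x species x patches).
#' @param detected optional logical vector marking detected species.
#' @param prob credible-interval mass (default 0.95).
#' @return List of class `richness_summary` with `S_draws`, `median`, `ci`,
#'   and (when partitioned) a data frame `undetected` with per-draw class
#'   counts.
#' @export
derive_regional_richness <- function(w_draws, z_draws = NULL, detected = NULL,
                                     prob = 0.95) {
  w_draws <- as.matrix(w_draws)
  if (nrow(w_draws) < 1) stop_invalid("draws", "need at least one draw")
  S_draws <- rowSums(w_draws)
  alpha <- (1 - prob) / 2
  out <- list(S_draws = S_draws,
              median = stats::median(S_draws),
              ci = stats::quantile(S_draws, c(alpha, 1 - alpha), names = FALSE))
  if (!is.null(z_draws) && !is.null(detected)) {
    stopifnot(dim(z_draws)[1] == nrow(w_draws),
              dim(z_draws)[2] == ncol(w_draws),
              length(detected) == ncol(w_draws))
    und <- which(!detected)
    present <- apply(z_draws[, und, , drop = FALSE] > 0, c(1, 2), any)
    memb <- w_draws[, und, drop = FALSE] > 0
    out$undetected <- data.frame(
      on_sampled_patches = rowSums(memb & present),
      off_sampled_patches = rowSums(memb & !present))
  }
  structure(out, class = "richness_summary")
}

#' @export
print.richness_summary <- function(x, ...) {
  cat(sprintf("Regional species richness S: median %g (95%% CI %g-%g), %d draws\n",
              x$median, x$ci[1], x$ci[2], length(x$S_draws)))
  if (!is.null(x$undetected))
    cat(sprintf("  undetected members per draw: %.1f on sampled patches, %.1f absent from them (means)\n",
                mean(x$undetected$on_sampled_patches),
                mean(x$undetected$off_sampled_patches)))
  invisible(x)
}
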
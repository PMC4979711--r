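# shared fixtures and oracles, all built in code

quick_cfg <- function(seed = 1, iters = 600, burn = 200, chains = 2,
                      thin = 2, adapt = 200, ...) {
  fit_config(chains = chains, iterations = iters, burn_in = burn,
             thin = thin, adapt = adapt, seed = seed, ...)
}

abund_data_2x2 <- function(visits = 3) {
  community_data(
    data.frame(patch_id = c("p1", "p2"), area_ha = c(1, 4), phi = c(1, 0.5),
               visits = visits),
    data.frame(species_id = c("spA", "spA", "spB"),
               patch_id = c("p1", "p2", "p1"),
               H = c(1, 2, 1), count = c(2, 1, 5)),
    mode = "abundance")
}

freq_data_2x2 <- function() {
  community_data(
    data.frame(patch_id = c("p1", "p2"), area_ha = c(1, 4), ap = c(4, 16),
               tp = c(100, 400)),
    data.frame(species_id = c("spA", "spA", "spB"),
               patch_id = c("p1", "p2", "p1"), y = c(2, 5, 1)),
    mode = "frequency")
}

# A posterior whose every draw is the same parameter vector; lets closed-form
# oracles be compared against the simulation-based derived quantities.
constant_posterior <- function(params, data, ndraws = 1, extra = list(),
                               null_model = FALSE) {
  m <- matrix(rep(unlist(params), each = ndraws), nrow = ndraws,
              dimnames = list(NULL, names(unlist(params))))
  colnames(m) <- names(flatten_params(params))
  ml <- coda::mcmc.list(coda::mcmc(m))
  commsar:::new_posterior(ml, data, quick_cfg(), "constant mock",
                          detected = rep(TRUE, nrow(data$species)),
                          null_model = null_model, extra = extra)
}

flatten_params <- function(params) {
  out <- list()
  for (nm in names(params)) {
    v <- params[[nm]]
    if (is.matrix(v)) {
      for (j in seq_len(ncol(v))) for (i in seq_len(nrow(v)))
        out[[sprintf("%s[%d,%d]", nm, i, j)]] <- v[i, j]
    } else if (length(v) > 1) {
      for (i in seq_along(v)) out[[sprintf("%s[%d]", nm, i)]] <- v[i]
    } else out[[nm]] <- v
  }
  unlist(out)
}

# comm_data shells sized to match mock posteriors
shell_data <- function(S, areas, mode = "abundance", ap = NULL, tp = NULL) {
  sp <- sprintf("sp%02d", seq_len(S))
  pa <- sprintf("p%02d", seq_along(areas))
  if (mode == "abundance")
    community_data(data.frame(patch_id = pa, area_ha = areas, phi = 1,
                              visits = 2),
                   data.frame(species_id = sp, patch_id = pa[1], H = 1,
                              count = 1),
                   mode = "abundance")
  else
    community_data(data.frame(patch_id = pa, area_ha = areas,
                              ap = ap %||% 1, tp = tp %||% NA),
                   data.frame(species_id = sp, patch_id = pa[1], y = 1),
                   mode = "frequency")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# chi-square goodness-of-fit p-value with expected-count pooling
gof_pvalue <- function(obs_counts, probs, min_expected = 5) {
  stopifnot(length(obs_counts) == length(probs))
  n <- sum(obs_counts)
  exp_counts <- n * probs
  # pool cells from the right until all expected counts are large enough
  while (length(exp_counts) > 2 && min(exp_counts) < min_expected) {
    k <- which.min(exp_counts)
    j <- if (k == length(exp_counts)) k - 1 else k + 1
    exp_counts[j] <- exp_counts[j] + exp_counts[k]
    obs_counts[j] <- obs_counts[j] + obs_counts[k]
    exp_counts <- exp_counts[-k]; obs_counts <- obs_counts[-k]
  }
  stat <- sum((obs_counts - exp_counts)^2 / exp_counts)
  stats::pchisq(stat, df = length(obs_counts) - 1, lower.tail = FALSE)
}
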
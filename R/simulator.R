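#' Design for a synthetic community simulation
#'
#' Describes the community and sampling design the generator emulates.
#' Abundance-mode defaults mirror a small-patch bird survey: 30 species on
#' 15 patches of 0.5-10 ha (log-spaced), 5 visits, full transect coverage
#' (`phi = 1`), constant density on average (`mu_beta1 = 1`, `sigma_beta1 =
#' 0.2`) and mean per-visit detection 0.5.  Frequency-mode defaults mirror a
#' sparse plant survey: 100 species on 10 patches of 1-10 ha sampled by
#' 1-m^2 plots at about 16 plots/ha, occurrence probabilities well below 1
#' and no area dependence on average.  A fraction `f_neg` of species are
#' "edge" species with a negative density-area relationship: their
#' area-scaling coefficient is shifted down by `dar_offset` (so e.g.
#' `beta1 = 1 - 0.5` for abundance, `0 - 0.3` for frequency).
#'
#' @param mode `"abundance"` or `"frequency"`.
#' @param n_species,n_patches community and design size.
#' @param area_min,area_max patch-area range (ha); patches are log-spaced.
#' @param areas optional explicit area vector overriding the range.
#' @param hyper an [abundance_hyperparams()] or [frequency_hyperparams()]
#'   object (mode-matching default if `NULL`).
#' @param visits number of repeat visits (abundance mode).
#' @param phi sampled fraction per patch, recycled (abundance mode).
#' @param ap_per_ha sampled-plot density (frequency mode); `ap` is capped at
#'   `tp`.
#' @param plot_area_m2 plot size (frequency mode).
#' @param f_neg fraction of species with a negative density-area
#'   relationship, in \[0, 1\].
#' @param dar_offset downward shift of `beta1` for those species.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(mode = c("abundance", "frequency"),
                              n_species = NULL, n_patches = NULL,
                              area_min = NULL, area_max = NULL, areas = NULL,
                              hyper = NULL, visits = 5, phi = 1,
                              ap_per_ha = 16, plot_area_m2 = 1,
                              f_neg = 0, dar_offset = NULL) {
  mode <- match.arg(mode)
  if (mode == "abundance") {
    n_species <- n_species %||% 30
    n_patches <- n_patches %||% 15
    area_min <- area_min %||% 0.5
    area_max <- area_max %||% 10
    hyper <- hyper %||% abundance_hyperparams()
    dar_offset <- dar_offset %||% 0.5
    stopifnot(inherits(hyper, "abundance_hyperparams"))
  } else {
    n_species <- n_species %||% 100
    n_patches <- n_patches %||% 10
    area_min <- area_min %||% 1
    area_max <- area_max %||% 10
    hyper <- hyper %||% frequency_hyperparams()
    dar_offset <- dar_offset %||% 0.3
    stopifnot(inherits(hyper, "frequency_hyperparams"))
  }
  areas <- areas %||% exp(seq(log(area_min), log(area_max),
                              length.out = n_patches))
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop_invalid("area", "patch areas must be positive")
  if (length(areas) != n_patches)
    stop_invalid("area", "length(areas) must equal n_patches")
  if (!is.numeric(f_neg) || f_neg < 0 || f_neg > 1)
    stop_invalid("f_neg", "f_neg must lie in [0, 1]")
  if (!is_count(n_species) || n_species < 1 || !is_count(n_patches) ||
      n_patches < 1)
    stop_invalid("design", "n_species and n_patches must be positive integers")
  structure(list(mode = mode, n_species = n_species, n_patches = n_patches,
                 areas = areas, hyper = hyper, visits = visits, phi = phi,
                 ap_per_ha = ap_per_ha, plot_area_m2 = plot_area_m2,
                 f_neg = f_neg, dar_offset = dar_offset),
            class = "simulation_design")
}

#' Simulate a community survey dataset
#'
#' Generates a synthetic community from the full generative chain of the
#' hierarchical models — species-level coefficients from the community
#' hyperdistributions, random site effects, latent abundances or plot
#' frequencies, binomial coverage thinning, and multinomial encounter or
#' plot-subsampling observation — and packages the observations of the
#' *detected* species as a validated [community_data()] dataset, retaining
#' the full truth for recovery scoring.  In frequency mode the observed
#' frequency is drawn hypergeometrically given the patch-level frequency
#' (a random `ap`-subset of the `tp` plots), whose marginal is the
#' `Binomial(ap, psi)` sampling model.
#'
#' @param design a [simulation_design()].
#' @param seed optional seed; fixed seed gives byte-identical output.
#' @param keep_undetected if `TRUE`, all-zero rows for undetected species
#'   are kept in the observation table (their histories are then explicit
#'   rather than implicit).
#' @return A list of class `simulated_community`: `data` (a `comm_data` of
#'   the detected species), `truth` (list with `species_id`, `beta0`,
#'   `beta1`, `p` or `group`, site effects `b`, latent `z`, `N`, `S_true`,
#'   and the negative-DAR flags), `design`, `seed`.
#' @export
simulate_community <- function(design, seed = NULL, keep_undetected = FALSE) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(seed, {
    S <- design$n_species
    J <- design$n_patches
    areas <- design$areas
    sp_ids <- sprintf("sp_%04d", seq_len(S))
    pa_ids <- sprintf("patch_%03d", seq_len(J))
    n_neg <- round(design$f_neg * S)
    neg <- rep(FALSE, S)
    neg[sample.int(S, n_neg)] <- TRUE
    h <- design$hyper

    if (design$mode == "abundance") {
      par <- sample_species_params(h, S, n_patches = J)
      par$beta1[neg] <- par$beta1[neg] - design$dar_offset
      z <- sample_latent_abundance(par, areas)
      phi <- rep_len(design$phi, J)
      N <- thin_to_sampled(z, phi)
      tvis <- design$visits
      rows <- vector("list", S * J)
      k <- 0L
      for (i in seq_len(S)) {
        cp <- stats::dbinom(0:tvis, tvis, par$p[i])
        for (j in seq_len(J)) {
          freq <- if (N[i, j] > 0)
            as.vector(stats::rmultinom(1, N[i, j], cp))[-1] else integer(tvis)
          hpos <- which(freq > 0)
          if (length(hpos)) {
            k <- k + 1L
            rows[[k]] <- data.frame(species_id = sp_ids[i],
                                    patch_id = pa_ids[j],
                                    H = hpos, count = freq[hpos])
          }
        }
      }
      obs <- if (k) do.call(rbind, rows[seq_len(k)])
             else data.frame(species_id = character(), patch_id = character(),
                             H = integer(), count = integer())
      det <- sp_ids %in% obs$species_id
      if (keep_undetected && any(!det))
        obs <- rbind(obs, data.frame(species_id = sp_ids[!det],
                                     patch_id = pa_ids[1], H = 1L,
                                     count = 0L))
      patches <- data.frame(patch_id = pa_ids, area_ha = areas, phi = phi,
                            visits = tvis)
      data <- community_data(patches, obs, mode = "abundance")
      truth <- list(species_id = sp_ids, beta0 = par$beta0, beta1 = par$beta1,
                    p = par$p, b = par$b, z = z, N = N, S_true = S,
                    negative_dar = neg, detected = det, hyper = h)
    } else {
      G <- length(h$mu_beta0)
      grp <- sample.int(G, S, replace = TRUE, prob = h$group_props)
      beta0 <- stats::rnorm(S, h$mu_beta0[grp], h$sigma_beta0[grp])
      beta1 <- stats::rnorm(S, h$mu_beta1[grp], h$sigma_beta1[grp])
      beta1[neg] <- beta1[neg] - design$dar_offset
      b <- matrix(stats::rnorm(S * J, 0, h$sigma_b), S, J)
      tp <- total_plots(areas, design$plot_area_m2)
      ap <- pmin(pmax(1L, as.integer(round(design$ap_per_ha * areas))), tp)
      psi <- inv_logit(outer(beta0, rep(1, J)) + outer(beta1, areas) + b)
      z <- matrix(stats::rbinom(S * J, rep(tp, each = S), as.vector(psi)),
                  S, J)
      # observed plots are a random ap-subset of the tp tessellating plots
      y <- matrix(stats::rhyper(S * J, m = as.vector(z),
                                n = rep(tp, each = S) - as.vector(z),
                                k = rep(ap, each = S)), S, J)
      det <- rowSums(y) > 0
      keep <- det | keep_undetected
      idx <- which(y > 0 | outer(!det & keep_undetected, rep(TRUE, J)),
                   arr.ind = TRUE)
      obs <- data.frame(species_id = sp_ids[idx[, 1]],
                        patch_id = pa_ids[idx[, 2]],
                        y = y[idx])
      patches <- data.frame(patch_id = pa_ids, area_ha = areas, ap = ap,
                            tp = tp)
      groups <- if (G > 1)
        data.frame(species_id = sp_ids[keep],
                   group = h$group_names[grp[keep]])
      data <- community_data(patches, obs, mode = "frequency",
                             groups = groups,
                             plot_area_m2 = design$plot_area_m2)
      truth <- list(species_id = sp_ids, beta0 = beta0, beta1 = beta1,
                    group = h$group_names[grp], b = b, psi = psi, z = z,
                    y_full = y, S_true = S, negative_dar = neg,
                    detected = det, hyper = h)
    }
    structure(list(data = data, truth = truth, design = design, seed = seed),
              class = "simulated_community")
  })
}

#' @export
print.simulated_community <- function(x, ...) {
  cat(sprintf("<simulated_community> %s: %d true species (%d detected) x %d patches\n",
              x$design$mode, x$truth$S_true, sum(x$truth$detected),
              x$design$n_patches))
  invisible(x)
}

#' How the mixture of density-area relationships shapes the SAR
#'
#' Monte-Carlo experiment: communities are drawn repeatedly for each value
#' of `f_neg` (the fraction of species with a negative density-area or
#' occurrence-area relationship), the noise-free expected richness curve is
#' computed over the patch-area grid — `sum_i (1 - exp(-lambda_i(A)))` for
#' abundance designs, `sum_i (1 - (1 - psi_i(A))^{tp(A)})` for frequency
#' designs — and the SAR "slope" is the least-squares slope of log expected
#' richness on log area.  Communities richer in negative-DAR (edge) species
#' are expected to show flatter SARs.
#'
#' @param design a [simulation_design()]; its `f_neg` is overridden by the
#'   grid.  Site effects are ignored here (the ecological signal is
#'   isolated from patch-level noise).
#' @param f_neg_grid values of `f_neg` to compare (at least one; the
#'   area grid must have at least two areas).
#' @param replicates simulated communities per grid value.
#' @param seed master seed; every replicate draws from its own derived
#'   stream.
#' @param use_sampled if `TRUE`, slopes are computed on one realized
#'   (Poisson/binomial) richness draw instead of the expectation.
#' @return Data frame of class `dar_experiment` with columns `design` (grid
#'   position), `f_neg`, `replicate`, `slope`; attribute `"summary"` holds
#'   mean slope and Monte-Carlo standard error per grid entry.
#' @export
run_dar_experiment <- function(design, f_neg_grid, replicates = 50, seed = 1,
                               use_sampled = FALSE) {
  stopifnot(inherits(design, "simulation_design"))
  if (length(design$areas) < 2)
    stop_invalid("grid", "the area grid must contain at least two areas")
  if (!length(f_neg_grid))
    stop_invalid("f_neg", "f_neg_grid must be nonempty")
  if (!is_count(replicates) || replicates < 1)
    stop_invalid("replicates", "replicates must be a positive integer")
  seeds <- matrix(spawn_seeds(seed, length(f_neg_grid) * replicates),
                  replicates, length(f_neg_grid))
  areas <- design$areas
  logA <- log(areas)
  h <- design$hyper
  S <- design$n_species
  slope_one <- function(f_neg, sd_seed) {
    with_seed(sd_seed, {
      neg <- rep(FALSE, S)
      neg[sample.int(S, round(f_neg * S))] <- TRUE
      if (design$mode == "abundance") {
        beta0 <- stats::rnorm(S, h$mu_beta0, h$sigma_beta0)
        beta1 <- stats::rnorm(S, h$mu_beta1, h$sigma_beta1)
        beta1[neg] <- beta1[neg] - design$dar_offset
        lam <- exp(outer(beta0, rep(1, length(areas))) + outer(beta1, logA))
        es <- if (use_sampled)
          colSums(matrix(stats::rpois(length(lam), lam), S) > 0)
        else colSums(1 - exp(-lam))
      } else {
        G <- length(h$mu_beta0)
        grp <- sample.int(G, S, replace = TRUE, prob = h$group_props)
        beta0 <- stats::rnorm(S, h$mu_beta0[grp], h$sigma_beta0[grp])
        beta1 <- stats::rnorm(S, h$mu_beta1[grp], h$sigma_beta1[grp])
        beta1[neg] <- beta1[neg] - design$dar_offset
        tp <- total_plots(areas, design$plot_area_m2)
        psi <- inv_logit(outer(beta0, rep(1, length(areas))) +
                           outer(beta1, areas))
        es <- if (use_sampled)
          colSums(matrix(stats::rbinom(length(psi), rep(tp, each = S),
                                       as.vector(psi)), S) > 0)
        else colSums(1 - (1 - psi)^rep(tp, each = S))
      }
      if (any(es <= 0)) return(NA_real_)
      unname(stats::coef(stats::lm(log(es) ~ logA))[2])
    })
  }
  out <- do.call(rbind, lapply(seq_along(f_neg_grid), function(gi)
    data.frame(design = gi, f_neg = f_neg_grid[gi],
               replicate = seq_len(replicates),
               slope = vapply(seq_len(replicates), function(r)
                 slope_one(f_neg_grid[gi], seeds[r, gi]), 0))))
  sm <- do.call(rbind, lapply(split(out, out$design), function(d)
    data.frame(design = d$design[1], f_neg = d$f_neg[1],
               mean_slope = mean(d$slope),
               mc_se = stats::sd(d$slope) / sqrt(nrow(d)))))
  rownames(sm) <- NULL
  structure(out, summary = sm, class = c("dar_experiment", "data.frame"))
}

#' @export
print.dar_experiment <- function(x, ...) {
  cat("DAR -> SAR experiment (log-log slope of expected richness on area)\n")
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}

#' Score parameter recovery of a fit against simulation truth
#'
#' Matches the fitted species to the simulation truth by identifier and
#' reports, per parameter family, the mean bias of the posterior medians,
#' their RMSE, and the empirical coverage of the central 95% credible
#' intervals; hyperparameters are scored against the design values, and
#' regional richness (when augmentation was used) against the true `S`.
#' Zero-width intervals (degenerate draws) are reported so their nominal
#' coverage can be discounted.
#'
#' @param sim a `simulated_community` (or its `truth` list).
#' @param post the `community_posterior` fitted to `sim$data`.
#' @param prob credible mass for the coverage intervals.
#' @return Data frame with columns `parameter`, `n`, `bias`, `rmse`,
#'   `coverage`, `zero_width`.
#' @export
score_recovery <- function(sim, post, prob = 0.95) {
  truth <- if (inherits(sim, "simulated_community")) sim$truth else sim
  stopifnot(inherits(post, "community_posterior"))
  alpha <- (1 - prob) / 2
  score_vec <- function(draws, true_vals) {
    med <- apply(draws, 2, stats::median)
    lo <- apply(draws, 2, stats::quantile, alpha)
    hi <- apply(draws, 2, stats::quantile, 1 - alpha)
    data.frame(n = length(true_vals),
               bias = mean(med - true_vals),
               rmse = sqrt(mean((med - true_vals)^2)),
               coverage = mean(true_vals >= lo & true_vals <= hi),
               zero_width = mean(hi == lo))
  }
  ids <- post$species$species_id[!post$species$augmented]
  ti <- match(ids, truth$species_id)
  if (anyNA(ti))
    stop_invalid("match", "fitted species '%s' absent from simulation truth",
                 ids[which(is.na(ti))[1]])
  fams <- c("beta0", "beta1", if (post$mode == "abundance") "p")
  rows <- lapply(fams, function(f) {
    dr <- extract_draws(post, f)
    if (is.null(dim(dr))) dr <- matrix(dr, length(dr), length(ids))
    else dr <- dr[, match(ids, post$species$species_id), drop = FALSE]
    cbind(parameter = f, score_vec(dr, truth[[f]][ti]))
  })
  h <- truth$hyper
  hyper_map <- if (post$mode == "abundance")
    c(mu.beta0 = h$mu_beta0, mu.beta1 = h$mu_beta1, mu.lp = h$mu_lp)
  else c(mu.beta0 = mean(h$mu_beta0), mu.beta1 = mean(h$mu_beta1))
  for (nm in names(hyper_map)) {
    dr <- try(extract_draws(post, nm), silent = TRUE)
    if (inherits(dr, "try-error")) next
    if (!is.null(dim(dr))) dr <- rowMeans(dr)  # group-mean average
    rows <- c(rows, list(cbind(parameter = nm,
                               score_vec(matrix(dr), hyper_map[[nm]]))))
  }
  if (isTRUE(post$augmented) && !is.null(truth$S_true)) {
    sd_ <- extract_draws(post, "S.rich")
    rows <- c(rows, list(cbind(parameter = "S",
                               score_vec(matrix(sd_), truth$S_true))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
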
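#' MCMC configuration for model fitting
#'
#' Settings for the JAGS run and the (configurable) hyperpriors.  Defaults:
#' 3 chains, 20000 iterations of which 10000 burn-in, thin 10; community
#' means `~ Normal(0, 10^2)`, standard deviations `~ Uniform(0, 10)`,
#' inclusion probability `Omega ~ Uniform(0, 1)`, flat `Dirichlet(1, ..., 1)`
#' over groups.  The retained draw count is
#' `chains * (iterations - burn_in) / thin`.
#'
#' @param chains number of chains (>= 2 recommended for diagnostics).
#' @param iterations post-adaptation iterations per chain, including burn-in.
#' @param burn_in discarded initial iterations per chain (< `iterations`).
#' @param thin thinning interval.
#' @param adapt JAGS adaptation steps.
#' @param seed master seed; per-chain RNG seeds are derived from it, so a
#'   fit is exactly reproducible given the same config and data.
#' @param priors named list overriding any of `mu_mean`, `mu_sd`
#'   (hyper-mean prior), `sigma_upper` (upper bound of the uniform sd
#'   priors), `dirichlet_alpha` (group prior concentration).
#' @param warn_omega warn after fitting when the upper 95% bound of the
#'   posterior of `Omega` exceeds this value, the symptom that the augmented
#'   species pool `M` is too small (or richness is non-identifiable).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(chains = 3, iterations = 20000, burn_in = 10000,
                       thin = 10, adapt = 1000, seed = 1, priors = list(),
                       warn_omega = 0.95) {
  stopifnot(is_count(chains), chains >= 1, is_count(iterations),
            is_count(burn_in), is_count(thin), thin >= 1, is_count(adapt))
  if (burn_in >= iterations)
    stop_invalid("burn_in", "burn_in (%d) must be < iterations (%d)",
                 burn_in, iterations)
  defaults <- list(mu_mean = 0, mu_sd = 10, sigma_upper = 10,
                   dirichlet_alpha = 1)
  unknown <- setdiff(names(priors), names(defaults))
  if (length(unknown))
    stop_invalid("priors", "unknown prior setting(s): %s",
                 paste(unknown, collapse = ", "))
  defaults[names(priors)] <- priors
  structure(list(chains = chains, iterations = iterations, burn_in = burn_in,
                 thin = thin, adapt = adapt, seed = seed, priors = defaults,
                 warn_omega = warn_omega),
            class = "fit_config")
}

# ---- model-string builders ------------------------------------------------

hyperprior_lines <- function(priors) {
  sprintf("  # hyper-mean prior Normal(%g, %g^2); sd prior Uniform(0, %g)",
          priors$mu_mean, priors$mu_sd, priors$sigma_upper)
}

abundance_model_string <- function(t, thinning, augmented, null_model,
                                   ncov, priors) {
  mu <- sprintf("dnorm(%g, %g)", priors$mu_mean, 1 / priors$mu_sd^2)
  su <- sprintf("dunif(0, %g)", priors$sigma_upper)
  lam <- paste0("beta0[i] + beta1[i] * logA[j]",
                if (ncov > 0) " + inprod(X[j, ], bcov[i, ])" else "",
                " + b[i, j]")
  c("model {",
    "  for (i in 1:S) {",
    "    beta0[i] ~ dnorm(mu.beta0, tau.beta0)",
    if (null_model) "    beta1[i] <- 1"
    else "    beta1[i] ~ dnorm(mu.beta1, tau.beta1)",
    "    lp[i] ~ dnorm(mu.lp, tau.lp)",
    "    logit(p[i]) <- lp[i]",
    "    pstar[i] <- 1 - pow(1 - p[i], nvisits)",
    if (t > 1) c(
    "    for (h in 1:nvisits) {",
    "      pic[i, h] <- exp(logdensity.bin(h, p[i], nvisits)) / pstar[i]",
    "    }"),
    if (augmented) "    w[i] ~ dbern(Omega)",
    if (ncov > 0) c(
    "    for (k in 1:K) { bcov[i, k] ~ dnorm(mu.cov[k], tau.cov[k]) }"),
    "    for (j in 1:J) {",
    "      b[i, j] ~ dnorm(0, tau.site)",
    sprintf("      log(lambda[i, j]) <- %s", lam),
    if (augmented) "      z[i, j] ~ dpois(lambda[i, j] * w[i])"
    else "      z[i, j] ~ dpois(lambda[i, j])",
    if (thinning) "      N[i, j] ~ dbin(phi[j], z[i, j])"
    else "      N[i, j] <- z[i, j]",
    "      n[i, j] ~ dbin(pstar[i], N[i, j])",
    if (t > 1) "      y[i, j, 1:nvisits] ~ dmulti(pic[i, 1:nvisits], n[i, j])",
    "    }",
    "  }",
    hyperprior_lines(priors),
    sprintf("  mu.beta0 ~ %s", mu),
    sprintf("  sd.beta0 ~ %s", su),
    "  tau.beta0 <- pow(sd.beta0, -2)",
    if (!null_model) c(
    sprintf("  mu.beta1 ~ %s", mu),
    sprintf("  sd.beta1 ~ %s", su),
    "  tau.beta1 <- pow(sd.beta1, -2)"),
    sprintf("  mu.lp ~ %s", mu),
    sprintf("  sd.lp ~ %s", su),
    "  tau.lp <- pow(sd.lp, -2)",
    sprintf("  sd.site ~ %s", su),
    "  tau.site <- pow(sd.site, -2)",
    if (ncov > 0) c(
    "  for (k in 1:K) {",
    sprintf("    mu.cov[k] ~ %s", mu),
    sprintf("    sd.cov[k] ~ %s", su),
    "    tau.cov[k] <- pow(sd.cov[k], -2)",
    "  }"),
    if (augmented) c(
    "  Omega ~ dunif(0, 1)",
    "  S.rich <- sum(w[1:S])"),
    "}")
}

frequency_model_string <- function(G, augmented, null_model, ncov, priors,
                                   constant_psi = FALSE) {
  if (constant_psi) {
    return(c("model {",
             "  # degenerate validation mode: one flat Beta(1,1) occurrence",
             "  # probability per species, no area term, no site effects",
             "  for (i in 1:S) {",
             "    psi0[i] ~ dbeta(1, 1)",
             "    for (j in 1:J) { y[i, j] ~ dbin(psi0[i], ap[j]) }",
             "  }",
             "}"))
  }
  mu <- sprintf("dnorm(%g, %g)", priors$mu_mean, 1 / priors$mu_sd^2)
  su <- sprintf("dunif(0, %g)", priors$sigma_upper)
  idx <- if (G > 1) "[g[i]]" else ""
  hk <- if (G > 1) "[k]" else ""
  eta <- paste0("beta0[i] + beta1[i] * A[j]",
                if (ncov > 0) " + inprod(X[j, ], bcov[i, ])" else "",
                " + b[i, j]")
  hyper_block <- c(
    sprintf("  mu.beta0%s ~ %s", hk, mu),
    sprintf("  sd.beta0%s ~ %s", hk, su),
    sprintf("  tau.beta0%s <- pow(sd.beta0%s, -2)", hk, hk),
    if (!null_model) c(
      sprintf("  mu.beta1%s ~ %s", hk, mu),
      sprintf("  sd.beta1%s ~ %s", hk, su),
      sprintf("  tau.beta1%s <- pow(sd.beta1%s, -2)", hk, hk)))
  c("model {",
    "  for (i in 1:S) {",
    if (augmented) "    w[i] ~ dbern(Omega)",
    if (G > 1) "    g[i] ~ dcat(pg[1:G])",
    sprintf("    beta0[i] ~ dnorm(mu.beta0%s, tau.beta0%s)", idx, idx),
    if (null_model) "    beta1[i] <- 0"
    else sprintf("    beta1[i] ~ dnorm(mu.beta1%s, tau.beta1%s)", idx, idx),
    if (ncov > 0)
    "    for (k in 1:K) { bcov[i, k] ~ dnorm(mu.cov[k], tau.cov[k]) }",
    "    for (j in 1:J) {",
    "      b[i, j] ~ dnorm(0, tau.site)",
    sprintf("      logit(psi[i, j]) <- %s", eta),
    if (augmented) "      y[i, j] ~ dbin(psi[i, j] * w[i], ap[j])"
    else "      y[i, j] ~ dbin(psi[i, j], ap[j])",
    "    }",
    "  }",
    hyperprior_lines(priors),
    if (G > 1) c("  for (k in 1:G) {", hyper_block, "  }") else hyper_block,
    if (G > 1)
    "  pg[1:G] ~ ddirch(alpha[1:G])",
    if (ncov > 0) c(
    "  for (k in 1:K) {",
    sprintf("    mu.cov[k] ~ %s", mu),
    sprintf("    sd.cov[k] ~ %s", su),
    "    tau.cov[k] <- pow(sd.cov[k], -2)",
    "  }"),
    sprintf("  sd.site ~ %s", su),
    "  tau.site <- pow(sd.site, -2)",
    if (augmented) c(
    "  Omega ~ dunif(0, 1)",
    "  S.rich <- sum(w[1:S])"),
    "}")
}

run_jags <- function(model_lines, data, inits_builder, monitors, config) {
  seeds <- spawn_seeds(config$seed, config$chains)
  inits <- lapply(seq_len(config$chains), function(ch)
    c(inits_builder(ch),
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = seeds[ch])))
  con <- textConnection(paste(model_lines, collapse = "\n"))
  on.exit(close(con), add = TRUE)
  jm <- rjags::jags.model(con, data = data, inits = inits,
                          n.chains = config$chains, n.adapt = config$adapt,
                          quiet = TRUE)
  if (config$burn_in > 0)
    stats::update(jm, config$burn_in, progress.bar = "none")
  rjags::coda.samples(jm, monitors,
                      n.iter = config$iterations - config$burn_in,
                      thin = config$thin, progress.bar = "none")
}

new_posterior <- function(samples, data, config, model_lines, detected,
                          null_model, extra = list()) {
  structure(c(list(samples = samples, mode = data$mode, data = data,
                   species = data$species, patches = data$patches,
                   detected = detected, config = config,
                   null_model = null_model,
                   model = paste(model_lines, collapse = "\n")),
              extra),
            class = "community_posterior")
}

check_omega <- function(post) {
  om <- try(extract_draws(post, "Omega"), silent = TRUE)
  if (inherits(om, "try-error")) return(invisible(post))
  up <- stats::quantile(om, 0.975, names = FALSE)
  if (up > post$config$warn_omega)
    warning(sprintf(paste0("upper 95%% bound of Omega is %.3f: the augmented ",
                           "pool M may be too small, or regional richness is ",
                           "weakly identified; consider increasing M or ",
                           "fitting without augmentation"), up),
            call. = FALSE)
  invisible(post)
}

#' Fit the hierarchical multispecies abundance model
#'
#' Bayesian fit (MCMC via JAGS) of the community abundance model: Poisson
#' latent patch-level abundance with species-specific log-link area scaling
#' and random site effects, binomial thinning to the sampled fraction
#' `phi_j` of each patch, and multinomial encounter-frequency detection over
#' `t` repeated visits, reparameterized by conditioning on encounter (the
#' total detected is `Binomial(N, 1 - (1-p)^t)` and the frequencies over
#' `H >= 1` are multinomial on the conditional cell probabilities).
#' Species-level coefficients and logit-scale detection probabilities are
#' drawn from community normal hyperdistributions.  If the dataset contains
#' augmented (or otherwise never-detected) species, community-membership
#' indicators `w_i ~ Bernoulli(Omega)` zero-inflate the Poisson process and
#' regional richness `S.rich = sum(w)` is monitored.
#'
#' All patches must share one visit count `t`; detection requires `t >= 1`
#' repeat visits (with `t = 1` the multinomial term is degenerate and only
#' the binomial total is informative).
#'
#' @param data an abundance-mode `comm_data` object.
#' @param config a [fit_config()].
#' @param covariates optional numeric matrix of patch covariates (rows in
#'   the sorted patch order); per-species coefficients get their own normal
#'   hyperdistributions.
#' @param null_model if `TRUE`, fixes every `beta1_i = 1` (constant density)
#'   with `sigma_beta1 = 0`, retaining random site effects.
#' @param augment `"auto"` turns on the membership indicators and `Omega`
#'   whenever the dataset contains species without detections (augmented or
#'   otherwise); `"none"` fits without augmentation — every species is taken
#'   to be a community member, the choice appropriate when the species pool
#'   is known from expert knowledge.
#' @return A `community_posterior` object; see [extract_draws()],
#'   [diagnostics()], [derive_patch_summaries()], [predict_sar_curve()].
#' @references The monitored nodes include species coefficients (`beta0`,
#'   `beta1`), detection (`p`), latent states (`z`, `N`), hyperparameters and,
#'   under augmentation, `w`, `Omega` and `S.rich`.
#' @export
fit_abundance_model <- function(data, config = fit_config(),
                                covariates = NULL, null_model = FALSE,
                                augment = c("auto", "none")) {
  augment <- match.arg(augment)
  stopifnot(inherits(data, "comm_data"))
  if (data$mode != "abundance")
    stop_invalid("mode", "fit_abundance_model needs an abundance-mode dataset")
  stopifnot(inherits(config, "fit_config"))
  enc <- encounter_array(data)
  t_all <- unique(data$patches$visits)
  if (length(t_all) != 1L)
    stop_invalid("visits", "fitting requires a single visit count across patches (got %s)",
                 paste(t_all, collapse = ", "))
  tvis <- as.integer(t_all)
  S <- nrow(data$species)
  J <- nrow(data$patches)
  detected <- detected_species(data)
  augmented <- augment == "auto" && any(!detected)
  if (augmented && any(!detected & !data$species$augmented))
    warning("species with no detections supplied as observed rows are treated as augmented (membership estimated)",
            call. = FALSE)
  thinning <- any(data$patches$phi < 1)
  ncov <- if (is.null(covariates)) 0L else ncol(covariates)

  jd <- list(S = S, J = J, nvisits = tvis, logA = log(data$patches$area_ha),
             n = enc$n)
  if (tvis > 1) jd$y <- enc$y
  if (thinning) jd$phi <- data$patches$phi
  if (augmented) jd$w <- ifelse(detected, 1, NA)
  if (ncov > 0) { jd$X <- as.matrix(covariates); jd$K <- ncov }

  lines <- abundance_model_string(tvis, thinning, augmented, null_model,
                                  ncov, config$priors)
  inits_builder <- function(ch) {
    s_ini <- min(1, config$priors$sigma_upper / 2)
    z_ini <- enc$n + if (thinning) 2L else 1L
    if (augmented) z_ini[!detected, ] <- 0L  # consistent with w = 0 starts
    ini <- list(mu.beta0 = 0, sd.beta0 = s_ini, mu.lp = 0, sd.lp = s_ini,
                sd.site = s_ini / 2, z = z_ini)
    if (!null_model) { ini$mu.beta1 <- min(1, config$priors$mu_sd)
                       ini$sd.beta1 <- s_ini / 2 }
    if (thinning) ini$N <- enc$n
    if (augmented) {
      ini$w <- ifelse(detected, NA_real_, 0)
      ini$Omega <- (sum(detected) + 1) / (S + 2)
    }
    ini
  }
  monitors <- c("beta0", "beta1", "p", "z", "N", "mu.beta0", "sd.beta0",
                "mu.lp", "sd.lp", "sd.site",
                if (!null_model) c("mu.beta1", "sd.beta1"),
                if (augmented) c("w", "Omega", "S.rich"),
                if (ncov > 0) c("bcov", "mu.cov", "sd.cov"))
  samples <- run_jags(lines, jd, inits_builder, monitors, config)
  post <- new_posterior(samples, data, config, lines, detected, null_model,
                        extra = list(visits = tvis, augmented = augmented))
  check_omega(post)
  post
}

#' Fit the hierarchical multispecies frequency model
#'
#' Bayesian fit (MCMC via JAGS) of the community frequency model for
#' plot-based surveys: the observed frequency of species `i` among the
#' `ap_j` sampled plots of patch `j` is `y_ij ~ Binomial(ap_j, psi_ij)` with
#' a logit-linear occurrence-area relationship and random site effects;
#' detection within plots is assumed perfect.  When a species-group table is
#' present, intercepts and slopes get separate normal hyperdistributions per
#' group, group proportions get a Dirichlet prior, and augmented species are
#' assigned to groups categorically within the MCMC.  Augmented species
#' carry membership indicators `w_i ~ Bernoulli(Omega)` zero-inflating the
#' binomial, and regional richness `S.rich = sum(w)` is monitored.
#' Patch-level frequency over the full tessellation (`tp_j` plots) is
#' reconstructed posterior-predictively by [derive_patch_summaries()].
#'
#' @param data a frequency-mode `comm_data` object.
#' @param config a [fit_config()].
#' @param covariates optional patch covariate matrix, as in
#'   [fit_abundance_model()].
#' @param augment `"auto"` or `"none"`, as in [fit_abundance_model()].
#' @param null_model if `TRUE`, fixes every `beta1_i = 0` (occurrence
#'   probability independent of area) with `sigma_beta1 = 0`, retaining
#'   random site effects.
#' @param standardize_area if `TRUE`, the sampler works on area standardized
#'   to mean 0 / sd 1 and species-level coefficients and hyper-means are
#'   transformed back to the hectare scale afterwards (the back-transformed
#'   intercept hyper-sd combines the two component sds).
#' @param constant_psi degenerate validation mode: a single flat Beta(1, 1)
#'   occurrence probability per species, no area term, no site effects, no
#'   hyperstructure.  Used to check the sampling machinery against the
#'   conjugate beta-binomial posterior.
#' @return A `community_posterior` object.
#' @export
fit_frequency_model <- function(data, config = fit_config(),
                                covariates = NULL, null_model = FALSE,
                                standardize_area = FALSE,
                                constant_psi = FALSE,
                                augment = c("auto", "none")) {
  augment <- match.arg(augment)
  stopifnot(inherits(data, "comm_data"))
  if (data$mode != "frequency")
    stop_invalid("mode", "fit_frequency_model needs a frequency-mode dataset")
  stopifnot(inherits(config, "fit_config"))
  y <- occurrence_matrix(data)
  S <- nrow(data$species)
  J <- nrow(data$patches)
  detected <- detected_species(data)

  if (constant_psi) {
    jd <- list(S = S, J = J, y = y, ap = as.integer(data$patches$ap))
    lines <- frequency_model_string(1, FALSE, FALSE, 0, config$priors,
                                    constant_psi = TRUE)
    samples <- run_jags(lines, jd, function(ch) list(), "psi0", config)
    return(new_posterior(samples, data, config, lines, detected, FALSE,
                         extra = list(constant_psi = TRUE, augmented = FALSE)))
  }

  augmented <- augment == "auto" && any(!detected)
  if (augmented && any(!detected & !data$species$augmented))
    warning("species with no detections supplied as observed rows are treated as augmented (membership estimated)",
            call. = FALSE)
  glev <- sort(unique(stats::na.omit(data$species$group)))
  G <- max(1L, length(glev))
  ncov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (null_model) standardize_area <- FALSE
  A <- data$patches$area_ha
  a_center <- 0; a_scale <- 1
  if (standardize_area) {
    a_center <- mean(A); a_scale <- stats::sd(A)
    if (!is.finite(a_scale) || a_scale == 0) a_scale <- 1
    A <- (A - a_center) / a_scale
  }

  jd <- list(S = S, J = J, y = y, ap = as.integer(data$patches$ap), A = A)
  if (augmented) jd$w <- ifelse(detected, 1, NA)
  if (G > 1) {
    jd$G <- G
    jd$alpha <- rep(config$priors$dirichlet_alpha, G)
    jd$g <- match(data$species$group, glev)  # NA for ungrouped/augmented
  }
  if (ncov > 0) { jd$X <- as.matrix(covariates); jd$K <- ncov }

  lines <- frequency_model_string(G, augmented, null_model, ncov,
                                  config$priors)
  rep_g <- function(x) if (G > 1) rep(x, G) else x
  # data-informed starts: species-level logit occurrence rates put the
  # intercept hyperparameters straight into the data's region, which cuts
  # the burn-in transient dramatically for sparse augmented communities
  rate <- (rowSums(y) + 0.5) / (sum(data$patches$ap) + 1)
  lg0 <- qlogis(pmin(pmax(rate, 1e-6), 1 - 1e-6))
  inits_builder <- function(ch) {
    s_ini <- min(1, config$priors$sigma_upper / 2)
    mu0 <- if (any(detected)) mean(lg0[detected]) else -2
    sd0 <- min(max(0.5, if (sum(detected) > 1) stats::sd(lg0[detected]) else 1),
               config$priors$sigma_upper * 0.9)
    ini <- list(mu.beta0 = rep_g(mu0), sd.beta0 = rep_g(sd0),
                beta0 = lg0, sd.site = s_ini / 2)
    if (!null_model) { ini$mu.beta1 <- rep_g(0)
                       ini$sd.beta1 <- rep_g(s_ini / 2) }
    if (augmented) {
      # start undetected members out of the community with Omega near the
      # detected fraction: the chain then grows S as the data demand, which
      # burns in much faster than shedding members from a full pool
      ini$w <- ifelse(detected, NA_real_, 0)
      ini$Omega <- (sum(detected) + 1) / (S + 2)
    }
    if (G > 1 && anyNA(jd$g)) ini$g <- ifelse(is.na(jd$g), 1L, NA_integer_)
    ini
  }
  monitors <- c("beta0", "beta1", "psi", "mu.beta0", "sd.beta0", "sd.site",
                if (!null_model) c("mu.beta1", "sd.beta1"),
                if (augmented) c("w", "Omega", "S.rich"),
                if (G > 1) c("g", "pg"),
                if (ncov > 0) c("bcov", "mu.cov", "sd.cov"))
  samples <- run_jags(lines, jd, inits_builder, monitors, config)
  if (standardize_area)
    samples <- destandardize_area(samples, a_center, a_scale, G, null_model)
  post <- new_posterior(samples, data, config, lines, detected, null_model,
                        extra = list(groups = if (G > 1) glev,
                                     augmented = augmented,
                                     constant_psi = FALSE,
                                     area_standardized = standardize_area))
  check_omega(post)
  post
}

# Transform draws taken on standardized area back to the hectare scale:
# beta1 = beta1'/s, beta0 = beta0' - beta1' m/s; hyper-means likewise; the
# intercept hyper-sd becomes sqrt(sd0'^2 + (m/s)^2 sd1'^2) since the two
# species-level coefficients are independent given the hyperparameters.
destandardize_area <- function(samples, m, s, G, null_model) {
  r <- m / s
  as_list <- lapply(samples, function(ch) {
    x <- as.matrix(ch)
    cn <- colnames(x)
    b0 <- grep("^beta0\\[", cn)
    b1 <- grep("^beta1\\[", cn)
    if (length(b1)) {
      x[, b0] <- x[, b0] - x[, b1, drop = FALSE] * r
      x[, b1] <- x[, b1] / s
    }
    if (!null_model) {
      m0 <- grep("^mu\\.beta0(\\[|$)", cn)
      m1 <- grep("^mu\\.beta1(\\[|$)", cn)
      s0 <- grep("^sd\\.beta0(\\[|$)", cn)
      s1 <- grep("^sd\\.beta1(\\[|$)", cn)
      sd0_new <- sqrt(x[, s0, drop = FALSE]^2 + r^2 * x[, s1, drop = FALSE]^2)
      x[, m0] <- x[, m0, drop = FALSE] - x[, m1, drop = FALSE] * r
      x[, m1] <- x[, m1, drop = FALSE] / s
      x[, s0] <- sd0_new
      x[, s1] <- x[, s1, drop = FALSE] / s
    }
    coda::mcmc(x, start = stats::start(ch), end = stats::end(ch),
               thin = coda::thin(ch))
  })
  coda::as.mcmc.list(as_list)
}

#' @export
print.community_posterior <- function(x, ...) {
  nd <- coda::niter(x$samples) * coda::nchain(x$samples)
  cat(sprintf("<community_posterior> %s model%s: %d species x %d patches, %d draws (%d chains)\n",
              x$mode,
              if (isTRUE(x$null_model)) " (null)" else "",
              nrow(x$species), nrow(x$patches), nd, coda::nchain(x$samples)))
  if (isTRUE(x$augmented)) {
    s <- derive_regional_richness(extract_draws(x, "w"))
    cat(sprintf("  regional richness S: median %g (95%% CI %g-%g)\n",
                s$median, s$ci[1], s$ci[2]))
  }
  invisible(x)
}

#' Extract posterior draws of a monitored parameter
#'
#' Collects the draws of one monitored node across chains into a vector
#' (scalar node), matrix (vector node, draws x index) or 3-d array (matrix
#' node, draws x row x column), with species/patch identifiers as dimnames
#' where the node is indexed by them.
#'
#' @param post a `community_posterior`.
#' @param name node name, e.g. `"beta1"`, `"z"`, `"Omega"`.
#' @return Vector, matrix or array of draws.
#' @export
extract_draws <- function(post, name) {
  x <- as.matrix(post$samples)
  cn <- colnames(x)
  hit <- grep(sprintf("^%s(\\[|$)", gsub("\\.", "\\\\.", name)), cn)
  if (!length(hit))
    stop_invalid("monitor", "parameter '%s' was not monitored", name)
  x <- x[, hit, drop = FALSE]
  idx <- sub(sprintf("^%s", gsub("\\.", "\\\\.", name)), "", colnames(x))
  if (all(idx == "")) return(drop(x))
  parts <- strsplit(gsub("[][]", "", idx), ",")
  ii <- as.integer(vapply(parts, `[`, "", 1L))
  if (lengths(parts)[1] == 1L) {
    out <- matrix(NA_real_, nrow(x), max(ii))
    out[, ii] <- x
    if (max(ii) == nrow(post$species))
      colnames(out) <- post$species$species_id
    return(out)
  }
  jj <- as.integer(vapply(parts, `[`, "", 2L))
  out <- array(NA_real_, c(nrow(x), max(ii), max(jj)))
  for (k in seq_along(hit)) out[, ii[k], jj[k]] <- x[, k]
  dn <- list(NULL, NULL, NULL)
  if (max(ii) == nrow(post$species)) dn[[2]] <- post$species$species_id
  if (max(jj) == nrow(post$patches)) dn[[3]] <- post$patches$patch_id
  dimnames(out) <- dn
  out
}

# ---- convergence diagnostics ----------------------------------------------

# Split R-hat of one iterations x chains matrix (each chain halved).
split_rhat <- function(x) {
  n2 <- floor(nrow(x) / 2)
  if (n2 < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n2), , drop = FALSE],
                  x[seq_len(n2) + n2, , drop = FALSE])
  mns <- colMeans(halves)
  vrs <- apply(halves, 2, stats::var)
  W <- mean(vrs)
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n2 * stats::var(mns)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' Convergence diagnostics for a fitted posterior
#'
#' Computes per-parameter split R-hat (each chain halved, so non-stationarity
#' within chains is also penalized) and effective sample size, and summarizes
#' a pass/fail against the R-hat threshold.  Parameters that are constant
#' across all draws (e.g. fixed null-model coefficients, membership of
#' well-detected species) are flagged rather than scored.
#'
#' @param post a `community_posterior`.
#' @param threshold R-hat pass threshold (default 1.1).
#' @param params optional character vector restricting which monitored
#'   parameters are scored (prefix match on the node name).
#' @return A data frame of class `commsar_diagnostics` with columns
#'   `parameter`, `rhat`, `ess`, `flag`; attribute `"pass"` is `TRUE` when no
#'   scored parameter exceeds the threshold, and attribute `"flagged"` lists
#'   the offenders.  With a single chain R-hat is not computable and the
#'   result is flagged accordingly.
#' @export
diagnostics <- function(post, threshold = 1.1, params = NULL) {
  stopifnot(inherits(post, "community_posterior"))
  nch <- coda::nchain(post$samples)
  mats <- lapply(post$samples, as.matrix)
  cn <- colnames(mats[[1]])
  if (!is.null(params)) {
    keep <- unlist(lapply(params, function(p)
      grep(sprintf("^%s(\\[|$)", gsub("\\.", "\\\\.", p)), cn)))
    cn <- cn[sort(unique(keep))]
  }
  ess <- tryCatch(coda::effectiveSize(post$samples), error = function(e) NULL)
  rows <- lapply(cn, function(nm) {
    x <- vapply(mats, function(m) m[, nm], numeric(nrow(mats[[1]])))
    x <- as.matrix(x)
    if (max(x) == min(x))
      return(data.frame(parameter = nm, rhat = NA_real_, ess = NA_real_,
                        flag = "constant"))
    rh <- if (nch >= 2) split_rhat(x) else NA_real_
    data.frame(parameter = nm, rhat = rh,
               ess = if (!is.null(ess)) unname(ess[nm]) else NA_real_,
               flag = if (nch < 2) "single-chain"
                      else if (is.na(rh)) "undefined"
                      else if (rh > threshold) "exceeds" else "ok")
  })
  out <- do.call(rbind, rows)
  flagged <- out$parameter[out$flag == "exceeds"]
  if (nch < 2)
    warning("single chain: R-hat not computable, diagnostics are limited",
            call. = FALSE)
  if (length(flagged))
    warning(sprintf("%d parameter(s) exceed R-hat %.2f: %s%s",
                    length(flagged), threshold,
                    paste(utils::head(flagged, 5), collapse = ", "),
                    if (length(flagged) > 5) ", ..." else ""),
            call. = FALSE)
  structure(out, pass = nch >= 2 && length(flagged) == 0, flagged = flagged,
            threshold = threshold,
            class = c("commsar_diagnostics", "data.frame"))
}

#' @export
print.commsar_diagnostics <- function(x, ...) {
  scored <- x[x$flag %in% c("ok", "exceeds"), ]
  cat(sprintf("Convergence: %d parameters scored, max R-hat %.3f (threshold %.2f) -> %s\n",
              nrow(scored), suppressWarnings(max(scored$rhat, na.rm = TRUE)),
              attr(x, "threshold"),
              if (isTRUE(attr(x, "pass"))) "PASS" else "CHECK"))
  fl <- attr(x, "flagged")
  if (length(fl))
    cat("  exceeding:", paste(utils::head(fl, 10), collapse = ", "),
        if (length(fl) > 10) "..." else "", "\n")
  invisible(x)
}
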
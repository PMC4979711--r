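tiny_abund <- function(seed = 3)
  simulate_community(simulation_design("abundance", n_species = 8,
                                       n_patches = 6), seed = seed)

test_that("identical seed and config reproduce the draw sequences exactly", {
  s <- tiny_abund()
  cfg <- quick_cfg(seed = 5)
  f1 <- suppressWarnings(fit_abundance_model(s$data, cfg))
  f2 <- suppressWarnings(fit_abundance_model(s$data, cfg))
  expect_identical(as.matrix(f1$samples), as.matrix(f2$samples))
  f3 <- suppressWarnings(fit_abundance_model(s$data, quick_cfg(seed = 6)))
  expect_false(identical(as.matrix(f1$samples), as.matrix(f3$samples)))
  # draw count contract: chains * (iterations - burn_in) / thin
  expect_equal(nrow(as.matrix(f1$samples)), 2 * (600 - 200) / 2)
})

test_that("the sampler reproduces the conjugate beta-binomial posterior", {
  # one species, full coverage (ap = tp), flat prior: psi | y ~ Beta(y+1, ap-y+1)
  d <- community_data(data.frame(patch_id = "p1", area_ha = 1, ap = 30, tp = 30),
                      data.frame(species_id = "s1", patch_id = "p1", y = 9),
                      mode = "frequency")
  f <- fit_frequency_model(d, quick_cfg(seed = 2, iters = 6000, burn = 500,
                                        thin = 1, adapt = 200),
                           constant_psi = TRUE)
  psi <- extract_draws(f, "psi0")
  n <- length(psi)
  mc_se <- sd(psi) / sqrt(n / 10)  # conservative for autocorrelation
  expect_lt(abs(mean(psi) - 10 / 32), 4 * mc_se)
  expect_lt(abs(var(psi) - (10 * 22) / (32^2 * 33)), 0.002)
})

test_that("with near-perfect detection the fit matches per-species Poisson GLMs", {
  h <- abundance_hyperparams(mu_beta0 = 0.8, sigma_beta0 = 0.8, mu_beta1 = 1,
                             sigma_beta1 = 0.2, mu_lp = 3, sigma_lp = 0.01,
                             sigma_b = 0.05)
  s <- simulate_community(simulation_design("abundance", n_species = 12,
                                            n_patches = 15, hyper = h),
                          seed = 44)
  f <- suppressWarnings(fit_abundance_model(
    s$data, quick_cfg(seed = 4, iters = 2000, burn = 600, adapt = 300)))
  n <- commsar:::encounter_array(s$data)$n
  logA <- log(s$data$patches$area_ha)
  b1 <- extract_draws(f, "beta1")
  ok <- vapply(seq_len(nrow(n)), function(i) {
    g <- glm(n[i, ] ~ logA, family = poisson)
    abs(median(b1[, i]) - coef(g)[2]) <= 2.5 * max(sd(b1[, i]), 0.05)
  }, TRUE)
  expect_gte(mean(ok), 0.85)
})

test_that("group-specific hyperparameters recover their ordering", {
  h <- frequency_hyperparams(mu_beta0 = rep(-4, 3), sigma_beta0 = rep(1, 3),
                             mu_beta1 = c(-0.4, 0, 0.4),
                             sigma_beta1 = rep(0.1, 3),
                             group_names = c("neg", "flat", "pos"))
  s <- simulate_community(simulation_design("frequency", n_species = 60,
                                            n_patches = 8, hyper = h),
                          seed = 17)
  f <- suppressWarnings(fit_frequency_model(
    s$data, quick_cfg(seed = 7, iters = 1200, burn = 400, adapt = 300)))
  mu1 <- extract_draws(f, "mu.beta1")
  # groups are indexed alphabetically: flat, neg, pos
  med <- apply(mu1, 2, median)
  expect_lt(med[2], med[1])   # neg below flat
  expect_lt(med[1], med[3])   # flat below pos
})

test_that("all-zero augmented species keep membership uncertain", {
  s <- simulate_community(simulation_design("frequency", n_species = 30,
                                            n_patches = 6), seed = 23)
  da <- augment_dataset(s$data, 30)
  f <- suppressWarnings(fit_frequency_model(da, quick_cfg(seed = 3)))
  w <- extract_draws(f, "w")
  aug <- f$species$augmented
  expect_true(all(colMeans(w[, !aug, drop = FALSE]) == 1))
  expect_lt(mean(w[, aug]), 1)
  # a too-small augmented pool pushes Omega against 1 and warns
  expect_warning(fit_frequency_model(augment_dataset(s$data, 2),
                                     quick_cfg(seed = 3)),
                 "Omega")
})

test_that("diagnostics score split R-hat and flag pathological chains", {
  set.seed(99)
  n <- 400
  mk <- function(shift = 0) cbind(good = rnorm(n), const = 1,
                                  drift = rnorm(n) + shift)
  ml <- coda::mcmc.list(coda::mcmc(mk(0)), coda::mcmc(mk(5)))
  post <- commsar:::new_posterior(ml, shell_data(2, c(1, 2)), quick_cfg(),
                                  "mock", detected = c(TRUE, TRUE), FALSE)
  dg <- suppressWarnings(diagnostics(post))
  expect_lt(dg$rhat[dg$parameter == "good"], 1.05)
  expect_equal(dg$flag[dg$parameter == "const"], "constant")
  expect_equal(dg$flag[dg$parameter == "drift"], "exceeds")
  expect_false(attr(dg, "pass"))
  expect_true("drift" %in% attr(dg, "flagged"))
  expect_warning(diagnostics(post), "exceed")

  ml1 <- coda::mcmc.list(coda::mcmc(mk(0)))
  post1 <- commsar:::new_posterior(ml1, shell_data(2, c(1, 2)), quick_cfg(),
                                   "mock", detected = c(TRUE, TRUE), FALSE)
  expect_warning(diagnostics(post1), "single chain")
})

test_that("simulation-based calibration ranks are approximately uniform", {
  # reduced SBC: tight hyperpriors shared by generator and fit
  pri <- list(mu_mean = 0, mu_sd = 0.5, sigma_upper = 0.5)
  cycles <- 40
  seeds <- commsar:::spawn_seeds(314, cycles * 2)
  ranks <- vapply(seq_len(cycles), function(k) {
    hy <- commsar:::with_seed(seeds[k], abundance_hyperparams(
      mu_beta0 = rnorm(1, 0, 0.5), sigma_beta0 = runif(1, 0, 0.5),
      mu_beta1 = rnorm(1, 0, 0.5), sigma_beta1 = runif(1, 0, 0.5),
      mu_lp = rnorm(1, 0, 0.5), sigma_lp = runif(1, 0, 0.5),
      sigma_b = runif(1, 0, 0.5)))
    s <- simulate_community(simulation_design("abundance", n_species = 5,
                                              n_patches = 4, visits = 3,
                                              hyper = hy),
                            seed = seeds[cycles + k], keep_undetected = TRUE)
    f <- suppressWarnings(fit_abundance_model(
      s$data, quick_cfg(seed = k, iters = 1700, burn = 500, thin = 8,
                        adapt = 300, priors = pri), augment = "none"))
    dr <- extract_draws(f, "mu.beta1")
    sum(dr < hy$mu_beta1) / length(dr)
  }, 0)
  counts <- tabulate(findInterval(ranks, c(0.25, 0.5, 0.75)) + 1, nbins = 4)
  expect_gt(gof_pvalue(counts, rep(0.25, 4)), 0.01)
})
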
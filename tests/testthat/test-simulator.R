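test_that("the noise-free path reproduces latent states exactly", {
  h <- abundance_hyperparams(mu_beta0 = log(3), sigma_beta0 = 0, mu_beta1 = 1,
                             sigma_beta1 = 0, mu_lp = 20, sigma_lp = 0,
                             sigma_b = 0)
  d <- simulation_design("abundance", n_species = 6, n_patches = 5,
                         visits = 1, phi = 1, hyper = h)
  s <- simulate_community(d, seed = 2, keep_undetected = TRUE)
  n <- commsar:::encounter_array(s$data)$n
  expect_identical(s$truth$N, s$truth$z)         # phi = 1
  # p ~ 1 and t = 1: every individual is observed exactly once
  expect_equal(unname(n), unname(s$truth$z))
})

test_that("a fixed seed makes simulations byte-identical", {
  d <- simulation_design("frequency", n_species = 15, n_patches = 4)
  expect_identical(simulate_community(d, seed = 5),
                   simulate_community(d, seed = 5))
  expect_false(identical(simulate_community(d, seed = 5),
                         simulate_community(d, seed = 6)))
})

test_that("simulated encounter frequencies match the multinomial cells", {
  # one abundant, well-mixed species surveyed five times at p = 0.66
  h <- abundance_hyperparams(mu_beta0 = log(2e4), sigma_beta0 = 0,
                             mu_beta1 = 1, sigma_beta1 = 0,
                             mu_lp = qlogis(0.66), sigma_lp = 0, sigma_b = 0)
  d <- simulation_design("abundance", n_species = 1, n_patches = 1,
                         areas = 1, visits = 5, hyper = h)
  s <- simulate_community(d, seed = 42)
  enc <- commsar:::encounter_array(s$data)
  yH <- apply(enc$y, 3, sum)
  N <- s$truth$N[1, 1]
  counts <- c(N - sum(yH), yH)
  expect_gt(gof_pvalue(counts, multinomial_cell_probs(0.66, 5)), 0.001)
})

test_that("simulator marginals match their closed forms", {
  # abundance: z ~ Poisson(lambda), N ~ Poisson(lambda * phi) marginally
  h <- abundance_hyperparams(mu_beta0 = log(6), sigma_beta0 = 0, mu_beta1 = 0,
                             sigma_beta1 = 0, sigma_b = 0)
  d <- simulation_design("abundance", n_species = 3000, n_patches = 2,
                         areas = c(1, 3), phi = 0.4, hyper = h)
  s <- simulate_community(d, seed = 77)
  expect_equal(mean(s$truth$z), 6, tolerance = 0.02)
  expect_equal(var(as.vector(s$truth$z)), 6, tolerance = 0.08)
  expect_equal(mean(s$truth$N), 2.4, tolerance = 0.03)
  expect_equal(var(as.vector(s$truth$N)), 2.4, tolerance = 0.08)

  # frequency: patch-level frequency has mean tp * psi
  hf <- frequency_hyperparams(mu_beta0 = qlogis(0.02), sigma_beta0 = 0,
                              mu_beta1 = 0, sigma_beta1 = 0, sigma_b = 0)
  df <- simulation_design("frequency", n_species = 2000, n_patches = 1,
                          areas = 0.05, hyper = hf)  # tp = 500
  sf <- simulate_community(df, seed = 78)
  expect_equal(mean(sf$truth$z), 500 * 0.02, tolerance = 0.03)
  # and the observed y | z subsample is Binomial(ap, psi) marginally
  ap <- sf$data$patches$ap
  expect_gt(gof_pvalue(tabulate(sf$truth$y_full + 1, nbins = ap + 1),
                       dbinom(0:ap, ap, 0.02)), 0.001)
})

test_that("DAR experiment slopes behave as the exchangeable baseline demands", {
  d <- simulation_design("abundance", n_species = 50,
                         areas = exp(seq(log(0.1), log(10), length.out = 10)),
                         n_patches = 10)
  ex <- run_dar_experiment(d, f_neg_grid = c(0, 0, 0.8), replicates = 20,
                           seed = 99)
  sm <- attr(ex, "summary")
  expect_true(all(is.finite(ex$slope)))
  expect_true(all(sm$mean_slope >= 0))
  # two identical designs agree within Monte-Carlo error
  expect_lt(abs(sm$mean_slope[1] - sm$mean_slope[2]),
            4 * sqrt(sm$mc_se[1]^2 + sm$mc_se[2]^2))
  # more edge species flatten the SAR
  expect_lt(sm$mean_slope[3], sm$mean_slope[1])
  expect_error(run_dar_experiment(
    simulation_design("abundance", n_patches = 1, areas = 1), c(0, 0.5)),
    class = "commsar_validation_error")
})

test_that("recovery scoring reports bias, RMSE and interval coverage", {
  h <- abundance_hyperparams(mu_beta0 = 1, sigma_beta0 = 0.5, mu_beta1 = 1,
                             sigma_beta1 = 0.2, mu_lp = 2.5, sigma_lp = 0.1)
  s <- simulate_community(simulation_design("abundance", n_species = 10,
                                            n_patches = 8, hyper = h),
                          seed = 55)
  stopifnot(all(s$truth$detected))
  truth_pars <- list(beta0 = s$truth$beta0, beta1 = s$truth$beta1,
                     p = s$truth$p)
  post <- constant_posterior(truth_pars, s$data, ndraws = 20)
  sc <- score_recovery(s, post)
  expect_equal(sc$bias[sc$parameter == "beta1"], 0)
  expect_equal(sc$rmse[sc$parameter == "beta0"], 0)
  expect_equal(sc$zero_width[sc$parameter == "p"], 1)

  shifted <- truth_pars
  shifted$beta0 <- shifted$beta0 + 0.5
  post2 <- constant_posterior(shifted, s$data, ndraws = 20)
  sc2 <- score_recovery(s, post2)
  expect_equal(sc2$bias[sc2$parameter == "beta0"], 0.5)
  expect_equal(sc2$coverage[sc2$parameter == "beta0"], 0)
})
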
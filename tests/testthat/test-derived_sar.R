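test_that("patch summaries count species with positive latent states", {
  d <- shell_data(2, c(1, 4))
  post <- constant_posterior(list(z = matrix(c(0, 1, 2, 0), 2, 2)), d)
  ps <- derive_patch_summaries(post)
  expect_equal(ps$richness_med, c(1, 1))
  expect_equal(ps$total_med, c(1, 2))

  post0 <- constant_posterior(list(z = matrix(0, 2, 2)), d)
  ps0 <- derive_patch_summaries(post0)
  expect_equal(ps0$richness_med, c(0, 0))
  expect_equal(ps0$richness_hi, c(0, 0))
})

test_that("frequency patch summaries add observed and unsurveyed plots", {
  d <- freq_data_2x2()
  # psi high for spA, zero for spB: z must be >= the observed y in every draw
  psi <- matrix(c(0.4, 0, 0.4, 0), 2, 2)
  post <- constant_posterior(list(psi = psi), d, ndraws = 200,
                             extra = list(augmented = FALSE,
                                          constant_psi = FALSE))
  ps <- derive_patch_summaries(post, seed = 5)
  y <- commsar:::occurrence_matrix(d)
  z <- attr(ps, "z_draws")
  expect_true(all(sweep(z, 2:3, y, ">=") ))
  # E[z] = y + (tp - ap) psi
  expect_equal(mean(z[, 1, 1]), y[1, 1] + (100 - 4) * 0.4, tolerance = 0.05)
})

test_that("the null-model SAR matches the random placement closed form", {
  set.seed(12)
  S <- 25
  lam <- runif(S, 0.2, 3)
  areas <- exp(seq(log(0.05), log(10), length.out = 10))
  d <- shell_data(S, c(1, 4))
  post <- constant_posterior(list(beta0 = log(lam), beta1 = rep(1, S),
                                  sd.site = 0), d,
                             ndraws = 600, null_model = TRUE)
  sc <- predict_sar_curve(post, areas, ndraws = 600, site_effects = "zero",
                          seed = 31)
  oracle <- random_placement_expected_richness(lam, areas)
  se <- sqrt(vapply(areas, function(a)
    sum((1 - exp(-lam * a)) * exp(-lam * a)), 0) / 600)
  expect_true(all(abs(colMeans(attr(sc, "richness_draws")) - oracle)
                  < 4 * se + 1e-9))
  expect_true(all(abs(sc$richness_med - oracle) <= 1.5))
  expect_equal(unique(sc$model), "null")
  # credible band brackets the median everywhere; extrapolation is flagged
  expect_true(all(sc$richness_lo <= sc$richness_med))
  expect_true(all(sc$richness_med <= sc$richness_hi))
  expect_equal(sc$extrapolated, areas < 1)
})

test_that("the frequency SAR converges to its binomial closed form", {
  S <- 20
  set.seed(13)
  psi0 <- runif(S, 0.005, 0.05)
  areas <- c(0.001, 0.005, 0.02)   # tp = 10, 50, 200 one-m2 plots
  d <- shell_data(S, c(0.001, 0.02), mode = "frequency", ap = 1)
  post <- constant_posterior(list(beta0 = qlogis(psi0), beta1 = rep(0, S),
                                  sd.site = 0), d, ndraws = 600)
  sc <- predict_sar_curve(post, areas, ndraws = 600, site_effects = "zero",
                          seed = 8)
  oracle <- vapply(total_plots(areas), function(tp)
    sum(1 - (1 - psi0)^tp), 0)
  expect_equal(colMeans(attr(sc, "richness_draws")), oracle, tolerance = 0.08)
})

test_that("an empty community predicts a flat zero curve", {
  S <- 4
  d <- shell_data(S, c(1, 2))
  post <- constant_posterior(list(beta0 = rep(0, S), beta1 = rep(1, S),
                                  sd.site = 0, w = rep(0, S)), d,
                             ndraws = 50, extra = list(augmented = TRUE))
  sc <- predict_sar_curve(post, c(0.5, 5), ndraws = 50, seed = 1)
  expect_true(all(sc$richness_hi == 0))
  expect_true(all(sc$total_hi == 0))
  expect_error(predict_sar_curve(post, numeric(0)),
               class = "commsar_validation_error")
})

test_that("null-model fits pin the area coefficient at its constant", {
  s <- simulate_community(simulation_design("abundance", n_species = 6,
                                            n_patches = 5), seed = 9)
  fa <- suppressWarnings(fit_null_model(s$data, quick_cfg(seed = 2)))
  expect_true(all(extract_draws(fa, "beta1") == 1))
  sf <- simulate_community(simulation_design("frequency", n_species = 25,
                                             n_patches = 5), seed = 9)
  ff <- suppressWarnings(fit_null_model(sf$data, quick_cfg(seed = 2)))
  expect_true(all(extract_draws(ff, "beta1") == 0))
  # constant occurrence: psi identical across patches up to site effects?
  # with beta1 = 0 the area term vanishes by construction, so the linear
  # predictor differs between patches only through b; check via the model
  expect_match(ff$model, "beta1\\[i\\] <- 0")
})

test_that("random placement richness follows its closed form", {
  expect_equal(random_placement_expected_richness(c(1, 2), 1),
               (1 - exp(-1)) + (1 - exp(-2)))
  expect_lt(random_placement_expected_richness(c(1, 2), 1e-9), 1e-6)
  lam <- c(0.5, 1, 4)
  es <- random_placement_expected_richness(lam, c(0.1, 1, 10, 100))
  expect_true(all(diff(es) > 0))
  expect_true(all(es <= length(lam)))
  expect_lt(es[2], length(lam))
  expect_error(random_placement_expected_richness(c(1, -1), 1),
               class = "commsar_validation_error")
  expect_error(random_placement_expected_richness(1, 0),
               class = "commsar_validation_error")
})
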
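test_that("expected abundance follows the log-link identities", {
  expect_equal(expected_abundance(0, 1, 1), 1)
  expect_equal(expected_abundance(0, 0.5, 4), 2)
  expect_equal(expected_abundance(log(2), 1, 5), 10)
  expect_error(expected_abundance(0, 1, -2), class = "commsar_validation_error")
  # multiplicative separability: lambda = exp(beta0) * A^beta1
  set.seed(4)
  for (k in 1:20) {
    b0 <- rnorm(1); b1 <- rnorm(1); a <- rexp(1) + 0.01
    expect_equal(expected_abundance(b0, b1, a), exp(b0) * a^b1)
  }
})

test_that("species-level draws follow the community hyperdistributions", {
  h0 <- abundance_hyperparams(mu_beta0 = 0.3, sigma_beta0 = 0, mu_beta1 = 1,
                              sigma_beta1 = 0, mu_lp = 0.5, sigma_lp = 0,
                              sigma_b = 0)
  p0 <- sample_species_params(h0, 5, n_patches = 3, seed = 1)
  expect_equal(p0$beta0, rep(0.3, 5))
  expect_equal(p0$beta1, rep(1, 5))
  expect_equal(p0$p, rep(plogis(0.5), 5))
  expect_equal(p0$b, matrix(0, 5, 3))

  h <- abundance_hyperparams(mu_beta1 = 1, sigma_beta1 = 0.2)
  expect_identical(sample_species_params(h, 50, seed = 9),
                   sample_species_params(h, 50, seed = 9))
  # law of large numbers at n = 10000
  big <- sample_species_params(h, 10000, seed = 2)
  expect_lt(abs(mean(big$beta1) - 1), 4 * 0.2 / sqrt(10000))
  expect_error(abundance_hyperparams(sigma_beta1 = -1),
               class = "commsar_validation_error")
})

test_that("latent abundance and coverage thinning match Poisson closed forms", {
  pars <- list(beta0 = c(-Inf, log(4)), beta1 = c(1, 0))
  z <- sample_latent_abundance(pars, c(1, 2), seed = 3)
  expect_true(all(z[1, ] == 0))            # lambda = 0 limit
  expect_identical(z, sample_latent_abundance(pars, c(1, 2), seed = 3))

  # moments of Poisson(4) at 1e5 replicate draws
  zz <- sample_latent_abundance(list(beta0 = rep(log(4), 1e5), beta1 = rep(0, 1e5)),
                                1, seed = 5)
  expect_lt(abs(mean(zz) - 4), 4 * sqrt(4 / 1e5))
  expect_lt(abs(var(zz) - 4), 0.2)

  expect_identical(thin_to_sampled(z, 1, seed = 1), z)     # phi = 1 keeps all
  expect_true(all(thin_to_sampled(matrix(0, 3, 2), 0.4, seed = 1) == 0))
  expect_error(thin_to_sampled(z, 1.3), class = "commsar_validation_error")

  # thinned-Poisson marginal: Poisson(10) thinned at 0.3 is Poisson(3)
  n <- 4e4
  zt <- sample_latent_abundance(list(beta0 = rep(log(10), n), beta1 = rep(0, n)),
                                1, seed = 6)
  Nt <- thin_to_sampled(zt, 0.3, seed = 7)
  expect_true(all(Nt <= zt))
  expect_lt(abs(mean(Nt) - 3), 4 * sqrt(3 / n))
  expect_lt(abs(var(Nt) - 3), 0.15)
})

test_that("encounter-frequency cell probabilities are the binomial pmf", {
  expect_equal(unname(multinomial_cell_probs(0.5, 2)), c(0.25, 0.5, 0.25))
  for (p in c(0.1, 0.37, 0.9)) for (t in c(1, 3, 6))
    expect_equal(sum(multinomial_cell_probs(p, t)), 1)
  # a territory surveyed five times at p = 0.66 is almost surely seen
  pstar <- 1 - multinomial_cell_probs(0.66, 5)[["H0"]]
  expect_equal(pstar, 1 - 0.34^5)
  expect_gt(pstar, 0.99)
  expect_error(multinomial_cell_probs(1, 3), class = "commsar_validation_error")
  expect_error(multinomial_cell_probs(0.5, 0), class = "commsar_validation_error")
})

test_that("conditioning on encounter decomposes the multinomial likelihood", {
  # t = 1: the conditional multinomial is degenerate
  ll1 <- conditional_encounter_loglik(3, N = 5, p = 0.4)
  expect_equal(attr(ll1, "multinomial"), 0)
  expect_equal(as.numeric(ll1), dbinom(3, 5, 0.4, log = TRUE))

  # hand-enumerated case: conditional probs (2/3, 1/3), multinomial 4/9
  ll <- conditional_encounter_loglik(c(2, 1), N = 5, p = 0.5)
  expect_equal(exp(attr(ll, "multinomial")), 4 / 9, tolerance = 1e-12)

  # binomial component normalizes over n = 0..N
  for (N in c(2, 6)) for (p in c(0.3, 0.8)) for (t in c(2, 5)) {
    tot <- sum(vapply(0:N, function(n) {
      y <- integer(t); y[1] <- n   # any split; only the binomial attr is used
      exp(attr(conditional_encounter_loglik(y, N = N, p = p), "binomial"))
    }, 0))
    expect_equal(tot, 1, tolerance = 1e-12)
  }

  # equals the full multinomial over {y_0 = N - n, y_1..y_t}
  cells <- function(n, t) {  # all encounter splits of n detections
    if (t == 1) return(matrix(n, 1, 1))
    do.call(rbind, lapply(0:n, function(k)
      cbind(k, cells(n - k, t - 1))))
  }
  for (N in c(0, 3, 6)) for (t in c(2, 4)) for (p in c(0.25, 0.66)) {
    probs <- multinomial_cell_probs(p, t)
    for (n in 0:N) for (r in seq_len(nrow(cells(n, t)))) {
      y <- cells(n, t)[r, ]
      full <- dmultinom(c(N - n, y), prob = probs, log = TRUE)
      expect_equal(as.numeric(conditional_encounter_loglik(y, N = N, p = p)),
                   full, tolerance = 1e-12)
    }
  }
  expect_error(conditional_encounter_loglik(c(2, 2), N = 3, p = 0.5),
               class = "commsar_validation_error")
})

test_that("binomial count likelihood matches the pmf and normalizes", {
  expect_equal(binomial_count_loglik(5, 5, 1), 0)
  expect_equal(binomial_count_loglik(4, 5, 1), -Inf)
  expect_equal(exp(binomial_count_loglik(2, 5, 0.5)), 0.3125)
  expect_equal(sum(exp(binomial_count_loglik(0:7, 7, 0.23))), 1)
  expect_error(binomial_count_loglik(6, 5, 0.5),
               class = "commsar_validation_error")
})
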
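test_that("environmental variance follows the exponential link", {
  expect_equal(env_variance(log(0.19), 2.20, 0), 0.19)
  expect_equal(env_variance(0, 0, 5), 1.0)
  expect_equal(env_variance(log(0.19), 2.20, 0.5), 0.19 * exp(1.10))
  # strictly monotone in g with the sign of beta1, always positive
  g <- seq(-3, 3, 0.1)
  expect_true(all(diff(env_variance(-1, 1.5, g)) > 0))
  expect_true(all(diff(env_variance(-1, -1.5, g)) < 0))
  expect_true(all(env_variance(-20, 3, g) > 0))
  expect_error(env_variance(Inf, 0, 0), "finite")
})

test_that("heritability follows the variance-ratio definition", {
  expect_equal(heritability(0.25, exp_beta0 = 0.19), 0.25 / 0.44)
  expect_equal(round(100 * heritability(0.25, exp_beta0 = 0.19)), 57)
  expect_equal(heritability(0, exp_beta0 = 0.3), 0)
  expect_equal(heritability(0.27, exp_beta0 = 0.51, sigma2_C = 0.31),
               0.27 / 1.09, tolerance = 1e-12)
  expect_error(heritability(0, exp_beta0 = 0), "zero")
  # invariant under joint rescaling of all components
  expect_equal(heritability(0.25 * 3, exp_beta0 = 0.19 * 3),
               heritability(0.25, exp_beta0 = 0.19))
  p <- table2_params()
  expect_equal(heritability(p), 0.25 / 0.44)
})

test_that("interaction effect size is exp(beta1 * genetic SD)", {
  expect_equal(round(interaction_effect_size(2.20, 0.25), 2), 3.00)
  expect_equal(round(interaction_effect_size(2.16, 0.27), 2), 3.07)
  expect_equal(interaction_effect_size(0, 0.5), 1.0)
})

test_that("total phenotypic variance sums the model's components", {
  expect_equal(total_phenotypic_variance(table2_params()), 0.44)
  p4 <- genetic_params("ACE", sigma2_A = 0.27, sigma2_C = 0.31,
                       beta0 = log(0.51), beta1 = 2.16)
  expect_equal(total_phenotypic_variance(p4), 1.09)
  p0 <- genetic_params("AE", sigma2_A = 0, beta0 = log(0.6), beta1 = 0,
                       interaction = FALSE)
  expect_equal(total_phenotypic_variance(p0), 0.6)
})

make_state <- function(params, items, lat) {
  list(params = params, items = items, latents = lat)
}

test_that("joint log density integrates to the marginal data probability", {
  # 1 MZ pair, 1 item, K = 2: integrate exp(joint density without priors)
  # over (A, E1, E2) on a grid and compare with an independent nested
  # quadrature of the same marginal probability
  params <- genetic_params("AE", sigma2_A = 0.3, beta0 = log(0.25),
                           beta1 = 0.8)
  items <- item_bank(1.2, list(c(0, 0.3)), "GPCM")
  data <- twinace:::new_item_response_table(
    data.frame(family_id = c(1, 1), zygosity = "MZ", twin = 1:2,
               item_1 = c(2L, 1L)), 2L)
  spec <- model_spec("AE", interaction = TRUE)

  gr_A <- seq(-3, 3, length.out = 21)
  gr_E <- seq(-4, 4, length.out = 21)
  dA <- diff(gr_A)[1]; dE <- diff(gr_E)[1]

  # route 1: independent factorized integrand, same Riemann grid
  total <- 0
  for (a in gr_A) {
    sE <- sqrt(exp(log(0.25) + 0.8 * a))
    f1 <- sum(plogis(1.2 * (a + gr_E - 0.3)) * dnorm(gr_E, 0, sE)) * dE
    f2 <- sum((1 - plogis(1.2 * (a + gr_E - 0.3))) * dnorm(gr_E, 0, sE)) * dE
    total <- total + f1 * f2 * dnorm(a, 0, sqrt(0.3)) * dA
  }

  # route 2: exhaustive 3-D grid over exp(joint_log_density)
  total_jld <- 0
  for (a in gr_A) for (e1 in gr_E) for (e2 in gr_E) {
    lat <- data.frame(A = c(a, a), C = c(0, 0), D = c(0, 0), E = c(e1, e2))
    total_jld <- total_jld +
      exp(joint_log_density(make_state(params, items, lat), data, spec,
                            include_priors = FALSE)) * dE * dE * dA
  }
  expect_equal(total_jld, total, tolerance = 1e-4)
})

test_that("joint log density reduces and marginalizes as expected", {
  params1 <- genetic_params("AE", sigma2_A = 0.3, beta0 = log(0.25),
                            beta1 = 0, interaction = TRUE)
  params0 <- genetic_params("AE", sigma2_A = 0.3, beta0 = log(0.25),
                            beta1 = 0, interaction = FALSE)
  items <- tiny_bank()
  lat <- data.frame(A = c(0.2, 0.2, -0.1, 0.4), C = 0, D = 0,
                    E = c(0.1, -0.3, 0.2, 0))
  data <- twinace:::new_item_response_table(
    data.frame(family_id = c(1, 1, 2, 2), zygosity = rep(c("MZ", "DZ"), each = 2),
               twin = c(1, 2, 1, 2),
               item_1 = c(1L, 3L, 2L, 2L), item_2 = c(2L, 1L, 1L, 2L)),
    c(3L, 2L))
  spec1 <- model_spec("AE", interaction = TRUE)
  spec0 <- model_spec("AE", interaction = FALSE)
  # beta1 = 0: identical to the homoscedastic density at the same state
  expect_equal(
    joint_log_density(make_state(params1, items, lat), data, spec1,
                      include_priors = FALSE),
    joint_log_density(make_state(params0, items, lat), data, spec0,
                      include_priors = FALSE))

  # a marginalized missing response contributes nothing
  data_miss <- data
  data_miss$item_2[3] <- NA_integer_
  full <- joint_log_density(make_state(params0, items, lat), data, spec0,
                            include_priors = FALSE)
  miss <- joint_log_density(make_state(params0, items, lat), data_miss, spec0,
                            include_priors = FALSE)
  p_obs <- gpcm_category_probs(lat$A[3] + lat$E[3], items$alpha[2],
                               items$thresholds[[2]])[1, 1]
  expect_equal(miss, full - log(p_obs))

  # invalid category index errors
  data_bad <- data
  data_bad$item_2[1] <- 9L
  expect_error(joint_log_density(make_state(params0, items, lat), data_bad,
                                 spec0), "invalid category")
})
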
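test_that("latent components respect the twin covariance structure", {
  p <- genetic_params("ACE", sigma2_A = 0.4, sigma2_C = 0.2,
                      beta0 = log(0.3), beta1 = 0, interaction = FALSE)
  lat <- generate_latents(p, cohort_design(4000, 6000, missingness_spec = NULL),
                          seed = 7)
  a1 <- lat$A[c(TRUE, FALSE)]; a2 <- lat$A[c(FALSE, TRUE)]
  mz <- lat$zygosity[c(TRUE, FALSE)] == "MZ"
  # MZ twins share A exactly; C is family-shared
  expect_identical(a1[mz], a2[mz])
  expect_identical(lat$C[c(TRUE, FALSE)], lat$C[c(FALSE, TRUE)])
  # DZ additive correlation 0.5, variances as specified (3 MC SEs)
  expect_equal(cor(a1[!mz], a2[!mz]), 0.5, tolerance = 3 / sqrt(6000) / 0.5)
  expect_equal(var(lat$A), 0.4, tolerance = 0.02)
  expect_equal(var(lat$E), 0.3, tolerance = 0.02)
  # trait is the exact sum of its components
  expect_identical(lat$theta, lat$A + lat$C + lat$D + lat$E)
})

test_that("twin trait correlations match the biometric expectation for beta1 = 0", {
  p <- genetic_params("ACE", sigma2_A = 0.4, sigma2_C = 0.2,
                      beta0 = log(0.4), beta1 = 0, interaction = FALSE)
  lat <- generate_latents(p, cohort_design(8000, 8000, missingness_spec = NULL),
                          seed = 13)
  t1 <- lat$theta[c(TRUE, FALSE)]; t2 <- lat$theta[c(FALSE, TRUE)]
  mz <- lat$zygosity[c(TRUE, FALSE)] == "MZ"
  tot <- 0.4 + 0.2 + 0.4
  se <- 3 / sqrt(8000)
  expect_equal(cor(t1[mz], t2[mz]), (0.4 + 0.2) / tot, tolerance = se / 0.5)
  expect_equal(cor(t1[!mz], t2[!mz]), (0.5 * 0.4 + 0.2) / tot, tolerance = se / 0.4)
})

test_that("unique-environment variance follows the log-linear model", {
  # homoscedastic: Var(E) = exp(beta0) = 0.19
  p0 <- genetic_params("AE", sigma2_A = 0.25, beta0 = log(0.19), beta1 = 0,
                       interaction = FALSE)
  lat0 <- generate_latents(p0, cohort_design(50000, 0, missingness_spec = NULL),
                           seed = 3)
  expect_equal(var(lat0$E), 0.19, tolerance = 0.005)

  # degenerate decomposition: all variance from E
  pd <- genetic_params("AE", sigma2_A = 0, beta0 = log(0.7), beta1 = 0,
                       interaction = FALSE)
  latd <- generate_latents(pd, cohort_design(20000, 0, missingness_spec = NULL),
                           seed = 4)
  expect_identical(latd$theta, latd$E)
  expect_equal(var(latd$theta), 0.7, tolerance = 0.02)

  # AxE: E[Var(E)] = exp(beta0 + beta1^2 sigma2_A / 2) (lognormal moment)
  p <- table2_params()
  lat <- generate_latents(p, cohort_design(100000, 0, missingness_spec = NULL),
                          seed = 5)
  expect_equal(var(lat$E), 0.19 * exp(2.2^2 * 0.25 / 2), tolerance = 0.02)
})

test_that("latent generation is deterministic given the seed", {
  p <- table2_params()
  d <- cohort_design(30, 40)
  expect_identical(generate_latents(p, d, seed = 9),
                   generate_latents(p, d, seed = 9))
  expect_false(identical(generate_latents(p, d, seed = 9),
                         generate_latents(p, d, seed = 10)))
  sim1 <- simulate_twin_cohort(p, d, seed = 9)
  sim2 <- simulate_twin_cohort(p, d, seed = 9)
  expect_identical(sim1$data, sim2$data)
})

test_that("item responses follow the GPCM category distribution", {
  bank <- tiny_bank()
  # fixed theta: frequencies match gpcm_category_probs within MC error
  lat <- data.frame(family_id = rep(1:50000, each = 2),
                    zygosity = "DZ", twin = rep(1:2, 50000),
                    theta = 0.4)
  tab <- generate_item_responses(lat, bank, seed = 11)
  y <- response_matrix(tab)
  for (i in 1:2) {
    p_exp <- gpcm_category_probs(0.4, bank$alpha[i], bank$thresholds[[i]])[1, ]
    p_obs <- tabulate(y[, i], nbins = bank$K[i]) / nrow(y)
    expect_equal(p_obs, p_exp, tolerance = 0.01)
  }
  # zero discrimination: uniform categories
  b0 <- item_bank(0, list(c(0, -1, 1, 0.5)), "GPCM")
  tab0 <- generate_item_responses(lat, b0, seed = 12)
  freq <- tabulate(response_matrix(tab0)[, 1], nbins = 4) / nrow(lat)
  expect_equal(freq, rep(0.25, 4), tolerance = 0.01)
  # no missingness spec leaves the table complete
  expect_false(anyNA(y))
})

test_that("missingness injection hits the requested family counts", {
  p <- genetic_params("AE", sigma2_A = 0.3, beta0 = log(0.3), beta1 = 0,
                      interaction = FALSE)
  des <- cohort_design(500, 500, missingness_spec = data.frame(
    fraction = c(0.95, 0.02, 0.01, 0.02), n_missing = c(0, 1, 5, 9)))
  sim <- simulate_twin_cohort(p, des, seed = 31)
  y <- response_matrix(sim$data)
  miss_per_fam <- tapply(rowSums(is.na(y)), sim$data$family_id, sum)
  counts <- table(factor(miss_per_fam, levels = c(0, 1, 5, 9)))
  expect_equal(as.integer(counts), c(950, 20, 10, 20))

  # simple pattern, exact rounding
  des2 <- cohort_design(50, 50, missingness_spec = data.frame(
    fraction = c(0.95, 0.05), n_missing = c(0, 1)))
  sim2 <- simulate_twin_cohort(p, des2, seed = 32)
  m2 <- tapply(rowSums(is.na(response_matrix(sim2$data))),
               sim2$data$family_id, sum)
  expect_equal(sum(m2 == 1), 5)
  expect_equal(sum(m2 == 0), 95)

  # all-complete spec leaves the table unchanged
  des3 <- cohort_design(20, 20, missingness_spec = data.frame(
    fraction = 1, n_missing = 0))
  tab <- generate_item_responses(
    generate_latents(p, des3, seed = 33), seed = 34)
  expect_identical(inject_missingness(tab, des3, seed = 35), tab)
})

test_that("invalid model combinations are rejected", {
  expect_error(genetic_params("ADE", sigma2_A = 0.2, sigma2_C = 0.1,
                              beta0 = 0), "invalid model")
  expect_error(genetic_params("AE", sigma2_A = 0.2, sigma2_C = 0.1,
                              beta0 = 0), "invalid model")
  expect_error(genetic_params("AE", sigma2_A = -0.1, beta0 = 0),
               "non-negative")
  expect_error(genetic_params("AE", sigma2_A = 0.1, beta0 = 0, beta1 = 1,
                              interaction = FALSE), "beta1")
  expect_error(cohort_design(10, 10, missingness_spec = data.frame(
    fraction = c(0.9, 0.2), n_missing = c(0, 1))), "sum to <= 1")
  expect_error(cohort_design(10, 10, n_items = 3, missingness_spec =
    data.frame(fraction = 0.1, n_missing = 7)), "between 0 and")
})

test_that("ADE latents carry dominance with correlation 0.25 in DZ pairs", {
  p <- genetic_params("ADE", sigma2_A = 0.3, sigma2_D = 0.2,
                      beta0 = log(0.2), beta1 = 0, interaction = FALSE)
  lat <- generate_latents(p, cohort_design(5000, 8000, missingness_spec = NULL),
                          seed = 17)
  d1 <- lat$D[c(TRUE, FALSE)]; d2 <- lat$D[c(FALSE, TRUE)]
  mz <- lat$zygosity[c(TRUE, FALSE)] == "MZ"
  expect_identical(d1[mz], d2[mz])
  expect_equal(cor(d1[!mz], d2[!mz]), 0.25,
               tolerance = 3 / sqrt(8000) / 0.25)
  expect_equal(var(lat$D), 0.2, tolerance = 0.01)
})
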
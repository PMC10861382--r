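test_that("GPCM category probabilities normalize and match enumeration", {
  set.seed(1)
  for (r in 1:100) {
    theta <- rnorm(1, 0, 1.5)
    alpha <- runif(1, 0.3, 2)
    thr <- c(0, sort(runif(6, -2, 2)))
    p <- gpcm_category_probs(theta, alpha, thr)[1, ]
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_equal(p, oracle_gpcm_probs(theta, alpha, thr), tolerance = 1e-12)
  }
})

test_that("two-category GPCM reduces to the logistic model", {
  # K = 2, thresholds (0, b): P(category 2) = logistic(alpha * (theta - b))
  for (theta in c(-1, 0, 0.7)) {
    p <- gpcm_category_probs(theta, 1, c(0, 0.4))[1, ]
    expect_equal(p[2], plogis(theta - 0.4), tolerance = 1e-12)
    expect_equal(p, oracle_gpcm_probs(theta, 1, c(0, 0.4)), tolerance = 1e-12)
  }
})

test_that("zero discrimination yields uniform categories and zero information", {
  p <- gpcm_category_probs(c(-2, 0, 3), 0, c(0, -1, 1, 2))
  expect_equal(p, matrix(0.25, 3, 4), tolerance = 1e-12)
  bank <- item_bank(0, list(c(0, -1, 1)), "GPCM")
  info <- item_information(bank, seq(-3, 3, 0.5))
  expect_equal(unname(info$item[, 1]), rep(0, 13), tolerance = 1e-12)
})

test_that("item information equals the enumerated score variance", {
  bank <- tiny_bank()
  grid <- seq(-2, 2, 0.25)
  info <- item_information(bank, grid)
  expect_true(all(info$item >= 0))
  expect_equal(info$total, rowSums(info$item))
  for (i in 1:2) {
    a <- bank$alpha[i]; thr <- bank$thresholds[[i]]; K <- length(thr)
    oracle <- sapply(grid, function(th) {
      p <- oracle_gpcm_probs(th, a, thr)
      sc <- seq_len(K)
      a^2 * (sum(p * sc^2) - sum(p * sc)^2)
    })
    expect_equal(unname(info$item[, i]), oracle, tolerance = 1e-10)
  }
  expect_error(item_information(bank, numeric(0)), "non-empty")
})

test_that("GRM probabilities normalize and its information is non-negative", {
  bank <- item_bank(c(1.2), list(c(0, -0.8, 0.1, 0.9)), "GRM")
  p <- grm_category_probs(seq(-3, 3, 0.5), 1.2, c(0, -0.8, 0.1, 0.9))
  expect_equal(rowSums(p), rep(1, 13), tolerance = 1e-9)
  expect_true(all(p >= 0))
  info <- item_information(bank, seq(-3, 3, 0.5))
  expect_true(all(info$item >= -1e-12))
  expect_error(item_bank(1, list(c(0, 0.5, 0.2)), "GRM"), "increasing")
})

test_that("item bank construction enforces its invariants", {
  expect_error(item_bank(1, list(c(0))), "at least 2 categories")
  expect_error(item_bank(1, list(c(0.3, 1))), "first threshold")
  expect_error(item_bank(-1, list(c(0, 1))), "non-negative")
  expect_error(item_bank(c(1, 2), list(c(0, 1)), "PCM"),
               "alpha.*and.*thresholds|one entry per item")
  expect_error(gpcm_category_probs(NaN, 1, c(0, 1)), "finite")
})

test_that("marginal likelihood matches a brute-force quadrature evaluation", {
  sim <- small_sim()
  fit <- fit_irt(sim$data, "GPCM", max_iter = 8, select_seed = 5)
  set.seed(5)
  fams <- split(seq_len(nrow(sim$data)), sim$data$family_id)
  rows <- sort(vapply(fams, function(r) r[sample.int(length(r), 1)], integer(1)))
  y <- response_matrix(sim$data)[rows, ]
  # independent recomputation: raw Gauss-Hermite rule from statmod-free code
  n <- 61
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n); J[cbind(1:(n-1), 2:n)] <- off; J[cbind(2:n, 1:(n-1))] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- sqrt(2) * sort(e$values)
  w <- e$vectors[1, order(e$values)]^2
  ll <- 0
  for (j in seq_len(nrow(y))) {
    lik_q <- rep(1, n)
    for (i in seq_len(ncol(y))) {
      if (is.na(y[j, i])) next
      pk <- vapply(nodes, function(th)
        oracle_gpcm_probs(th, fit$item_bank$alpha[i],
                          fit$item_bank$thresholds[[i]])[y[j, i]], numeric(1))
      lik_q <- lik_q * pk
    }
    ll <- ll + log(sum(w * lik_q))
  }
  expect_equal(irt_marginal_loglik(y, fit$item_bank), ll, tolerance = 1e-8)
})

test_that("EM log-likelihood is monotone and the AIC identity holds", {
  sim <- small_sim()
  fit <- fit_irt(sim$data, "GPCM", max_iter = 15)
  expect_true(all(diff(fit$loglik_path) > -1e-6))
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$n_parameters)
  # 9 items x 7 categories: 9 discriminations + 9 * 6 free thresholds
  expect_identical(fit$n_parameters, 63L)
  pcm <- fit_irt(sim$data, "PCM", max_iter = 15)
  expect_identical(pcm$n_parameters, 54L)
})

test_that("PCM log-likelihood never exceeds GPCM on the same data", {
  sim <- small_sim()
  pcm <- fit_irt(sim$data, "PCM", max_iter = 60, tol = 1e-8)
  gpcm <- fit_irt(sim$data, "GPCM", max_iter = 60, tol = 1e-8)
  expect_lte(pcm$loglik, gpcm$loglik + 1e-4)
})

test_that("AIC recovers the generating measurement model", {
  # PCM-generated data: AIC should favour PCM over GPCM in most replicates
  bank_pcm <- item_bank(rep(1, 5),
                        replicate(5, c(0, sort(runif(2, -1, 1))),
                                  simplify = FALSE), "PCM")
  bank_pcm$model_kind <- "GPCM"
  wins <- 0L
  for (r in 1:20) {
    set.seed(400 + r)
    theta <- rnorm(500)
    lat <- data.frame(family_id = seq_len(500), zygosity = "DZ", twin = 1,
                      theta = theta)
    tab <- generate_item_responses(lat, bank_pcm, seed = 500 + r)
    y <- response_matrix(tab)
    f_pcm <- fit_irt(y, "PCM", max_iter = 25)
    f_gpcm <- fit_irt(y, "GPCM", max_iter = 25)
    if (f_pcm$AIC < f_gpcm$AIC) wins <- wins + 1L
  }
  expect_gte(wins, 11L)
})

test_that("GPCM discrimination parameters are recovered from GPCM data", {
  bank <- swan_item_bank()
  set.seed(77)
  lat <- data.frame(family_id = seq_len(2000), zygosity = "DZ", twin = 1,
                    theta = rnorm(2000))
  tab <- generate_item_responses(lat, bank, seed = 78)
  fit <- fit_irt(response_matrix(tab), "GPCM", max_iter = 35)
  err <- mean(abs(fit$item_bank$alpha - bank$alpha))
  expect_lt(err, 0.15)
})

test_that("classical scale statistics match direct recomputation", {
  sim <- small_sim()
  cs <- classical_stats(sim$data)
  y <- response_matrix(sim$data)
  # direct spreadsheet-style recomputation of alpha
  I <- ncol(y)
  alpha_direct <- (I / (I - 1)) *
    (1 - sum(apply(y, 2, var)) / var(rowSums(y)))
  expect_equal(cs$alpha, alpha_direct)
  expect_equal(cs$item_rest[1], cor(y[, 1], rowSums(y[, -1])))

  # two duplicated items: alpha = 1
  dup <- data.frame(family_id = rep(1:100, each = 2), zygosity = "MZ",
                    twin = rep(1:2, 100),
                    item_1 = rep(1:5, 40), item_2 = rep(1:5, 40))
  dup <- twinace:::new_item_response_table(dup, c(5L, 5L))
  expect_equal(classical_stats(dup)$alpha, 1)

  # constant item: flagged undefined item-rest (the constant rest also
  # makes the other item's item-rest correlation warn)
  con <- dup; con$item_2 <- 3L
  w <- capture_warnings(cs2 <- classical_stats(con))
  expect_true(any(grepl("zero variance", w)))
  expect_true(is.na(cs2$item_rest[2]))
})
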
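# shared fixtures, built in code at test time

table2_params <- function(beta1 = 2.2) {
  genetic_params("AE", sigma2_A = 0.25, beta0 = log(0.19), beta1 = beta1,
                 interaction = beta1 != 0)
}

tiny_bank <- function() {
  item_bank(alpha = c(1, 1.3),
            thresholds = list(c(0, -0.5, 0.5), c(0, 0.3)),
            model_kind = "GPCM")
}

# small complete cohort reused by several tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- genetic_params("AE", sigma2_A = 0.25, beta0 = log(0.19), beta1 = 0,
                          interaction = FALSE)
      cache <<- simulate_twin_cohort(p, cohort_design(60, 90,
        missingness_spec = NULL), seed = 42)
    }
    cache
  }
})

# independent slow GPCM category probabilities by direct enumeration of the
# cumulative sums (oracle; no shared code with the package)
oracle_gpcm_probs <- function(theta, alpha, thresholds) {
  K <- length(thresholds)
  s <- numeric(K)
  for (k in seq_len(K)) s[k] <- sum(alpha * (theta - thresholds[seq_len(k)]))
  exp(s) / sum(exp(s))
}
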
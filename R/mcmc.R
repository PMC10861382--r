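flavour_code <- function(flavour) match(flavour, c("AE", "ACE", "ADE")) - 1L

hyper_names <- function(spec) {
  c("sigma2_A",
    if (spec$flavour == "ACE") "sigma2_C",
    if (spec$flavour == "ADE") "sigma2_D",
    "beta0",
    if (spec$interaction) "beta1")
}

param_names <- function(spec, K) {
  I <- length(K)
  thr <- unlist(lapply(seq_len(I), function(i) paste0("b_", i, "_", 2:K[i])))
  c(hyper_names(spec), paste0("alpha_", seq_len(I)), thr)
}

# order rows family-major (twin 1 then 2) and validate pairing
canonical_table <- function(data) {
  stopifnot(all(c("family_id", "zygosity", "twin") %in% names(data)))
  data <- data[order(match(data$family_id, unique(data$family_id)), data$twin), ]
  tab <- table(data$family_id)
  if (any(tab != 2)) stop("every family must contribute exactly two twins")
  if (!all(data$zygosity %in% c("MZ", "DZ"))) stop("unknown zygosity code")
  rownames(data) <- NULL
  data
}

chain_init <- function(y, K, spec, mz) {
  N <- nrow(y)
  mid <- (K + 1) / 2
  sc <- sweep(y, 2, mid)
  rs <- rowMeans(sc, na.rm = TRUE)
  rs[is.nan(rs)] <- 0
  z <- (rs - mean(rs)) / max(stats::sd(rs), 1e-6)
  theta0 <- 0.7 * z + stats::rnorm(N, 0, 0.1)
  A0 <- 0.5 * theta0
  fam_mz <- rep(mz, each = 2L)
  # MZ twins must share the additive value
  pair_mean <- rep((A0[c(TRUE, FALSE)] + A0[c(FALSE, TRUE)]) / 2, each = 2L)
  A0[fam_mz] <- pair_mean[fam_mz]
  C0 <- numeric(N / 2)
  D0 <- numeric(N)
  E0 <- theta0 - A0
  I <- length(K)
  Kmax <- max(K)
  thr0 <- matrix(0, I, Kmax)
  for (i in seq_len(I))
    thr0[i, 2:K[i]] <- seq(-1, 1, length.out = K[i] - 1) + stats::rnorm(1, 0, 0.05)
  alpha0 <- exp(stats::rnorm(I, 0, 0.05))
  if (spec$anchor == "alpha1") alpha0[1] <- 1
  list(A = A0, C = C0, D = D0, E = E0,
       alpha = alpha0, thresholds = thr0,
       s2A = exp(stats::rnorm(1, log(0.25), 0.2)),
       s2C = if (spec$flavour == "ACE") 0.15 else 0,
       s2D = if (spec$flavour == "ADE") 0.15 else 0,
       beta0 = log(0.25) + stats::rnorm(1, 0, 0.2),
       beta1 = 0)
}

#' Fit the joint measurement + biometric model by MCMC
#'
#' Runs a Metropolis-within-Gibbs sampler for the one-step model: GPCM
#' measurement of the latent trait combined with the AE/ACE/ADE variance
#' decomposition and, optionally, the log-linear genotype-environment
#' interaction. Each iteration updates, in turn, imputed values for missing
#' item scores (drawn from the GPCM predictive), the per-individual latent
#' components, the item parameters, and the hyperparameters; proposal step
#' sizes adapt during burn-in only. The deviance (twice the negative GPCM
#' log-likelihood of the originally observed responses) is recorded for
#' every retained draw.
#'
#' @param data an `item_response_table` (or data frame with `family_id`,
#'   `zygosity`, `twin` and `item_*` columns); each family must contribute
#'   exactly two twins.
#' @param spec a [model_spec].
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param burn_in discarded iterations per chain.
#' @param iterations retained iterations per chain (after thinning).
#' @param thin thinning interval.
#' @param seed integer master seed; chain `c` uses `seed + c - 1`.
#' @return A `posterior_fit`: list with `draws` (per-chain matrices with
#'   named columns), `deviance` (per-chain traces), `dic` (Dbar, pD, DIC),
#'   `psrf` (per-hyperparameter potential scale reduction factors),
#'   `converged` (all PSRF <= 1.1), `latent` (posterior means of `theta` and
#'   `A` per individual), `spec`, `settings` and a `data_fingerprint`.
#' @export
#' @examples
#' \donttest{
#' p <- genetic_params("AE", sigma2_A = 0.25, beta0 = log(0.19), beta1 = 2.2)
#' sim <- simulate_twin_cohort(p, cohort_design(40, 60), seed = 1)
#' fit <- run_chains(sim$data, model_spec("AE", interaction = TRUE),
#'                   burn_in = 200, iterations = 200, seed = 1)
#' summarize_fit(fit)
#' }
run_chains <- function(data, spec, n_chains = 2, burn_in = 5000,
                       iterations = 10000, thin = 1, seed) {
  stopifnot(inherits(spec, "model_spec"), n_chains >= 1,
            burn_in >= 0, iterations >= 1, thin >= 1)
  data <- canonical_table(data)
  y <- response_matrix(data)
  storage.mode(y) <- "integer"
  K <- attr(data, "n_categories")
  if (is.null(K)) K <- apply(y, 2, max, na.rm = TRUE)
  K <- as.integer(K)
  miss <- is.na(y)
  mz <- data$zygosity[c(TRUE, FALSE)] == "MZ"
  pn <- param_names(spec, K)

  draws <- vector("list", n_chains)
  devs <- vector("list", n_chains)
  theta_mean <- A_mean <- matrix(0, nrow(y), n_chains)
  alpha_mean <- matrix(0, ncol(y), n_chains)
  thr_mean <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    init <- chain_init(y, K, spec, mz)
    res <- sampler_run(y, miss, K, mz, flavour_code(spec$flavour),
                       spec$interaction,
                       if (spec$anchor == "alpha1") 1L else 0L,
                       unclass(spec$priors), init,
                       as.integer(burn_in), as.integer(iterations),
                       as.integer(thin))
    colnames(res$draws) <- pn
    draws[[ch]] <- res$draws
    devs[[ch]] <- res$deviance
    theta_mean[, ch] <- res$theta_mean
    A_mean[, ch] <- res$A_mean
    alpha_mean[, ch] <- res$alpha_mean
    thr_mean[[ch]] <- res$thr_mean
  }

  fit <- structure(list(
    draws = draws, deviance = devs, spec = spec,
    settings = list(n_chains = n_chains, burn_in = burn_in,
                    iterations = iterations, thin = thin, seed = seed),
    latent = list(theta = rowMeans(theta_mean), A = rowMeans(A_mean)),
    item_means = list(alpha = rowMeans(alpha_mean),
                      thresholds = Reduce(`+`, thr_mean) / n_chains),
    data_fingerprint = data_fingerprint(data),
    families = list(n_mz = sum(mz), n_dz = sum(!mz)), K = K
  ), class = "posterior_fit")

  # conditional-deviance DIC at the posterior means of latents + item params
  thr_list <- lapply(seq_along(K), function(i) fit$item_means$thresholds[i, 1:K[i]])
  d_hat <- -2 * cpp_table_loglik(y, fit$latent$theta, fit$item_means$alpha, thr_list)
  d_bar <- mean(unlist(devs))
  fit$dic <- list(Dbar = d_bar, pD = d_bar - d_hat, DIC = 2 * d_bar - d_hat)

  if (n_chains >= 2) {
    fit$psrf <- vapply(hyper_names(spec), function(p) gelman_rubin(fit, p),
                       numeric(1))
    fit$converged <- all(fit$psrf <= 1.1)
  } else {
    fit$psrf <- NULL
    fit$converged <- NA
  }
  fit
}

data_fingerprint <- function(data) {
  y <- response_matrix(data)
  c(n = nrow(y), items = ncol(y),
    sum = sum(y, na.rm = TRUE), n_missing = sum(is.na(y)))
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("<posterior_fit> %s: %d chains x %d draws, DIC = %.1f%s\n",
              model_label(x$spec), x$settings$n_chains, x$settings$iterations,
              x$dic$DIC,
              if (isFALSE(x$converged)) " [NOT CONVERGED]" else ""))
  invisible(x)
}

# pull one parameter's chains from a posterior_fit as a list of vectors
chain_values <- function(fit, parameter) {
  lapply(fit$draws, function(d) {
    if (!parameter %in% colnames(d)) stop("unknown parameter: ", parameter)
    d[, parameter]
  })
}

# all chains pooled
pooled <- function(fit, parameter) unlist(chain_values(fit, parameter))

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed from the between- and within-chain variances of equal-length
#' chains: \eqn{\hat{V} = \frac{n-1}{n} W + \frac{1}{n} B} with
#' \eqn{B = n \cdot \mathrm{var}(\bar{x}_m)}, and
#' \eqn{\mathrm{PSRF} = \sqrt{\hat{V} / W}}. Values near 1 indicate the
#' chains sample the same distribution; values well above 1.1 flag
#' non-stationarity.
#'
#' @param fit a `posterior_fit`, or a list of >= 2 equal-length numeric
#'   chains.
#' @param parameter parameter name (when `fit` is a `posterior_fit`).
#' @return The PSRF (scalar).
#' @export
gelman_rubin <- function(fit, parameter = NULL) {
  chains <- if (inherits(fit, "posterior_fit")) chain_values(fit, parameter)
            else fit
  if (!is.list(chains) || length(chains) < 2)
    stop("need at least two chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length")
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Deviance information criterion
#'
#' \eqn{\mathrm{DIC} = \bar{D} + p_D} with \eqn{p_D = \bar{D} - D(\hat\psi)}:
#' the posterior-mean deviance plus the effective number of parameters,
#' where \eqn{D(\hat\psi)} is the deviance at the posterior means of the
#' sampled quantities (here conditional on the individual latent traits and
#' item parameters).
#'
#' @param fit a `posterior_fit` (uses its stored deviance trace and
#'   point-estimate deviance), or a numeric deviance trace.
#' @param d_hat deviance at the point estimate (required when `fit` is a
#'   numeric trace).
#' @return List with `Dbar`, `pD` and `DIC`.
#' @export
#' @examples
#' dic(c(10, 12, 14), d_hat = 9)  # Dbar 12, pD 3, DIC 15
dic <- function(fit, d_hat = NULL) {
  if (inherits(fit, "posterior_fit")) {
    if (is.null(fit$dic)) stop("fit carries no deviance trace")
    return(fit$dic)
  }
  if (length(fit) == 0) stop("empty deviance trace")
  if (is.null(d_hat)) stop("`d_hat` required for a raw deviance trace")
  d_bar <- mean(fit)
  list(Dbar = d_bar, pD = d_bar - d_hat, DIC = 2 * d_bar - d_hat)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing a given posterior mass,
#' found by exhaustively sliding a window of \eqn{m = \lceil p \cdot n
#' \rceil} draws over the sorted sample and taking the narrowest.
#'
#' @param draws numeric vector of posterior draws.
#' @param prob probability mass, in (0, 1).
#' @return Named vector `c(lower, upper)`.
#' @export
#' @examples
#' hpd_interval(rnorm(5000), 0.95)
hpd_interval <- function(draws, prob = 0.95) {
  if (prob <= 0 || prob >= 1) stop("`prob` must be in (0, 1)")
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  if (n < 2) stop("need at least two draws")
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  i <- which.min(x[(m + 1):n] - x[1:(n - m)])
  c(lower = x[i], upper = x[i + m])
}

#' Conjugate Gibbs sampler for the AE model with observed traits
#'
#' Validation sampler for the homoscedastic AE subcase in which the latent
#' trait is treated as directly observed (no measurement layer):
#' \eqn{\theta_j = A_j + E_j}, MZ pairs sharing A, DZ pairs correlating 0.5,
#' \eqn{E_j \sim N(0, \sigma^2_E)}. With inverse-gamma priors on both
#' variances every full conditional is available in closed form, so this is
#' a pure Gibbs sampler — used to check the main sampler's machinery against
#' a grid-posterior oracle.
#'
#' @param theta observed trait values, family-major order (two per family).
#' @param mz logical per family: is the pair monozygotic?
#' @param n_iter retained iterations.
#' @param burn_in discarded iterations.
#' @param prior_shape,prior_rate inverse-gamma prior parameters shared by
#'   \eqn{\sigma^2_A} and \eqn{\sigma^2_E}.
#' @param seed integer seed.
#' @return Matrix of draws with columns `sigma2_A`, `sigma2_E`.
#' @export
ae_theta_gibbs <- function(theta, mz, n_iter = 4000, burn_in = 1000,
                           prior_shape = 1, prior_rate = 0.5, seed = 1) {
  set.seed(as.integer(seed))
  F <- length(mz)
  stopifnot(length(theta) == 2 * F)
  t1 <- theta[c(TRUE, FALSE)]; t2 <- theta[c(FALSE, TRUE)]
  s2A <- 0.5; s2E <- 0.5
  A1 <- A2 <- numeric(F)
  out <- matrix(NA_real_, n_iter, 2,
                dimnames = list(NULL, c("sigma2_A", "sigma2_E")))
  rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape, rate = rate)
  for (it in seq_len(burn_in + n_iter)) {
    # A | theta (MZ: shared scalar; DZ: bivariate normal conditional)
    if (any(mz)) {
      prec <- 1 / s2A + 2 / s2E
      mu <- ((t1[mz] + t2[mz]) / s2E) / prec
      A1[mz] <- A2[mz] <- stats::rnorm(sum(mz), mu, sqrt(1 / prec))
    }
    if (any(!mz)) {
      # prior precision of (A1, A2): inverse of s2A * [[1, .5], [.5, 1]]
      p11 <- (4 / 3) / s2A; p12 <- -(2 / 3) / s2A
      q11 <- p11 + 1 / s2E; q12 <- p12
      det <- q11^2 - q12^2
      v11 <- q11 / det; v12 <- -q12 / det
      m1 <- (v11 * t1[!mz] + v12 * t2[!mz]) / s2E
      m2 <- (v12 * t1[!mz] + v11 * t2[!mz]) / s2E
      z1 <- stats::rnorm(sum(!mz)); z2 <- stats::rnorm(sum(!mz))
      L11 <- sqrt(v11); L21 <- v12 / L11; L22 <- sqrt(v11 - L21^2)
      A1[!mz] <- m1 + L11 * z1
      A2[!mz] <- m2 + L21 * z1 + L22 * z2
    }
    # sigma2_A | A: MZ pairs add 1/2 to the shape, DZ pairs 1
    q_dz <- (A1[!mz]^2 + A2[!mz]^2 - A1[!mz] * A2[!mz]) / 0.75
    s2A <- rinvgamma(1, prior_shape + sum(mz) / 2 + sum(!mz),
                     prior_rate + sum(A1[mz]^2) / 2 + sum(q_dz) / 2)
    # sigma2_E | residuals
    E <- c(rbind(t1 - A1, t2 - A2))
    s2E <- rinvgamma(1, prior_shape + length(E) / 2,
                     prior_rate + sum(E^2) / 2)
    if (it > burn_in) out[it - burn_in, ] <- c(s2A, s2E)
  }
  out
}
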
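#' Unique-environmental variance under genotype-environment interaction
#'
#' The unique-environmental variance is modelled log-linearly in the latent
#' genetic value, \eqn{\sigma^2_{Ej} = \exp(\beta_0 + \beta_1 g_j)}; the
#' exponential guarantees positivity, and the sign of \eqn{\beta_1} sets the
#' direction of the interaction (more environmental variance at high or at
#' low genetic values).
#'
#' @param beta0 intercept: log variance at genetic value 0.
#' @param beta1 interaction slope.
#' @param g genetic value(s); additive (\eqn{A_j}) under AE/ACE, total
#'   (\eqn{G_j = A_j + D_j}) under ADE.
#' @return `exp(beta0 + beta1 * g)`, always positive; vectorized over `g`.
#' @export
#' @examples
#' env_variance(log(0.19), 2.20, 0)    # 0.19
#' env_variance(log(0.19), 2.20, 0.5)  # 0.19 * exp(1.1)
env_variance <- function(beta0, beta1, g) {
  if (!all(is.finite(c(beta0, beta1, g)))) stop("inputs must be finite")
  exp(beta0 + beta1 * g)
}

#' Narrow-sense heritability
#'
#' \eqn{h^2 = \sigma^2_A / (\sigma^2_A + \sigma^2_C + \exp(\beta_0))}: the
#' proportion of phenotypic variance (evaluated at genetic value 0, so the
#' unique-environment component enters as the plug-in \eqn{\exp(\beta_0)})
#' attributable to additive genetic effects. Under an AE model
#' \eqn{\sigma^2_C = 0}.
#'
#' @param sigma2_A additive genetic variance, or a [genetic_params] object
#'   (in which case the remaining arguments are taken from it).
#' @param exp_beta0 unique-environmental variance at genetic value 0.
#' @param sigma2_C shared-environment variance (default 0).
#' @return Proportion in \[0, 1\].
#' @export
#' @examples
#' heritability(0.25, exp_beta0 = 0.19)          # 0.568 -> "57%"
#' heritability(0.27, exp_beta0 = 0.51, sigma2_C = 0.31)
heritability <- function(sigma2_A, exp_beta0, sigma2_C = 0) {
  if (inherits(sigma2_A, "genetic_params")) {
    p <- sigma2_A
    sigma2_A <- p$sigma2_A; exp_beta0 <- exp(p$beta0); sigma2_C <- p$sigma2_C
  }
  if (sigma2_A < 0 || exp_beta0 < 0 || sigma2_C < 0)
    stop("variance components must be non-negative")
  tot <- sigma2_A + sigma2_C + exp_beta0
  if (tot <= 0) stop("total phenotypic variance is zero")
  sigma2_A / tot
}

#' Interaction effect size
#'
#' The factor by which the unique-environmental variance increases for an
#' individual whose additive genetic value equals one genetic standard
#' deviation: \eqn{\exp(\beta_1 \sqrt{\sigma^2_A})}.
#'
#' @param beta1 interaction slope.
#' @param sigma2_A additive genetic variance (>= 0).
#' @return The fold-change factor; 1 when `beta1 = 0`.
#' @export
#' @examples
#' interaction_effect_size(2.20, 0.25)  # exp(1.1) ~ 3.00
interaction_effect_size <- function(beta1, sigma2_A) {
  if (sigma2_A < 0) stop("sigma2_A must be non-negative")
  exp(beta1 * sqrt(sigma2_A))
}

#' Total phenotypic variance at genetic value zero
#'
#' The sum of the model's variance components with the unique-environment
#' component evaluated at genetic value 0 (plug-in \eqn{\exp(\beta_0)}):
#' \eqn{\sigma^2_A (+\sigma^2_C)(+\sigma^2_D) + \exp(\beta_0)}.
#'
#' @param params a [genetic_params] object.
#' @return Variance on the latent-trait scale.
#' @export
#' @examples
#' total_phenotypic_variance(
#'   genetic_params("AE", sigma2_A = 0.25, beta0 = log(0.19), beta1 = 2.2))
total_phenotypic_variance <- function(params) {
  stopifnot(inherits(params, "genetic_params"))
  params$sigma2_A + params$sigma2_C + params$sigma2_D + exp(params$beta0)
}

#' Prior specification for the joint model
#'
#' Weakly-informative defaults: half-normal(scale) priors on the standard
#' deviations \eqn{\sigma_A, \sigma_C, \sigma_D}; normal(0, sd) priors on
#' \eqn{\beta_0}, \eqn{\beta_1} and the free item thresholds; lognormal
#' priors on the free discriminations. All proper, all positive-support
#' where the parameter requires it.
#'
#' @param sigma_scale scale of the half-normal priors on the component SDs.
#' @param beta_sd prior SD for `beta0` and `beta1`.
#' @param threshold_sd prior SD for free item thresholds.
#' @param alpha_meanlog,alpha_sdlog lognormal prior parameters for free
#'   discriminations.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(sigma_scale = 2, beta_sd = 10, threshold_sd = 10,
                       alpha_meanlog = 0, alpha_sdlog = 1) {
  stopifnot(sigma_scale > 0, beta_sd > 0, threshold_sd > 0, alpha_sdlog > 0)
  structure(list(sigma_scale = sigma_scale, beta_sd = beta_sd,
                 threshold_sd = threshold_sd, alpha_meanlog = alpha_meanlog,
                 alpha_sdlog = alpha_sdlog),
            class = "prior_spec")
}

#' Specify a joint measurement + biometric model
#'
#' @param flavour `"AE"`, `"ACE"` or `"ADE"`.
#' @param interaction logical: include the log-linear genotype-environment
#'   interaction (AxE, or GxE under ADE)?
#' @param priors a [prior_spec].
#' @param anchor scale identification (the latent mean is always fixed at 0
#'   and the first threshold of every item at 0): `"geomean"` (default)
#'   samples with all discriminations free and rescales every recorded draw
#'   to the identified scale on which the geometric mean of the
#'   discriminations is 1 — a parameter-expansion scheme that spreads the
#'   scale information over all items; `"alpha1"` instead fixes the first
#'   item's discrimination at 1.
#' @return A `model_spec` object.
#' @export
#' @examples
#' model_spec("AE", interaction = TRUE)
model_spec <- function(flavour = c("AE", "ACE", "ADE"), interaction = FALSE,
                       priors = prior_spec(), anchor = c("geomean", "alpha1")) {
  flavour <- match.arg(flavour)
  anchor <- match.arg(anchor)
  stopifnot(is.logical(interaction), inherits(priors, "prior_spec"))
  structure(list(flavour = flavour, interaction = interaction,
                 priors = priors, anchor = anchor),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s%s, anchor=%s\n", x$flavour,
              if (x$interaction) " + AxE" else "", x$anchor))
  invisible(x)
}

model_label <- function(spec) {
  paste0(spec$flavour, if (spec$interaction)
    if (spec$flavour == "ADE") "+GxE" else "+AxE" else "")
}

# family layout helper: row indices and zygosity per family, in table order
family_layout <- function(table) {
  fams <- unique(table$family_id)
  rows <- split(seq_len(nrow(table)), factor(table$family_id, levels = fams))
  zyg <- vapply(rows, function(r) as.character(table$zygosity[r[1]]), character(1))
  list(ids = fams, rows = rows, zygosity = zyg)
}

# log density of the additive-genetic (or dominance) pair values given the
# component variance and the within-DZ correlation rho (0.5 additive, 0.25
# dominance); MZ pairs share a single draw.
pair_component_logdens <- function(x1, x2, mz, s2, rho) {
  if (s2 <= 0) stop("component variance must be positive for density evaluation")
  out <- numeric(length(x1))
  if (any(mz)) out[mz] <- stats::dnorm(x1[mz], 0, sqrt(s2), log = TRUE)
  if (any(!mz)) {
    a <- x1[!mz]; b <- x2[!mz]
    det <- s2^2 * (1 - rho^2)
    q <- (a^2 + b^2 - 2 * rho * a * b) / (s2 * (1 - rho^2))
    out[!mz] <- -log(2 * pi) - 0.5 * log(det) - 0.5 * q
  }
  out
}

half_normal_var_logprior <- function(s2, scale) {
  # prior stated on the SD sigma ~ half-normal(scale); change of variables
  # to the variance: p(s2) = p_sigma(sqrt(s2)) / (2 sqrt(s2))
  sig <- sqrt(s2)
  log(sqrt(2 / pi) / scale) - sig^2 / (2 * scale^2) - log(2 * sig)
}

#' Joint log density of the one-step model
#'
#' Evaluates the log of the joint density of data and model state: the GPCM
#' log-probabilities of the observed (and, if supplied, imputed) responses
#' at \eqn{\theta_j = A_j + C_j + D_j + E_j}, plus the log densities of the
#' latent components under the family covariance structure (MZ pairs share
#' A and D; DZ pairs correlate 0.5 and 0.25; C is family-shared; E is
#' independent with variance \eqn{\exp(\beta_0 + \beta_1 g_j)}), plus,
#' optionally, the log priors on hyperparameters and item parameters.
#'
#' @param state list with elements `params` (a [genetic_params]), `items`
#'   (an [item_bank]) and `latents` (data frame with columns `A`, `C`, `D`,
#'   `E`, one row per row of `data`); optionally `imputed`, an integer
#'   matrix shaped like `response_matrix(data)` providing category values
#'   for missing cells (missing cells are marginalized out — contribute
#'   nothing — when `imputed` is absent).
#' @param data an `item_response_table`.
#' @param spec a [model_spec].
#' @param include_priors include the log prior terms? (`TRUE` by default;
#'   turn off to work with the likelihood-times-latent-density alone.)
#' @return A single finite log-density value.
#' @export
joint_log_density <- function(state, data, spec, include_priors = TRUE) {
  params <- state$params; items <- state$items; lat <- state$latents
  stopifnot(inherits(params, "genetic_params"), inherits(items, "item_bank"),
            nrow(lat) == nrow(data))
  y <- response_matrix(data)
  if (!is.null(state$imputed)) {
    imp <- state$imputed
    y[is.na(y)] <- imp[is.na(y)]
  }
  theta <- lat$A + lat$C + lat$D + lat$E
  ll <- 0
  for (i in seq_len(n_items(items))) {
    yi <- y[, i]
    obs <- !is.na(yi)
    if (!any(obs)) next
    if (any(yi[obs] < 1 | yi[obs] > items$K[i])) stop("invalid category index")
    p <- category_probs(theta[obs], items$alpha[i], items$thresholds[[i]],
                        items$model_kind)
    ll <- ll + sum(log(p[cbind(seq_len(sum(obs)), yi[obs])]))
  }

  lay <- family_layout(data)
  first <- vapply(lay$rows, `[`, integer(1), 1L)
  second <- vapply(lay$rows, `[`, integer(1), 2L)
  mz <- lay$zygosity == "MZ"
  ll <- ll + sum(pair_component_logdens(lat$A[first], lat$A[second], mz,
                                        params$sigma2_A, 0.5))
  if (params$model == "ADE")
    ll <- ll + sum(pair_component_logdens(lat$D[first], lat$D[second], mz,
                                          params$sigma2_D, 0.25))
  if (params$model == "ACE")
    ll <- ll + sum(stats::dnorm(lat$C[first], 0, sqrt(params$sigma2_C), log = TRUE))
  g <- if (params$model == "ADE") lat$A + lat$D else lat$A
  ll <- ll + sum(stats::dnorm(lat$E, 0,
                              sqrt(env_variance(params$beta0, params$beta1, g)),
                              log = TRUE))

  if (include_priors) {
    pr <- spec$priors
    lp <- half_normal_var_logprior(params$sigma2_A, pr$sigma_scale)
    if (params$model == "ACE")
      lp <- lp + half_normal_var_logprior(params$sigma2_C, pr$sigma_scale)
    if (params$model == "ADE")
      lp <- lp + half_normal_var_logprior(params$sigma2_D, pr$sigma_scale)
    lp <- lp + stats::dnorm(params$beta0, 0, pr$beta_sd, log = TRUE)
    if (spec$interaction)
      lp <- lp + stats::dnorm(params$beta1, 0, pr$beta_sd, log = TRUE)
    free_alpha <- if (spec$anchor == "alpha1") -1L else TRUE
    a_free <- if (identical(free_alpha, -1L)) items$alpha[-1L] else items$alpha
    if (length(a_free))
      lp <- lp + sum(stats::dlnorm(a_free, pr$alpha_meanlog, pr$alpha_sdlog,
                                   log = TRUE))
    for (b in items$thresholds)
      lp <- lp + sum(stats::dnorm(b[-1L], 0, pr$threshold_sd, log = TRUE))
    ll <- ll + lp
  }
  ll
}
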
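#' Posterior summary table
#'
#' Posterior mean, SD and 95\% HPD interval of every hyperparameter,
#' followed by derived rows: `exp_beta0` (unique-environmental variance at
#' genetic value 0), narrow-sense heritability `h2` (both the posterior
#' mean of the per-draw ratio and, as `h2_plugin`, the ratio of posterior
#' means — the definition used for headline reporting), total phenotypic
#' variance and, for interaction models, the effect size
#' \eqn{\exp(\beta_1\sqrt{\sigma^2_A})} evaluated at the posterior means.
#' A parameter is flagged significant when its HPD interval excludes zero;
#' variance components, which are bounded below by zero, are never flagged.
#'
#' @param fit a `posterior_fit` from [run_chains()].
#' @param prob HPD mass (default 0.95).
#' @return A data frame with columns `parameter`, `mean`, `sd`, `hpd_lower`,
#'   `hpd_upper`, `significant`.
#' @export
summarize_fit <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "posterior_fit"))
  spec <- fit$spec
  hp <- hyper_names(spec)
  rows <- lapply(hp, function(p) {
    x <- pooled(fit, p)
    h <- hpd_interval(x, prob)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               hpd_lower = h[1], hpd_upper = h[2],
               significant = if (startsWith(p, "sigma2")) NA
                             else h[1] > 0 | h[2] < 0)
  })
  b0 <- pooled(fit, "beta0")
  eb0 <- exp(b0)
  h_eb0 <- hpd_interval(eb0, prob)
  rows[[length(rows) + 1L]] <- data.frame(
    parameter = "exp_beta0", mean = mean(eb0), sd = stats::sd(eb0),
    hpd_lower = h_eb0[1], hpd_upper = h_eb0[2], significant = NA)

  s2A <- pooled(fit, "sigma2_A")
  s2C <- if (spec$flavour == "ACE") pooled(fit, "sigma2_C") else 0
  h2_draws <- s2A / (s2A + s2C + eb0)
  h_h2 <- hpd_interval(h2_draws, prob)
  h2_plug <- heritability(mean(s2A), exp_beta0 = mean(eb0),
                          sigma2_C = if (spec$flavour == "ACE") mean(s2C) else 0)
  rows[[length(rows) + 1L]] <- data.frame(
    parameter = "h2", mean = mean(h2_draws), sd = stats::sd(h2_draws),
    hpd_lower = h_h2[1], hpd_upper = h_h2[2], significant = NA)
  rows[[length(rows) + 1L]] <- data.frame(
    parameter = "h2_plugin", mean = h2_plug, sd = NA_real_,
    hpd_lower = NA_real_, hpd_upper = NA_real_, significant = NA)
  tot <- mean(s2A) + (if (spec$flavour == "ACE") mean(s2C) else 0) +
    (if (spec$flavour == "ADE") mean(pooled(fit, "sigma2_D")) else 0) + mean(eb0)
  rows[[length(rows) + 1L]] <- data.frame(
    parameter = "total_variance", mean = tot, sd = NA_real_,
    hpd_lower = NA_real_, hpd_upper = NA_real_, significant = NA)
  if (spec$interaction) {
    es <- interaction_effect_size(mean(pooled(fit, "beta1")), mean(s2A))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "effect_size", mean = es, sd = NA_real_,
      hpd_lower = NA_real_, hpd_upper = NA_real_, significant = NA)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Credibility band of the interaction curve
#'
#' For each genetic value on a grid, quantiles over the posterior draws of
#' the unique-environmental variance \eqn{\exp(\beta_0 + \beta_1 g)}: the
#' median and an equal-tailed 95\% band by default (the band at \eqn{g = 0}
#' is exactly the posterior band of \eqn{\exp(\beta_0)}).
#'
#' @param fit a `posterior_fit`.
#' @param g_grid genetic-value grid; defaults to the sorted posterior means
#'   of the individual additive genetic values (the estimated range of
#'   genetic values in the sample).
#' @param prob band mass (default 0.95).
#' @param type `"equal_tail"` (default) or `"hpd"` per grid point.
#' @return Data frame with columns `g`, `median`, `lower`, `upper`.
#' @export
credibility_curve <- function(fit, g_grid = NULL, prob = 0.95,
                              type = c("equal_tail", "hpd")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "posterior_fit"))
  if (is.null(g_grid)) g_grid <- sort(fit$latent$A)
  if (length(g_grid) == 0) stop("`g_grid` must be non-empty")
  b0 <- pooled(fit, "beta0")
  b1 <- if (fit$spec$interaction) pooled(fit, "beta1") else rep(0, length(b0))
  lo_p <- (1 - prob) / 2
  out <- t(vapply(g_grid, function(g) {
    v <- exp(b0 + b1 * g)
    if (type == "equal_tail") {
      q <- stats::quantile(v, c(0.5, lo_p, 1 - lo_p), names = FALSE)
    } else {
      h <- hpd_interval(v, prob)
      q <- c(stats::median(v), h[1], h[2])
    }
    q
  }, numeric(3)))
  data.frame(g = g_grid, median = out[, 1], lower = out[, 2], upper = out[, 3])
}

#' DIC model-comparison table
#'
#' Ranks fits of the same data by DIC and flags the preferred (lowest DIC)
#' model; ties are all flagged and broken deterministically by model name.
#'
#' @param fits list of `posterior_fit` objects for the same data set.
#' @return Data frame with `model`, `DIC`, `Dbar`, `pD`, `preferred`,
#'   ordered by DIC.
#' @export
model_selection_table <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "posterior_fit")))
  fps <- lapply(fits, `[[`, "data_fingerprint")
  if (length(unique(lapply(fps, unname))) != 1)
    stop("fits are not based on the same data")
  tab <- data.frame(
    model = vapply(fits, function(f) model_label(f$spec), character(1)),
    DIC = vapply(fits, function(f) f$dic$DIC, numeric(1)),
    Dbar = vapply(fits, function(f) f$dic$Dbar, numeric(1)),
    pD = vapply(fits, function(f) f$dic$pD, numeric(1)))
  tab <- tab[order(tab$DIC, tab$model), ]
  tab$preferred <- tab$DIC == min(tab$DIC)
  rownames(tab) <- NULL
  tab
}
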
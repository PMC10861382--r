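#' Describe a twin cohort to simulate
#'
#' @param n_mz number of monozygotic (MZ) twin pairs.
#' @param n_dz number of dizygotic (DZ) twin pairs.
#' @param n_items number of questionnaire items.
#' @param n_categories per-item category counts \eqn{K_i \ge 2}; a single
#'   value is recycled to all items.
#' @param missingness_spec data frame with columns `fraction` (of families)
#'   and `n_missing` (item scores missing per family, out of the family's
#'   `2 * n_items` scores). Fractions must sum to at most 1; any remainder is
#'   left complete. The default emulates the missingness pattern of a large
#'   adolescent twin cohort: 95\% complete families, 2\% missing a single
#'   score, 1\% missing a handful, 2\% with one twin's scale entirely absent.
#' @return A `cohort_design` object.
#' @export
#' @examples
#' cohort_design(n_mz = 100, n_dz = 150)
cohort_design <- function(n_mz, n_dz, n_items = 9, n_categories = 7,
                          missingness_spec = data.frame(
                            fraction = c(0.95, 0.02, 0.01, 0.02),
                            n_missing = c(0, 1, 5, 9))) {
  n_mz <- as.integer(n_mz); n_dz <- as.integer(n_dz)
  if (n_mz < 0 || n_dz < 0) stop("pair counts must be non-negative")
  n_categories <- as.integer(rep_len(n_categories, n_items))
  if (any(n_categories < 2)) stop("every item needs K_i >= 2 categories")
  ms <- missingness_spec
  if (!is.null(ms)) {
    stopifnot(is.data.frame(ms), all(c("fraction", "n_missing") %in% names(ms)))
    if (sum(ms$fraction) > 1 + 1e-9) stop("missingness fractions must sum to <= 1")
    if (any(ms$fraction < 0)) stop("missingness fractions must be non-negative")
    if (any(ms$n_missing < 0) || any(ms$n_missing > 2L * n_items))
      stop("per-family missing count must be between 0 and 2 * n_items")
  }
  structure(list(n_mz = n_mz, n_dz = n_dz, n_items = as.integer(n_items),
                 n_categories = n_categories, missingness_spec = ms),
            class = "cohort_design")
}

#' Biometric hyperparameters of the twin model
#'
#' Collects the variance components of an AE, ACE or ADE decomposition
#' together with the log-linear unique-environment model
#' \eqn{\sigma^2_{Ej} = \exp(\beta_0 + \beta_1 g_j)}, where the moderating
#' genetic value \eqn{g_j} is the additive value \eqn{A_j} (AE/ACE) or the
#' total genetic value \eqn{G_j = A_j + D_j} (ADE).
#'
#' @param model `"AE"`, `"ACE"` or `"ADE"`.
#' @param sigma2_A additive genetic variance (>= 0).
#' @param sigma2_C shared-environment variance (ACE only).
#' @param sigma2_D dominance variance (ADE only).
#' @param beta0 log unique-environmental variance at genetic value 0.
#' @param beta1 interaction slope; 0 means no interaction.
#' @param interaction logical; defaults to `beta1 != 0`. Supplying
#'   `interaction = FALSE` together with a nonzero `beta1` is an error.
#' @return A `genetic_params` object.
#' @export
#' @examples
#' genetic_params("AE", sigma2_A = 0.25, beta0 = log(0.19), beta1 = 2.2)
genetic_params <- function(model = c("AE", "ACE", "ADE"), sigma2_A,
                           sigma2_C = 0, sigma2_D = 0, beta0, beta1 = 0,
                           interaction = NULL) {
  model <- match.arg(model)
  if (is.null(interaction)) interaction <- beta1 != 0
  if (!interaction && beta1 != 0)
    stop("interaction = FALSE requires beta1 = 0")
  if (sigma2_A < 0 || sigma2_C < 0 || sigma2_D < 0)
    stop("variance components must be non-negative")
  if (model != "ACE" && sigma2_C > 0)
    stop(sprintf("invalid model: %s excludes a shared-environment component", model))
  if (model != "ADE" && sigma2_D > 0)
    stop(sprintf("invalid model: %s excludes a dominance component", model))
  if (!is.finite(beta0) || !is.finite(beta1)) stop("beta0/beta1 must be finite")
  structure(list(model = model, interaction = interaction,
                 sigma2_A = sigma2_A, sigma2_C = sigma2_C, sigma2_D = sigma2_D,
                 beta0 = beta0, beta1 = beta1),
            class = "genetic_params")
}

#' @export
print.genetic_params <- function(x, ...) {
  cat(sprintf("<genetic_params> %s%s: sigma2_A=%.3g, sigma2_C=%.3g, sigma2_D=%.3g, beta0=%.3g, beta1=%.3g\n",
              x$model, if (x$interaction) " + GxE" else "",
              x$sigma2_A, x$sigma2_C, x$sigma2_D, x$beta0, x$beta1))
  invisible(x)
}
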
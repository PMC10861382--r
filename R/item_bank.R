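#' Construct an item bank
#'
#' An item bank holds the parameters of a polytomous IRT measurement model:
#' per-item discriminations and category thresholds, for one of the partial
#' credit model (PCM), generalized partial credit model (GPCM) or graded
#' response model (GRM).
#'
#' Thresholds are stored as one vector of length \eqn{K_i} per item whose
#' first element is fixed at 0 by convention (the identification used
#' throughout the package, together with a zero latent-trait mean). For the
#' PCM/GPCM the first threshold cancels from the category probabilities, so
#' the free parameters are elements \eqn{2..K_i}; for the GRM, elements
#' \eqn{2..K_i} are the cumulative-logit cut locations and must be strictly
#' increasing.
#'
#' @param alpha numeric vector of item discriminations (all > 0; PCM fixes
#'   them at 1).
#' @param thresholds list of numeric vectors, one per item; element 1 must
#'   be 0 and the length of each vector is the item's category count
#'   \eqn{K_i \ge 2}.
#' @param model_kind one of `"PCM"`, `"GPCM"`, `"GRM"`.
#' @return An object of class `item_bank` with fields `alpha`, `thresholds`,
#'   `K` (per-item category counts) and `model_kind`.
#' @export
#' @examples
#' bank <- item_bank(alpha = c(1, 1.2),
#'                   thresholds = list(c(0, -0.5, 0.5), c(0, 0, 1)),
#'                   model_kind = "GPCM")
#' gpcm_category_probs(0.3, alpha = 1, thresholds = c(0, -0.5, 0.5))
item_bank <- function(alpha, thresholds, model_kind = c("GPCM", "PCM", "GRM")) {
  model_kind <- match.arg(model_kind)
  if (!is.list(thresholds)) thresholds <- list(thresholds)
  if (length(alpha) != length(thresholds))
    stop("`alpha` and `thresholds` must have one entry per item")
  K <- vapply(thresholds, length, integer(1))
  if (any(K < 2)) stop("every item needs at least 2 categories (K_i >= 2)")
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("discriminations must be finite and non-negative")
  if (model_kind == "PCM" && any(alpha != 1))
    stop("PCM fixes all discriminations at 1")
  for (b in thresholds) {
    if (any(!is.finite(b))) stop("thresholds must be finite")
    if (abs(b[1]) > 1e-12) stop("the first threshold of every item must be 0")
  }
  if (model_kind == "GRM") {
    for (b in thresholds)
      if (length(b) > 2 && any(diff(b[-1]) <= 0))
        stop("GRM thresholds must be strictly increasing")
  }
  structure(list(alpha = as.numeric(alpha), thresholds = lapply(thresholds, as.numeric),
                 K = as.integer(K), model_kind = model_kind),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> %s, %d items, categories: %s\n", x$model_kind,
              length(x$alpha), paste(x$K, collapse = "/")))
  invisible(x)
}

n_items <- function(bank) length(bank$alpha)

#' GPCM category probabilities
#'
#' Response-category probabilities of the (generalized) partial credit model:
#' a softmax over the cumulative sums
#' \eqn{s_k = \sum_{h \le k} \alpha (\theta - b_h)}, so that the log-odds of
#' category \eqn{k} over \eqn{k-1} is \eqn{\alpha(\theta - b_k)}. The first
#' threshold enters every cumulative sum and therefore cancels; it is kept at
#' 0 by convention. A zero discrimination yields the uniform distribution
#' over categories.
#'
#' @param theta latent trait value(s); must be finite.
#' @param alpha item discrimination (scalar, >= 0).
#' @param thresholds numeric vector of length K, first element 0.
#' @return A `length(theta) x K` matrix of probabilities; rows sum to 1.
#' @export
gpcm_category_probs <- function(theta, alpha, thresholds) {
  if (any(!is.finite(theta))) stop("`theta` must be finite")
  K <- length(thresholds)
  if (K < 2) stop("item must have at least 2 categories")
  # s[n, k] = alpha * (k * theta - cumsum(b)[k])
  cb <- cumsum(thresholds)
  s <- alpha * (outer(theta, seq_len(K)) -
                  matrix(cb, nrow = length(theta), ncol = K, byrow = TRUE))
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

#' GRM category probabilities
#'
#' Graded response model probabilities from cumulative logits:
#' \eqn{P(Y \ge k) = \mathrm{logit}^{-1}(\alpha(\theta - b_k))} for
#' \eqn{k = 2..K}, with the category probability the difference of adjacent
#' cumulative probabilities.
#'
#' @inheritParams gpcm_category_probs
#' @return A `length(theta) x K` matrix of probabilities; rows sum to 1.
#' @export
grm_category_probs <- function(theta, alpha, thresholds) {
  if (any(!is.finite(theta))) stop("`theta` must be finite")
  K <- length(thresholds)
  cuts <- thresholds[-1]                     # K - 1 increasing cut locations
  Fge <- cbind(1, stats::plogis(alpha * outer(theta, cuts, "-")), 0)
  p <- Fge[, seq_len(K), drop = FALSE] - Fge[, seq_len(K) + 1L, drop = FALSE]
  pmax(p, 1e-300)
}

category_probs <- function(theta, alpha, thresholds, model_kind) {
  if (model_kind == "GRM") grm_category_probs(theta, alpha, thresholds)
  else gpcm_category_probs(theta, alpha, thresholds)
}

#' Item and test information curves
#'
#' Fisher information of each item at the supplied latent-trait grid,
#' \eqn{I_i(\theta) = \sum_k P'_k(\theta)^2 / P_k(\theta)}. For the
#' PCM/GPCM this equals \eqn{\alpha_i^2} times the variance of the category
#' score at \eqn{\theta}; for the GRM the derivative follows from the
#' cumulative logits. Test information is the sum over items.
#'
#' @param bank an [item_bank] or a fitted measurement model from [fit_irt()].
#' @param theta_grid non-empty numeric grid of latent-trait values.
#' @return A list with `theta` (the grid), `item` (grid x item matrix of
#'   information values) and `total` (their row sums).
#' @export
item_information <- function(bank, theta_grid) {
  if (inherits(bank, "fitted_irt")) bank <- bank$item_bank
  stopifnot(inherits(bank, "item_bank"))
  if (length(theta_grid) == 0) stop("`theta_grid` must be non-empty")
  if (any(!is.finite(theta_grid))) stop("`theta_grid` must be finite")
  I <- n_items(bank)
  info <- matrix(0, length(theta_grid), I)
  for (i in seq_len(I)) {
    a <- bank$alpha[i]; b <- bank$thresholds[[i]]; K <- length(b)
    if (bank$model_kind == "GRM") {
      cuts <- b[-1]
      Fge <- cbind(1, stats::plogis(a * outer(theta_grid, cuts, "-")), 0)
      dF <- cbind(0, a * Fge[, 2:K, drop = FALSE] * (1 - Fge[, 2:K, drop = FALSE]), 0)
      p <- Fge[, 1:K, drop = FALSE] - Fge[, 1:K + 1L, drop = FALSE]
      dp <- dF[, 1:K, drop = FALSE] - dF[, 1:K + 1L, drop = FALSE]
      info[, i] <- rowSums(dp^2 / pmax(p, 1e-300))
    } else {
      p <- gpcm_category_probs(theta_grid, a, b)
      sc <- seq_len(K)
      m1 <- p %*% sc
      m2 <- p %*% sc^2
      info[, i] <- a^2 * as.numeric(m2 - m1^2)
    }
  }
  colnames(info) <- paste0("item_", seq_len(I))
  list(theta = theta_grid, item = info, total = rowSums(info))
}

#' Default synthetic 9-item, 7-category item bank
#'
#' A GPCM item bank emulating a 9-item ADHD symptom subscale scored on a
#' 7-point scale: discriminations near 1 — the first exactly 1 and the
#' geometric mean exactly 1, so the bank sits on either of the package's
#' scale-identification conventions — and category steps spread over the
#' bulk of a latent trait with standard deviation of roughly 0.6-0.8, so
#' that all seven categories are used. This is the generator's default
#' measurement model.
#'
#' @return An [item_bank] with 9 GPCM items of 7 categories each.
#' @export
swan_item_bank <- function() {
  alpha <- c(1.00, 0.80, 1.25, 0.90, 1 / 0.90, 1.10, 1 / 1.10, 1.20, 1 / 1.20)
  shift <- c(0.00, -0.30, 0.20, -0.15, 0.30, 0.10, -0.25, 0.15, -0.05)
  steps <- seq(-0.9, 0.9, length.out = 6)
  thresholds <- lapply(shift, function(s) c(0, steps + s))
  item_bank(alpha, thresholds, "GPCM")
}
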
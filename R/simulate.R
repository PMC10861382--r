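#' Simulate latent twin components
#'
#' Draws per-individual latent components under the biometric model: additive
#' genetic values shared exactly within MZ pairs and correlated 0.5 within DZ
#' pairs (DZ values are built as
#' \eqn{A = \sqrt{\sigma^2_A/2}\,(z_{\mathrm{family}} + z_{\mathrm{twin}})}),
#' dominance values correlated 0.25 within DZ pairs (ADE), a
#' shared-environment value common to a family (ACE), and unique-environment
#' values drawn independently with variance
#' \eqn{\exp(\beta_0 + \beta_1 g_j)} where \eqn{g_j} is the moderating
#' genetic value. The trait is the exact sum
#' \eqn{\theta_j = A_j + C_j + D_j + E_j}; all components are zero-mean.
#'
#' @param params a [genetic_params] object.
#' @param design a [cohort_design] object.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A data frame of class `latent_twin_sample` with one row per
#'   individual and columns `family_id`, `zygosity`, `twin`, `A`, `C`, `D`,
#'   `E`, `theta`.
#' @export
#' @examples
#' p <- genetic_params("AE", sigma2_A = 0.25, beta0 = log(0.19), beta1 = 2.2)
#' lat <- generate_latents(p, cohort_design(50, 80), seed = 1)
#' all.equal(lat$theta, lat$A + lat$C + lat$D + lat$E)
generate_latents <- function(params, design, seed) {
  stopifnot(inherits(params, "genetic_params"), inherits(design, "cohort_design"))
  set.seed(as.integer(seed))
  n_mz <- design$n_mz; n_dz <- design$n_dz
  F <- n_mz + n_dz
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  fam <- rep(seq_len(F), each = 2L)
  sA <- sqrt(params$sigma2_A); sD <- sqrt(params$sigma2_D)

  A <- numeric(2L * F); D <- numeric(2L * F)
  if (n_mz > 0) {
    a_mz <- stats::rnorm(n_mz, 0, sA)
    A[seq_len(2L * n_mz)] <- rep(a_mz, each = 2L)
    if (params$model == "ADE") {
      d_mz <- stats::rnorm(n_mz, 0, sD)
      D[seq_len(2L * n_mz)] <- rep(d_mz, each = 2L)
    }
  }
  if (n_dz > 0) {
    idx <- 2L * n_mz + seq_len(2L * n_dz)
    z_f <- stats::rnorm(n_dz); z_i <- stats::rnorm(2L * n_dz)
    A[idx] <- sqrt(params$sigma2_A / 2) * (rep(z_f, each = 2L) + z_i)
    if (params$model == "ADE") {
      w_f <- stats::rnorm(n_dz); w_i <- stats::rnorm(2L * n_dz)
      # shared weight 1/4 of the variance -> DZ dominance correlation 0.25
      D[idx] <- sqrt(params$sigma2_D / 4) * rep(w_f, each = 2L) +
        sqrt(3 * params$sigma2_D / 4) * w_i
    }
  }
  C <- if (params$model == "ACE")
    rep(stats::rnorm(F, 0, sqrt(params$sigma2_C)), each = 2L) else numeric(2L * F)
  g <- if (params$model == "ADE") A + D else A
  E <- stats::rnorm(2L * F, 0, sqrt(env_variance(params$beta0, params$beta1, g)))

  out <- data.frame(family_id = fam, zygosity = zyg[fam],
                    twin = rep(1:2, F), A = A, C = C, D = D, E = E,
                    theta = A + C + D + E)
  class(out) <- c("latent_twin_sample", "data.frame")
  out
}

new_item_response_table <- function(df, n_categories) {
  attr(df, "n_categories") <- as.integer(n_categories)
  class(df) <- c("item_response_table", "data.frame")
  df
}

item_cols <- function(table) grep("^item_", names(table), value = TRUE)

#' Extract the response matrix of an item-response table
#'
#' @param table an `item_response_table`.
#' @return Integer matrix (individuals x items), `NA` for missing scores.
#' @export
response_matrix <- function(table) {
  as.matrix(table[, item_cols(table), drop = FALSE])
}

#' Simulate item responses from latent traits
#'
#' Draws each individual's response to each item from the measurement
#' model's category distribution evaluated at the individual's latent trait
#' \eqn{\theta_j}. Categories are coded `1..K_i`.
#'
#' @param latents a `latent_twin_sample` from [generate_latents()].
#' @param items an [item_bank]; defaults to [swan_item_bank()].
#' @param seed integer seed; deterministic given the seed.
#' @return An `item_response_table`: data frame with `family_id`, `zygosity`,
#'   `twin` and `item_1..item_I` columns, plus a `n_categories` attribute.
#' @export
generate_item_responses <- function(latents, items = swan_item_bank(), seed) {
  stopifnot(inherits(items, "item_bank"))
  set.seed(as.integer(seed))
  n <- nrow(latents); I <- n_items(items)
  resp <- matrix(NA_integer_, n, I)
  for (i in seq_len(I)) {
    p <- category_probs(latents$theta, items$alpha[i], items$thresholds[[i]],
                        items$model_kind)
    K <- ncol(p)
    cum <- p %*% upper.tri(diag(K), diag = TRUE)   # row-wise cumulative sums
    u <- stats::runif(n)
    resp[, i] <- 1L + rowSums(u > cum[, -K, drop = FALSE])
  }
  colnames(resp) <- paste0("item_", seq_len(I))
  df <- cbind(latents[, c("family_id", "zygosity", "twin")], as.data.frame(resp))
  new_item_response_table(df, items$K)
}

#' Remove item scores completely at random
#'
#' Applies the design's missingness pattern: for each `(fraction, n_missing)`
#' row the nearest whole number of families is selected at random and
#' `n_missing` of the family's `2 * n_items` scores are blanked, uniformly at
#' random (missing completely at random). Families are used at most once.
#'
#' @param table a complete `item_response_table`.
#' @param design a [cohort_design] whose `missingness_spec` is applied.
#' @param seed integer seed.
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(table, design, seed) {
  ms <- design$missingness_spec
  if (is.null(ms) || nrow(ms) == 0) return(table)
  if (anyNA(response_matrix(table))) stop("`table` must be complete")
  set.seed(as.integer(seed))
  fams <- unique(table$family_id)
  F <- length(fams)
  cols <- item_cols(table)
  I <- length(cols)
  if (any(ms$n_missing > 2L * I)) stop("cannot miss more scores than a family has")
  pool <- sample(fams)                       # random order; take blocks per group
  taken <- 0L
  for (r in seq_len(nrow(ms))) {
    m <- ms$n_missing[r]
    cnt <- round(ms$fraction[r] * F)
    if (m == 0L || cnt == 0L) next
    pick <- pool[taken + seq_len(min(cnt, F - taken))]
    taken <- taken + length(pick)
    for (f in pick) {
      rows <- which(table$family_id == f)
      cells <- sample(2L * I, m)             # cell = (twin - 1) * I + item
      for (cell in cells) {
        tw <- (cell - 1L) %/% I + 1L
        it <- (cell - 1L) %% I + 1L
        table[rows[tw], cols[it]] <- NA_integer_
      }
    }
  }
  table
}

#' Simulate a full twin cohort
#'
#' Convenience wrapper running [generate_latents()],
#' [generate_item_responses()] and [inject_missingness()] with seeds derived
#' from one master seed.
#'
#' @inheritParams generate_latents
#' @param items an [item_bank]; defaults to [swan_item_bank()].
#' @return List with `data` (the `item_response_table`) and `truth` (the
#'   `latent_twin_sample`).
#' @export
#' @examples
#' p <- genetic_params("AE", sigma2_A = 0.25, beta0 = log(0.19), beta1 = 2.2)
#' sim <- simulate_twin_cohort(p, cohort_design(20, 30), seed = 7)
#' dim(sim$data)
simulate_twin_cohort <- function(params, design, items = swan_item_bank(), seed) {
  seed <- as.integer(seed)
  truth <- generate_latents(params, design, seed = seed)
  tab <- generate_item_responses(truth, items, seed = seed + 1L)
  tab <- inject_missingness(tab, design, seed = seed + 2L)
  list(data = tab, truth = truth)
}
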
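# Gauss-Hermite quadrature adapted to a standard-normal latent density:
# Golub-Welsch nodes/weights for physicists' Hermite, rescaled so that
# sum(w) = 1 and sum(w * x^2) = 1.
gauss_hermite_normal <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = sqrt(2) * e$values[ord],
       weights = e$vectors[1, ord]^2)
}

irt_pack <- function(bank, kind) {
  lapply(seq_along(bank$alpha), function(i) {
    b <- bank$thresholds[[i]]
    switch(kind,
      PCM = b[-1],
      GPCM = c(log(bank$alpha[i]), b[-1]),
      GRM = c(log(bank$alpha[i]), b[2],
              if (length(b) > 2) log(diff(b[-1]))))
  })
}

irt_unpack <- function(par, K, kind) {
  switch(kind,
    PCM = list(alpha = 1, thresholds = c(0, par)),
    GPCM = list(alpha = exp(par[1]), thresholds = c(0, par[-1])),
    GRM = list(alpha = exp(par[1]),
               thresholds = c(0, par[2] + cumsum(c(0, exp(par[-(1:2)]))))))
}

# K x Q matrix of category log-probabilities at the quadrature nodes
item_logprob_matrix <- function(alpha, thresholds, kind, nodes) {
  p <- category_probs(nodes, alpha, thresholds, if (kind == "GRM") "GRM" else "GPCM")
  t(log(pmax(p, 1e-300)))
}

#' Marginal log-likelihood of an item bank
#'
#' Evaluates the marginal maximum likelihood objective: the log-likelihood
#' of the observed responses with the latent trait integrated out against a
#' standard-normal density by fixed Gauss-Hermite quadrature. Missing
#' responses are skipped (full-information likelihood).
#'
#' @param y integer response matrix (persons x items), `NA` allowed.
#' @param bank an [item_bank].
#' @param n_quad number of quadrature nodes.
#' @return Total log-likelihood (scalar).
#' @export
irt_marginal_loglik <- function(y, bank, n_quad = 61) {
  gh <- gauss_hermite_normal(n_quad)
  lp <- person_logpost(y, bank, gh)
  sum(lp$loglik_person)
}

# per-person log L_j and (unnormalized log) posterior over nodes
person_logpost <- function(y, bank, gh) {
  n <- nrow(y); Q <- length(gh$nodes)
  lp <- matrix(rep(log(gh$weights), each = n), n, Q)
  for (i in seq_len(ncol(y))) {
    lpi <- item_logprob_matrix(bank$alpha[i], bank$thresholds[[i]],
                               bank$model_kind, gh$nodes)
    obs <- !is.na(y[, i])
    lp[obs, ] <- lp[obs, ] + lpi[y[obs, i], , drop = FALSE]
  }
  mx <- apply(lp, 1, max)
  ll <- mx + log(rowSums(exp(lp - mx)))
  list(logpost = lp, loglik_person = ll)
}

collapse_categories <- function(y, K) {
  log <- list()
  for (i in seq_len(ncol(y))) {
    seen <- sort(unique(y[!is.na(y[, i]), i]))
    if (length(seen) < K[i]) {
      map <- match(y[, i], seen)
      y[, i] <- map
      log[[length(log) + 1L]] <- list(item = i, observed = seen,
                                      K_new = length(seen))
      K[i] <- length(seen)
    }
  }
  list(y = y, K = K, log = log)
}

#' Fit a polytomous IRT model by marginal maximum likelihood
#'
#' EM estimation of the PCM, GPCM or GRM with a standard-normal latent
#' trait integrated by fixed Gauss-Hermite quadrature. To avoid the
#' within-family dependence of twin data, one twin per family is selected
#' at random (seeded) before fitting; missing responses are skipped in the
#' likelihood. Item categories never observed in the data are collapsed
#' into their neighbour (with a record in the result) so that every
#' remaining category has data support. The M-step maximizes each item's
#' expected complete-data log-likelihood by BFGS, so the marginal
#' log-likelihood is non-decreasing over EM iterations.
#'
#' @param table an `item_response_table`, or a plain integer matrix of
#'   responses (persons x items; then no twin selection is applied).
#' @param kind `"PCM"`, `"GPCM"` or `"GRM"`.
#' @param n_quad Gauss-Hermite nodes (default 61).
#' @param max_iter,tol EM stopping rule (log-likelihood change).
#' @param one_per_family select one random twin per family? (only for
#'   `item_response_table` input)
#' @param select_seed seed for the twin selection.
#' @return A `fitted_irt`: `item_bank`, `loglik`, `n_parameters`, `AIC`
#'   (\eqn{-2\ell + 2p}), `loglik_path`, `converged`, `collapsed`,
#'   `selected_rows`.
#' @export
#' @examples
#' p <- genetic_params("AE", sigma2_A = 0.25, beta0 = log(0.19), beta1 = 0,
#'                     interaction = FALSE)
#' sim <- simulate_twin_cohort(p, cohort_design(100, 100,
#'   missingness_spec = NULL), seed = 3)
#' fit <- fit_irt(sim$data, "GPCM", max_iter = 25)
#' fit$AIC
fit_irt <- function(table, kind = c("GPCM", "PCM", "GRM"), n_quad = 61,
                    max_iter = 200, tol = 1e-6, one_per_family = TRUE,
                    select_seed = 1) {
  kind <- match.arg(kind)
  selected <- NULL
  if (inherits(table, "item_response_table") || is.data.frame(table)) {
    K <- attr(table, "n_categories")
    if (one_per_family) {
      set.seed(as.integer(select_seed))
      fams <- split(seq_len(nrow(table)), table$family_id)
      selected <- sort(vapply(fams, function(r) r[sample.int(length(r), 1)],
                              integer(1)))
      table <- table[selected, ]
    }
    y <- response_matrix(table)
  } else {
    y <- table
    K <- apply(y, 2, max, na.rm = TRUE)
  }
  if (is.null(K)) K <- apply(y, 2, max, na.rm = TRUE)
  K <- as.integer(K)
  if (any(K < 2)) stop("every item needs K_i >= 2 categories")
  cc <- collapse_categories(y, K)
  y <- cc$y; K <- cc$K
  I <- ncol(y)

  gh <- gauss_hermite_normal(n_quad)
  Q <- n_quad
  bank <- item_bank(alpha = rep(1, I),
                    thresholds = lapply(K, function(k)
                      c(0, seq(-1.5, 1.5, length.out = k - 1))),
                    model_kind = if (kind == "GRM") "GRM" else "PCM")
  bank$model_kind <- if (kind == "GRM") "GRM" else "GPCM"  # probs dispatch
  if (kind != "PCM") bank$alpha <- rep(1, I)

  path <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (em in seq_len(max_iter)) {
    pp <- person_logpost(y, bank, gh)
    ll <- sum(pp$loglik_person)
    path <- c(path, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    post <- exp(pp$logpost - pp$loglik_person)          # n x Q, rows sum to 1
    pars <- irt_pack(bank, kind)
    for (i in seq_len(I)) {
      obs <- !is.na(y[, i])
      # expected counts r[k, q] of category k at node q
      r <- rowsum(post[obs, , drop = FALSE], group = y[obs, i])
      kk <- as.integer(rownames(r))
      R <- matrix(0, K[i], Q); R[kk, ] <- r
      negE <- function(par) {
        u <- irt_unpack(par, K[i], kind)
        if (kind == "GRM" && any(diff(u$thresholds[-1]) <= 0)) return(1e10)
        lpi <- item_logprob_matrix(u$alpha, u$thresholds, kind, gh$nodes)
        -sum(R * lpi)
      }
      opt <- stats::optim(pars[[i]], negE, method = "BFGS",
                          control = list(maxit = 100, reltol = 1e-10))
      u <- irt_unpack(opt$par, K[i], kind)
      bank$alpha[i] <- u$alpha
      bank$thresholds[[i]] <- u$thresholds
    }
  }

  n_par <- as.integer(sum(K - 1L) + if (kind == "PCM") 0L else I)
  if (kind == "PCM") bank$model_kind <- "PCM"
  out <- list(item_bank = bank, loglik = ll, n_parameters = n_par,
              AIC = -2 * ll + 2 * n_par, loglik_path = path,
              converged = converged, n_iter = length(path),
              collapsed = cc$log, selected_rows = selected, kind = kind)
  class(out) <- "fitted_irt"
  out
}

#' @export
print.fitted_irt <- function(x, ...) {
  cat(sprintf("<fitted_irt> %s: loglik %.2f, %d parameters, AIC %.2f%s\n",
              x$kind, x$loglik, x$n_parameters, x$AIC,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Classical scale statistics
#'
#' Sum scores, Cronbach's alpha, item-rest correlations and MZ/DZ twin
#' sum-score correlations. Sum scores and alpha use complete responders
#' only; the twin correlations use pairs in which both twins are complete.
#' Cronbach's alpha is \eqn{\frac{I}{I-1}\left(1 - \sum_i
#' \mathrm{var}_i / \mathrm{var}_{\mathrm{total}}\right)}; the item-rest
#' correlation of item \eqn{i} is its correlation with the sum of the
#' remaining items. A zero-variance item yields an `NA` item-rest
#' correlation with a warning.
#'
#' @param table an `item_response_table`.
#' @return List with `sum_scores` (per complete individual), `alpha`,
#'   `item_rest`, `mz_cor`, `dz_cor`, `n_complete`.
#' @export
classical_stats <- function(table) {
  y <- response_matrix(table)
  if (ncol(y) < 2) stop("need at least two items")
  complete <- stats::complete.cases(y)
  yc <- y[complete, , drop = FALSE]
  I <- ncol(yc)
  tot <- rowSums(yc)
  item_var <- apply(yc, 2, stats::var)
  alpha <- (I / (I - 1)) * (1 - sum(item_var) / stats::var(tot))
  item_rest <- rep(NA_real_, I)
  for (i in seq_len(I)) {
    if (item_var[i] == 0) {
      warning(sprintf("item %d has zero variance; item-rest undefined", i))
      next
    }
    item_rest[i] <- stats::cor(yc[, i], tot - yc[, i])
  }
  ss <- data.frame(family_id = table$family_id[complete],
                   zygosity = table$zygosity[complete],
                   twin = table$twin[complete], sum_score = tot)
  pair_cor <- function(zyg) {
    s <- ss[ss$zygosity == zyg, ]
    w <- merge(s[s$twin == 1, c("family_id", "sum_score")],
               s[s$twin == 2, c("family_id", "sum_score")], by = "family_id")
    if (nrow(w) < 3) return(NA_real_)
    stats::cor(w$sum_score.x, w$sum_score.y)
  }
  list(sum_scores = ss, alpha = alpha,
       item_rest = item_rest,
       mz_cor = pair_cor("MZ"), dz_cor = pair_cor("DZ"),
       n_complete = sum(complete))
}
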
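#' Read twin item-response data from CSV
#'
#' Expected dialect: UTF-8, comma-separated, header row, columns
#' `family_id`, `zygosity` (MZ/DZ), `twin` (1/2) and `item_1..item_I`
#' holding integer categories (`1..K_i`), with an empty field for a missing
#' score. Families in which both twins are missing every item score are
#' excluded, with a message giving the count.
#'
#' @param path CSV file path.
#' @param n_categories per-item category counts; inferred from the data
#'   maximum when omitted.
#' @return An `item_response_table`.
#' @export
read_twin_csv <- function(path, n_categories = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("family_id", "zygosity", "twin")
  if (!all(need %in% names(df)))
    stop("missing required columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  items <- grep("^item_", names(df), value = TRUE)
  if (length(items) == 0) stop("no item_* columns found")
  bad <- !df$zygosity %in% c("MZ", "DZ")
  if (any(bad))
    stop("unknown zygosity code in rows: ", paste(which(bad), collapse = ", "))
  key <- paste(df$family_id, df$twin)
  if (anyDuplicated(key))
    stop("duplicated family/twin keys in rows: ",
         paste(which(duplicated(key)), collapse = ", "))
  y <- as.matrix(df[, items, drop = FALSE])
  storage.mode(y) <- "integer"
  K <- if (is.null(n_categories)) apply(y, 2, max, na.rm = TRUE)
       else rep_len(as.integer(n_categories), length(items))
  for (i in seq_along(items)) {
    v <- y[, i]
    out_of_range <- which(!is.na(v) & (v < 1 | v > K[i]))
    if (length(out_of_range))
      stop(sprintf("item_%d: category out of range [1, %d] in rows: %s",
                   i, K[i], paste(out_of_range, collapse = ", ")))
  }
  df[, items] <- y
  # drop families where every score of both twins is missing
  all_miss <- tapply(rowSums(!is.na(y)), df$family_id, sum) == 0
  if (any(all_miss)) {
    drop_f <- names(all_miss)[all_miss]
    message(sprintf("excluded %d famil%s with missing data on all items",
                    length(drop_f), if (length(drop_f) == 1) "y" else "ies"))
    df <- df[!df$family_id %in% drop_f, ]
    rownames(df) <- NULL
  }
  new_item_response_table(df, K)
}

#' Write twin item-response data to CSV
#'
#' Inverse of [read_twin_csv()]: missing scores become empty fields.
#'
#' @param table an `item_response_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_twin_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

parse_model_label <- function(label, priors = prior_spec()) {
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  model_spec(parts[1], interaction = length(parts) > 1, priors = priors)
}

#' Assemble a pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; every stage derives its seed from it.
#' @param simulate `NULL`, or a list with `model`, `sigma2_A`, `sigma2_C`,
#'   `sigma2_D`, `beta0`, `beta1`, `n_mz`, `n_dz` describing a cohort to
#'   simulate with [swan_item_bank()] items.
#' @param input_csv path of an existing data CSV (alternative to
#'   `simulate`).
#' @param irt_kinds measurement models to fit and compare by AIC (possibly
#'   empty).
#' @param models genetic models to fit, as labels like `"AE"`, `"AE+AxE"`,
#'   `"ACE+AxE"`.
#' @param sampler list with `n_chains`, `burn_in`, `iterations`.
#' @return A `pipeline_config` list, serializable losslessly to JSON via
#'   [save_config()] / [load_config()].
#' @export
pipeline_config <- function(out_dir, seed, simulate = NULL, input_csv = NULL,
                            irt_kinds = character(0),
                            models = c("AE", "AE+AxE"),
                            sampler = list(n_chains = 2, burn_in = 1000,
                                           iterations = 1000)) {
  if (is.null(simulate) && is.null(input_csv))
    stop("supply either `simulate` or `input_csv`")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, input_csv = input_csv,
                 irt_kinds = irt_kinds, models = models, sampler = sampler),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or read) the twin data; fit the requested
#' measurement models by marginal ML and compare them by AIC; fit each
#' requested genetic model jointly with the GPCM by MCMC; compare the fits
#' by DIC; and write report tables (posterior summaries, the interaction
#' credibility curve, sum scores). All outputs land in `config$out_dir`
#' together with a JSON manifest recording seeds, package version and the
#' MD5 checksum of every artifact; rerunning the same configuration
#' reproduces identical checksums.
#'
#' @param config a [pipeline_config].
#' @return List with `status` (0 on success) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(...) file.path(config$out_dir, ...)
  artifacts <- character(0)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("twinace")),
                   stages = list())

  # stage 1: data
  if (!is.null(config$simulate)) {
    sm <- config$simulate
    params <- genetic_params(sm$model,
                             sigma2_A = sm$sigma2_A,
                             sigma2_C = if (is.null(sm$sigma2_C)) 0 else sm$sigma2_C,
                             sigma2_D = if (is.null(sm$sigma2_D)) 0 else sm$sigma2_D,
                             beta0 = sm$beta0,
                             beta1 = if (is.null(sm$beta1)) 0 else sm$beta1)
    design <- cohort_design(sm$n_mz, sm$n_dz)
    sim <- simulate_twin_cohort(params, design, seed = config$seed)
    write_twin_csv(sim$data, outp("data.csv"))
    utils::write.csv(sim$truth, outp("truth.csv"), row.names = FALSE)
    artifacts <- c(artifacts, outp("data.csv"), outp("truth.csv"))
    data <- sim$data
    manifest$stages$simulate <- list(seed = config$seed,
                                     n_mz = sm$n_mz, n_dz = sm$n_dz)
  } else {
    data <- read_twin_csv(config$input_csv)
    manifest$stages$input <- list(path = config$input_csv)
  }

  # stage 2: measurement-model comparison by AIC
  if (length(config$irt_kinds)) {
    irt_fits <- lapply(config$irt_kinds, function(k)
      fit_irt(data, k, select_seed = config$seed))
    names(irt_fits) <- config$irt_kinds
    aic <- data.frame(kind = config$irt_kinds,
                      loglik = vapply(irt_fits, `[[`, numeric(1), "loglik"),
                      AIC = vapply(irt_fits, `[[`, numeric(1), "AIC"))
    utils::write.csv(aic, outp("irt_aic.csv"), row.names = FALSE)
    best <- irt_fits[[which.min(aic$AIC)]]
    jsonlite::write_json(
      list(kind = best$kind, loglik = best$loglik, AIC = best$AIC,
           alpha = best$item_bank$alpha, thresholds = best$item_bank$thresholds),
      outp("irt_fit.json"), auto_unbox = TRUE, digits = NA)
    grid <- seq(-3, 3, by = 0.1)
    info <- item_information(best, grid)
    utils::write.csv(data.frame(theta = grid, info$item, total = info$total),
                     outp("information.csv"), row.names = FALSE)
    artifacts <- c(artifacts, outp("irt_aic.csv"), outp("irt_fit.json"),
                   outp("information.csv"))
    manifest$stages$irt <- list(best = best$kind, seed = config$seed)
  }

  # stage 3: joint genetic-model fits
  fits <- list()
  for (m in config$models) {
    spec <- parse_model_label(m)
    fit <- run_chains(data, spec,
                      n_chains = config$sampler$n_chains,
                      burn_in = config$sampler$burn_in,
                      iterations = config$sampler$iterations,
                      seed = config$seed)
    fits[[m]] <- fit
    long <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
      d <- fit$draws[[ch]]
      hp <- hyper_names(spec)
      data.frame(chain = ch, iteration = seq_len(nrow(d)),
                 d[, hp, drop = FALSE], check.names = FALSE)
    }))
    utils::write.csv(long, outp(paste0("draws_", gsub("\\+", "_", m), ".csv")),
                     row.names = FALSE)
    utils::write.csv(summarize_fit(fit),
                     outp(paste0("summary_", gsub("\\+", "_", m), ".csv")),
                     row.names = FALSE)
    artifacts <- c(artifacts, outp(paste0("draws_", gsub("\\+", "_", m), ".csv")),
                   outp(paste0("summary_", gsub("\\+", "_", m), ".csv")))
  }
  manifest$stages$fit <- list(models = config$models, seed = config$seed,
                              converged = vapply(fits, `[[`, NA, "converged"))

  # stage 4: model comparison
  if (length(fits) >= 1) {
    tab <- model_selection_table(fits)
    utils::write.csv(tab, outp("dic_table.csv"), row.names = FALSE)
    artifacts <- c(artifacts, outp("dic_table.csv"))
    manifest$stages$compare <- list(preferred = tab$model[tab$preferred][1])

    # stage 5: report on the preferred model
    best_fit <- fits[[which.min(vapply(fits, function(f) f$dic$DIC, numeric(1)))]]
    curve <- credibility_curve(best_fit)
    utils::write.csv(curve, outp("credibility_curve.csv"), row.names = FALSE)
    cs <- classical_stats(data)
    utils::write.csv(cs$sum_scores, outp("sum_scores.csv"), row.names = FALSE)
    artifacts <- c(artifacts, outp("credibility_curve.csv"), outp("sum_scores.csv"))
    manifest$stages$report <- list(alpha = cs$alpha,
                                   mz_cor = cs$mz_cor, dz_cor = cs$dz_cor)
  }

  manifest$artifacts <- lapply(artifacts, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(status = 0L, manifest = manifest)
}
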
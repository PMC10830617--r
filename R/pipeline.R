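# Orchestration: decompose every group x scale cell, build attentiveness
# weights, run adjusted and unadjusted IRT analyses, validity checks, and a
# summary report. All randomness descends deterministically from one root
# seed, split per group x scale.

#' Decompose screen times for every group x scale cell
#'
#' Applies the log transform, fits BIC-selected weighted Gaussian mixtures
#' per group x scale (sampling weights as case weights), labels the C/IER
#' component, and returns attentiveness weights per respondent x scale. Rows
#' with a missing screen time are not decomposed: they keep weight 1 and are
#' flagged \code{not_assessed}.
#'
#' @param records screen-record data.frame (see
#'   \code{\link{read_screen_records}}).
#' @param transform \code{"per_item"} (log geometric mean time per item, the
#'   default) or \code{"total"} (plain log screen time).
#' @param max_components largest mixture size tried per cell.
#' @param seed root seed; each cell uses a seed derived from it and the
#'   cell's identifiers.
#' @return list of class \code{cier_decomposition_set}: \code{weights}
#'   (data.frame \code{respondent_id, group_id, scale_id, posterior_cier,
#'   attentiveness_weight, not_assessed}), \code{summary} (one row per
#'   cell), \code{fits} (per cell: \code{fit}, labelling results).
#' @export
decompose_screen_times <- function(records, transform = c("per_item", "total"),
                                   max_components = 9L, seed = 1L) {
  transform <- match.arg(transform)
  need <- setdiff(screen_record_columns, names(records))
  if (length(need)) {
    aw_stop(paste0("records missing column(s): ",
                   paste(need, collapse = ", ")),
            "attweights_error_schema")
  }
  cells <- unique(records[c("group_id", "scale_id")])
  cells <- cells[order(cells$group_id, cells$scale_id), , drop = FALSE]
  fits <- vector("list", nrow(cells))
  weights_out <- vector("list", nrow(cells))
  summ <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    g <- cells$group_id[i]
    s <- cells$scale_id[i]
    rows <- records[records$group_id == g & records$scale_id == s, ]
    assessed <- !is.na(rows$time_seconds)
    x <- if (transform == "per_item") {
      log_geometric_time(rows$time_seconds[assessed], rows$n_items[assessed])
    } else {
      log(rows$time_seconds[assessed])
    }
    w <- rows$sampling_weight[assessed]
    cell_seed <- derive_seed(seed, paste0(g, "|", s))
    fit <- withCallingHandlers(
      select_components(x, w, max_components = max_components,
                        seed = cell_seed),
      warning = function(cond) {
        message(sprintf("[%s x %s] %s", g, s, conditionMessage(cond)))
        invokeRestart("muffleWarning")
      }
    )
    lab <- label_cier(fit, x, w)
    post <- rep(0, nrow(rows))
    post[assessed] <- lab$posteriors
    weights_out[[i]] <- data.frame(
      respondent_id = rows$respondent_id,
      group_id = g, scale_id = s,
      posterior_cier = post,
      attentiveness_weight = 1 - post,
      not_assessed = as.integer(!assessed),
      stringsAsFactors = FALSE
    )
    fits[[i]] <- list(group_id = g, scale_id = s, fit = fit,
                      cier_component = lab$cier_component,
                      cier_proportion = lab$cier_proportion,
                      posterior_mean_cier = lab$posterior_mean_cier,
                      mean_cier_time_per_item = lab$mean_cier_time_per_item)
    summ[[i]] <- data.frame(
      group_id = g, scale_id = s,
      n = sum(assessed),
      n_components = fit$n_components,
      cier_proportion = lab$cier_proportion,
      posterior_mean_cier = lab$posterior_mean_cier,
      mean_cier_time_per_item = if (is.na(lab$cier_component)) NA_real_
                                else lab$mean_cier_time_per_item,
      bic = fit$bic,
      converged = fit$converged,
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    weights = do.call(rbind, weights_out),
    summary = do.call(rbind, summ),
    fits = fits
  ), class = "cier_decomposition_set")
}

#' @export
print.cier_decomposition_set <- function(x, ...) {
  cat(sprintf("Screen-time decomposition: %d group x scale cells\n",
              nrow(x$summary)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Run configuration for the full pipeline
#'
#' @param out_dir output directory.
#' @param transform,max_components,seed passed to
#'   \code{\link{decompose_screen_times}}.
#' @param thresholds fixed per-item time thresholds in seconds for the
#'   indicator comparison (default 2 s and 1 s).
#' @param nt_fraction normative-threshold fraction (default 0.30).
#' @param n_quadrature quadrature nodes for the GPCM fits.
#' @param beta_method estimation mode for the Beta regression stage.
#' @param max_lag largest lag for the rank-order consistency table.
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(out_dir = tempfile("attweights_run"),
                       transform = "per_item", max_components = 9L,
                       thresholds = c(2, 1), nt_fraction = 0.30,
                       n_quadrature = 61L, beta_method = "ml",
                       max_lag = 15L, seed = 1L) {
  if (max_components < 1L || n_quadrature < 21L || nt_fraction <= 0 ||
      any(thresholds <= 0)) {
    aw_stop("invalid run_config values", "attweights_error_config")
  }
  structure(list(out_dir = out_dir, transform = transform,
                 max_components = as.integer(max_components),
                 thresholds = thresholds, nt_fraction = nt_fraction,
                 n_quadrature = as.integer(n_quadrature),
                 beta_method = beta_method, max_lag = as.integer(max_lag),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full screen-time weighting pipeline
#'
#' decompose -> weights -> adjusted and unadjusted multi-group GPCM per
#' scale -> validity checks -> report. All declared outputs are written
#' under \code{config$out_dir}: \code{weights.csv},
#' \code{decomposition.json}, \code{comparison.csv},
#' \code{validity_checks.csv}, \code{lag_table.csv} and
#' \code{report.json}.
#'
#' @param records screen-record data.frame or CSV path.
#' @param responses named list (by scale_id) of lists with \code{responses}
#'   matrix and \code{group} vector, or a named character vector of wide
#'   CSV paths.
#' @param config a \code{\link{run_config}}.
#' @param scale_covariates optional data.frame
#'   (\code{scale_id, screen_position, n_items, n_options, avg_length})
#'   enabling the Beta regression stage.
#' @return list of class \code{pipeline_result} with \code{decomposition},
#'   \code{gpcm} (per scale: adjusted, unadjusted, comparison),
#'   \code{validity}, \code{lag_table}, \code{beta_fit} (or NULL),
#'   \code{report}, \code{paths}.
#' @export
run_pipeline <- function(records, responses = NULL,
                         config = run_config(), scale_covariates = NULL) {
  if (is.character(records)) records <- read_screen_records(records)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  dec <- decompose_screen_times(records, transform = config$transform,
                                max_components = config$max_components,
                                seed = config$seed)
  paths <- list(weights = file.path(config$out_dir, "weights.csv"),
                decomposition = file.path(config$out_dir, "decomposition.json"),
                report = file.path(config$out_dir, "report.json"))
  write_weights_csv(dec$weights, paths$weights)
  write_decomposition_json(dec, paths$decomposition)

  ## per-scale IRT analyses
  gpcm_results <- list()
  if (!is.null(responses)) {
    if (is.character(responses)) {
      responses <- lapply(responses, read_responses)
    }
    for (s in names(responses)) {
      rs <- responses[[s]]
      w_rows <- dec$weights[dec$weights$scale_id == s, ]
      att <- w_rows$attentiveness_weight[
        match(rownames(rs$responses) %||% seq_len(nrow(rs$responses)),
              w_rows$respondent_id)]
      att[is.na(att)] <- 1
      rec_rows <- records[records$scale_id == s, ]
      v <- rec_rows$sampling_weight[
        match(rownames(rs$responses), rec_rows$respondent_id)]
      v[is.na(v)] <- 1
      unadj <- fit_multigroup_gpcm(rs$responses, rs$group, weights = v,
                                   n_quadrature = config$n_quadrature)
      adj <- fit_multigroup_gpcm(rs$responses, rs$group, weights = v * att,
                                 n_quadrature = config$n_quadrature)
      gpcm_results[[s]] <- list(adjusted = adj, unadjusted = unadj,
                                comparison = compare_fits(adj, unadj))
      if (!adj$converged || !unadj$converged) {
        warning(sprintf("GPCM for scale %s did not converge", s),
                call. = FALSE)
      }
    }
    comp_tab <- do.call(rbind, lapply(names(gpcm_results), function(s) {
      tab <- gpcm_results[[s]]$comparison$table
      cbind(scale_id = s, tab)
    }))
    paths$comparison <- file.path(config$out_dir, "comparison.csv")
    utils::write.csv(comp_tab, paths$comparison, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }

  ## validity checks: tidy per group x scale statistics
  validity <- pipeline_validity_checks(records, responses, dec, config)
  paths$validity <- file.path(config$out_dir, "validity_checks.csv")
  utils::write.csv(validity$tidy, paths$validity, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  paths$lag_table <- file.path(config$out_dir, "lag_table.csv")
  utils::write.csv(validity$lag_table, paths$lag_table, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")

  ## Beta regression of cell proportions on scale characteristics
  beta_fit <- NULL
  if (!is.null(scale_covariates)) {
    d <- merge(dec$summary, scale_covariates, by = "scale_id")
    covars <- as.matrix(d[c("screen_position", "n_items", "n_options",
                            "avg_length")])
    beta_fit <- fit_hierarchical_beta(
      adjust_proportions(d$cier_proportion, nrow(d)),
      group = as.integer(factor(d$group_id)), covariates = covars,
      method = config$beta_method, seed = derive_seed(config$seed, "betareg")
    )
  }

  report <- list(
    n_cells = nrow(dec$summary),
    grand_mean_cier_proportion = mean(dec$summary$cier_proportion),
    mean_cier_time_per_item =
      mean(dec$summary$mean_cier_time_per_item, na.rm = TRUE),
    cells = dec$summary,
    comparison = lapply(gpcm_results, function(r) list(
      median_abs_diff_mean = r$comparison$median_abs_diff_mean,
      mid50_abs_diff_mean = r$comparison$mid50_abs_diff_mean,
      median_abs_diff_var = r$comparison$median_abs_diff_var,
      mid50_abs_diff_var = r$comparison$mid50_abs_diff_var
    )),
    beta_coefficients = if (!is.null(beta_fit)) beta_fit$coefficients,
    seed = config$seed
  )
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  structure(list(decomposition = dec, gpcm = gpcm_results,
                 validity = validity$tidy, lag_table = validity$lag_table,
                 beta_fit = beta_fit, report = report, paths = paths),
            class = "pipeline_result")
}

# tidy validity-check statistics for the report
pipeline_validity_checks <- function(records, responses, dec, config) {
  rows <- list()
  assessed <- !is.na(records$time_seconds)
  rec <- records[assessed, ]
  wkey <- paste(dec$weights$respondent_id, dec$weights$scale_id)
  post <- dec$weights$posterior_cier[
    match(paste(rec$respondent_id, rec$scale_id), wkey)]
  ind2 <- fixed_threshold_indicator(rec$time_seconds, rec$n_items,
                                    config$thresholds[1])
  ind1 <- fixed_threshold_indicator(rec$time_seconds, rec$n_items,
                                    config$thresholds[min(2, length(config$thresholds))])
  for (g in sort(unique(rec$group_id))) {
    for (s in sort(unique(rec$scale_id))) {
      sel <- rec$group_id == g & rec$scale_id == s
      if (!any(sel)) next
      nt <- nt30_indicator(rec$time_seconds[sel], rec$n_items[sel],
                           rep(g, sum(sel)), fraction = config$nt_fraction)
      stats_here <- list(
        pb_fixed_2s = point_biserial(ind2[sel], post[sel]),
        pb_fixed_1s = point_biserial(ind1[sel], post[sel]),
        pb_nt30 = point_biserial(nt, post[sel]),
        prop_fixed_2s = mean(ind2[sel]),
        prop_fixed_1s = mean(ind1[sel]),
        prop_nt30 = mean(nt)
      )
      if (!is.null(responses) && s %in% names(responses)) {
        Y <- responses[[s]]$responses
        ids <- rownames(Y)
        m <- match(rec$respondent_id[sel], ids)
        om <- omission_counts(Y)[m]
        stats_here$cor_omissions <- weighted_correlation(
          post[sel], om, rec$sampling_weight[sel])
      }
      for (nm in names(stats_here)) {
        rows[[length(rows) + 1L]] <- data.frame(
          group_id = g, scale_id = s, statistic = nm,
          value = as.numeric(stats_here[[nm]]), n = sum(sel),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  ## lag table per group over scale positions (scales sorted by id)
  lag_rows <- list()
  scales <- sort(unique(rec$scale_id))
  if (length(scales) >= 2L) {
    for (g in sort(unique(rec$group_id))) {
      ids <- sort(unique(rec$respondent_id[rec$group_id == g]))
      pm <- matrix(NA_real_, length(ids), length(scales),
                   dimnames = list(ids, scales))
      sel_g <- rec$group_id == g
      pm[cbind(match(rec$respondent_id[sel_g], ids),
               match(rec$scale_id[sel_g], scales))] <- post[sel_g]
      lt <- lagged_consistency(pm, max_lag = config$max_lag)
      lag_rows[[g]] <- cbind(group_id = g, lt)
    }
  }
  list(tidy = do.call(rbind, rows),
       lag_table = if (length(lag_rows)) do.call(rbind, lag_rows) else
         data.frame(group_id = character(0), lag = integer(0),
                    mean_correlation = numeric(0)))
}
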
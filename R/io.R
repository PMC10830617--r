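# CSV contracts (UTF-8, "." decimal, empty cell = missing) and JSON writers.

screen_record_columns <- c("respondent_id", "group_id", "scale_id",
                           "time_seconds", "n_items", "sampling_weight")

#' Read screen-time records
#'
#' Reads the long-format screen record contract: one row per respondent x
#' scale with columns \code{respondent_id, group_id, scale_id,
#' time_seconds, n_items, sampling_weight}. A missing column is a schema
#' error; rows failing validation (non-positive time, items < 1,
#' non-positive weight) are dropped and reported, with their line numbers,
#' in the \code{row_errors} attribute and a warning. A missing (empty)
#' \code{time_seconds} is allowed — such rows are kept and later flagged
#' "not assessed" by the decomposition instead of being down-weighted.
#'
#' @param path CSV file path.
#' @return validated data.frame of screen records; attribute
#'   \code{row_errors} lists rejected lines.
#' @export
read_screen_records <- function(path) {
  if (!file.exists(path)) {
    aw_stop(paste0("file not found: ", path), "attweights_error_schema")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(screen_record_columns, names(df))
  if (length(missing_cols)) {
    aw_stop(paste0("missing required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "attweights_error_schema")
  }
  df <- df[screen_record_columns]
  df$time_seconds <- suppressWarnings(as.numeric(df$time_seconds))
  df$n_items <- suppressWarnings(as.integer(df$n_items))
  df$sampling_weight <- suppressWarnings(as.numeric(df$sampling_weight))

  reasons <- character(nrow(df))
  bad_time <- !is.na(df$time_seconds) & df$time_seconds <= 0
  reasons[bad_time] <- "non-positive time_seconds"
  bad_items <- is.na(df$n_items) | df$n_items < 1L
  reasons[bad_items] <- "invalid n_items"
  bad_w <- is.na(df$sampling_weight) | df$sampling_weight <= 0
  reasons[bad_w] <- "invalid sampling_weight"
  bad <- reasons != ""
  row_errors <- data.frame(line = which(bad) + 1L,  # +1 for the header line
                           reason = reasons[bad],
                           stringsAsFactors = FALSE)
  if (nrow(row_errors)) {
    warning(sprintf("%d row(s) rejected: lines %s", nrow(row_errors),
                    paste(row_errors$line, collapse = ", ")),
            call. = FALSE)
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "row_errors") <- row_errors
  out
}

#' Read wide-format item responses for one scale
#'
#' Contract: \code{respondent_id, group_id, item_1..item_J}; empty cells are
#' omissions.
#'
#' @param path CSV file path.
#' @return list with \code{responses} (integer matrix, \code{NA} missing),
#'   \code{group} (integer index from the sorted unique \code{group_id}),
#'   \code{group_id}, \code{respondent_id}.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) {
    aw_stop(paste0("file not found: ", path), "attweights_error_schema")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("respondent_id", "group_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    aw_stop(paste0("missing required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "attweights_error_schema")
  }
  item_cols <- grep("^item_", names(df), value = TRUE)
  if (!length(item_cols)) {
    aw_stop("no item_* columns found", "attweights_error_schema")
  }
  Y <- as.matrix(df[item_cols])
  storage.mode(Y) <- "integer"
  rownames(Y) <- df$respondent_id
  glev <- sort(unique(df$group_id))
  list(responses = Y,
       group = match(df$group_id, glev),
       group_id = df$group_id,
       respondent_id = df$respondent_id)
}

#' Write the attentiveness-weights contract
#'
#' Columns: \code{respondent_id, group_id, scale_id, posterior_cier,
#' attentiveness_weight} (plus a \code{not_assessed} flag for rows without a
#' usable screen time).
#'
#' @param weights data.frame as produced by
#'   \code{\link{decompose_screen_times}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_weights_csv <- function(weights, path) {
  utils::write.csv(weights, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the attentiveness-weights contract
#' @param path CSV path written by \code{\link{write_weights_csv}}.
#' @return data.frame of weights.
#' @export
read_weights_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("respondent_id", "group_id", "scale_id", "posterior_cier",
            "attentiveness_weight")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    aw_stop(paste0("missing required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "attweights_error_schema")
  }
  df
}

#' Write a decomposition summary as JSON
#'
#' Per group x scale: selected number of components, component means, SDs
#' and proportions, the C/IER proportion, and the BIC path over the
#' candidate component counts.
#'
#' @param decomposition result of \code{\link{decompose_screen_times}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_decomposition_json <- function(decomposition, path) {
  cells <- lapply(decomposition$fits, function(cell) {
    fit <- cell$fit
    list(
      group_id = cell$group_id,
      scale_id = cell$scale_id,
      n_obs = fit$n_obs,
      n_components = fit$n_components,
      means = fit$means,
      sds = fit$sds,
      proportions = fit$proportions,
      bic = fit$bic,
      cier_component = cell$cier_component,
      cier_proportion = cell$cier_proportion,
      mean_cier_time_per_item = cell$mean_cier_time_per_item,
      bic_path = attr(fit, "bic_path")
    )
  })
  jsonlite::write_json(cells, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write simulated data to the CSV contracts
#'
#' Emits the screen-record CSV, one wide response CSV per scale
#' (\code{responses_<scale>.csv}), and a truth-labels CSV.
#'
#' @param sim a \code{\link{simulate_cier_dataset}} result.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(screen_records = file.path(dir, "screen_records.csv"),
                truth = file.path(dir, "truth_labels.csv"))
  utils::write.csv(sim$screen_records, paths$screen_records,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(sim$truth, paths$truth, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  for (s in names(sim$responses)) {
    Y <- sim$responses[[s]]$responses
    df <- data.frame(
      respondent_id = rownames(Y),
      group_id = sprintf("G%02d", sim$responses[[s]]$group),
      Y, stringsAsFactors = FALSE
    )
    names(df)[-(1:2)] <- paste0("item_", seq_len(ncol(Y)))
    p <- file.path(dir, paste0("responses_", s, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", na = "")
    paths[[paste0("responses_", s)]] <- p
  }
  invisible(paths)
}
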
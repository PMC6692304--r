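#' Run a full screening experiment
#'
#' Ties the pipeline together for one dataset: build the shared stratified
#' folds, train the pairwise rate table (or reuse a supplied one), screen at
#' each configured threshold from the highest downwards, cross-check every
#' surviving candidate, and optionally write results (CSV + JSON + run log)
#' to an output directory. An empty candidate set is a finding, not a
#' failure.
#'
#' @param dataset a [labeled_dataset()], or a path accepted by
#'   [read_dataset()] (then \code{...} is passed on to it).
#' @param thresholds sensitivity threshold(s) t; default the grid
#'   \code{seq(1, 0.5, by = -0.05)}.
#' @param repeats,folds cross-validation layout (default 10 x 10).
#' @param seed integer seed for the fold assignment.
#' @param labels optional label subset for partial-cascade screening.
#' @param learner a [base_learner()] (default linear SVM, cost 1).
#' @param table optional pre-trained \code{rate_table} (with prediction
#'   cache) to reuse instead of refitting.
#' @param out_dir optional output directory for result files.
#' @param ... passed to [read_dataset()] when \code{dataset} is a path.
#' @return a named list of cross-checked [cascades_screen()] results, one
#'   per threshold (highest first), invisibly when writing files.
#' @export
run_screen <- function(dataset, thresholds = seq(1, 0.5, by = -0.05),
                       repeats = 10L, folds = 10L, seed = 1L,
                       labels = NULL, learner = svm_learner(),
                       table = NULL, out_dir = NULL, ...) {
  if (is.character(dataset)) dataset <- read_dataset(dataset, ...)
  stopifnot(inherits(dataset, "labeled_dataset"))
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  fa <- if (!is.null(table) && !is.null(table$folds)) table$folds
        else make_folds(dataset, repeats, folds, seed)
  if (is.null(table)) {
    table <- train_pairwise_table(dataset, fa, learner)
  }
  results <- list()
  log_lines <- c(
    sprintf("ocscreen run: %d samples, %d classes, learner %s",
            nrow(dataset$features), length(dataset$label_space),
            table$provenance$learner %||% "unknown"),
    sprintf("folds: %d repeats x %d folds, seed %d",
            fa$repeats, fa$folds, fa$seed))
  for (t in thresholds) {
    res <- cascades_screen(table, t, labels = labels)
    res <- cross_check(res, dataset, fa, table)
    key <- sprintf("t=%.2f", t)
    results[[key]] <- res
    log_lines <- c(log_lines, sprintf(
      "t=%.2f: %d candidate(s), %s orders rejected (%.1f%%), %d lookups",
      t, length(res$candidates),
      format(res$rejected_count, big.mark = ","),
      100 * res$rejected_count / res$n_orders, res$lookups))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_rate_table(table, file.path(out_dir, "rate_table.json"))
    for (key in names(results)) {
      stem <- file.path(out_dir, gsub("[=.]", "_", paste0("screen_", key)))
      write_screen_result(results[[key]], stem)
    }
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    return(invisible(results))
  }
  results
}

#' Evaluate one named order without screening
#'
#' Builds folds and the rate table (or reuses supplied ones), then reports
#' the certified bound and the cross-validated class-wise sensitivities of a
#' single assumed order.
#'
#' @inheritParams run_screen
#' @param order a class order: character vector or \code{"a<b<c"} string.
#' @return a [evaluate_cascade()] sensitivity report.
#' @export
run_evaluate <- function(dataset, order, repeats = 10L, folds = 10L,
                         seed = 1L, learner = svm_learner(), table = NULL,
                         out_dir = NULL, ...) {
  if (is.character(dataset)) dataset <- read_dataset(dataset, ...)
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(order) == 1L && grepl("<", order, fixed = TRUE)) {
    order <- parse_order(order)
  }
  unknown <- setdiff(as.character(order), dataset$label_space)
  if (length(unknown)) {
    stop("unknown label(s) ", paste(unknown, collapse = ", "),
         "; valid labels: ", paste(dataset$label_space, collapse = ", "))
  }
  fa <- if (!is.null(table) && !is.null(table$folds)) table$folds
        else make_folds(dataset, repeats, folds, seed)
  if (is.null(table)) table <- train_pairwise_table(dataset, fa, learner)
  report <- evaluate_cascade(dataset, order, fa, table)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(order = order_string(report$order),
           class_sensitivities = as.list(report$class_sensitivities),
           min_sensitivity = report$min_sensitivity,
           class_bounds = as.list(report$bounds$class_bound),
           overall_bound = report$bounds$overall_bound),
      file.path(out_dir, "evaluate.json"),
      digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' Write a screen result as CSV and JSON
#'
#' The CSV holds one candidate per row (order string, overall bound,
#' cross-checked minimal sensitivity and pass flag when present); the JSON
#' carries the full result including counts, lookups and provenance.
#'
#' @param result a [cascades_screen()] result (cross-checked or not).
#' @param stem output path without extension; writes \code{<stem>.csv} and
#'   \code{<stem>.json}.
#' @return \code{stem}, invisibly.
#' @export
write_screen_result <- function(result, stem) {
  stopifnot(inherits(result, "screen_result"))
  df <- data.frame(order = vapply(result$candidates, order_string,
                                  character(1L)),
                   bound = result$bounds,
                   stringsAsFactors = FALSE)
  if (!is.null(result$cross_check)) {
    df$min_sensitivity <- result$cross_check$min_sensitivity
    df$pass <- result$cross_check$pass
  }
  utils::write.table(df, paste0(stem, ".csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  doc <- list(threshold = result$threshold,
              labels = result$labels,
              n_orders = result$n_orders,
              rejected_count = result$rejected_count,
              lookups = result$lookups,
              candidates = df,
              provenance = result$provenance)
  jsonlite::write_json(doc, paste0(stem, ".json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(stem)
}
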
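#' Class order
#'
#' A candidate total order of (a subset of) the class labels, written
#' \eqn{y_{(1)} \prec \ldots \prec y_{(m)}}. Orders over the full label space
#' are full cascades; orders over a strict subset are partial cascades.
#'
#' @param sequence character vector of distinct labels, length >= 2.
#' @param label_space optional label space to validate against.
#' @return the validated character vector, classed \code{class_order} with a
#'   \code{full} attribute when \code{label_space} is supplied.
#' @export
class_order <- function(sequence, label_space = NULL) {
  sequence <- as.character(sequence)
  if (length(sequence) < 2L) stop("an order needs at least 2 labels")
  if (anyDuplicated(sequence)) {
    stop("repeated label(s) in order: ",
         paste(unique(sequence[duplicated(sequence)]), collapse = ", "))
  }
  if (!is.null(label_space)) {
    unknown <- setdiff(sequence, label_space)
    if (length(unknown)) {
      stop("label(s) not in label space: ", paste(unknown, collapse = ", "))
    }
    attr(sequence, "full") <- length(sequence) == length(label_space)
  }
  class(sequence) <- c("class_order", class(sequence))
  sequence
}

#' Format an order as a precedence string
#'
#' @param order character vector of labels.
#' @return e.g. \code{"embryo<larva<pupa<adult"}.
#' @export
order_string <- function(order) paste(unclass(order), collapse = "<")

#' @rdname order_string
#' @param string a precedence string using \code{"<"} as separator.
#' @param label_space optional label space to validate against.
#' @export
parse_order <- function(string, label_space = NULL) {
  class_order(strsplit(string, "<", fixed = TRUE)[[1L]], label_space)
}

#' Predict with an ordinal classifier cascade
#'
#' Implements the cascade fusion rule: samples are passed sequentially
#' through the binary base classifiers of the assumed order. The first
#' classifier that predicts its first class stops the cascade and determines
#' the output; a sample passed on by every classifier receives the last label
#' of the order. Classifiers after the stop are not consulted.
#'
#' @param features numeric matrix of samples to classify (rows).
#' @param order character vector, the assumed class order (length m).
#' @param pair_models list of m - 1 fitted binary models for the adjacent
#'   pairs of the order, either positional or named with
#'   \code{"first<second"} names. Each model is either a function
#'   \code{features -> labels} or an object with a \code{predict} method
#'   returning labels of the pair.
#' @return character vector of predicted labels, all drawn from \code{order}.
#' @export
predict_cascade <- function(features, order, pair_models) {
  order <- as.character(order)
  m <- length(order)
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  models <- resolve_pair_models(pair_models, order)
  out <- rep(NA_character_, nrow(features))
  undecided <- seq_len(nrow(features))
  for (k in seq_len(m - 1L)) {
    if (!length(undecided)) break
    p <- apply_model(models[[k]], features[undecided, , drop = FALSE])
    bad <- setdiff(unique(p), order[c(k, k + 1L)])
    if (length(bad)) {
      stop("model for pair (", order[k], ", ", order[k + 1L],
           ") predicted foreign label(s): ", paste(bad, collapse = ", "))
    }
    fired <- p == order[k]
    out[undecided[fired]] <- order[k]
    undecided <- undecided[!fired]
  }
  out[undecided] <- order[m]
  out
}

resolve_pair_models <- function(pair_models, order) {
  m <- length(order)
  wanted <- paste(order[-m], order[-1L], sep = "<")
  if (!is.null(names(pair_models)) && all(nzchar(names(pair_models)))) {
    missing <- setdiff(wanted, names(pair_models))
    if (length(missing)) {
      stop("missing pair model(s): ", paste(missing, collapse = ", "))
    }
    return(pair_models[wanted])
  }
  if (length(pair_models) != m - 1L) {
    stop("need ", m - 1L, " pair models for an order of ", m,
         " classes, got ", length(pair_models))
  }
  pair_models
}

apply_model <- function(model, features) {
  if (is.function(model)) as.character(model(features))
  else as.character(stats::predict(model, features))
}

#' Theorem-style upper bounds on cascade class-wise sensitivities
#'
#' From the memorised rate table alone (no refitting), computes for each
#' position i of an assumed order an upper bound on the sensitivity that any
#' cascade built from these base classifiers can attain for class
#' \eqn{y_{(i)}}:
#' \itemize{
#'   \item \code{fc_bound}: the first-class sensitivity \code{FC} of the i-th
#'     base pair — the cascade can never recognise \eqn{y_{(i)}} more often
#'     than its own base classifier does (undefined at the last position,
#'     which has no classifier with it as first class);
#'   \item \code{chain_bound}: the minimum over all earlier pairs k < i of
#'     their pass-on rate \code{SC} for class \eqn{y_{(i)}} — a sample
#'     claimed by an earlier classifier never reaches position i (undefined
#'     at the first position).
#' }
#' The per-class bound is the minimum of the two, and \code{overall_bound}
#' (the bound on the minimal class-wise sensitivity \eqn{p^*}) is the minimum
#' over positions.
#'
#' @param table a \code{rate_table} covering the order's labels.
#' @param order character vector of labels (length >= 2).
#' @return An object of class \code{bound_report}: list with \code{order},
#'   \code{fc_bound}, \code{chain_bound}, \code{class_bound} (named numeric
#'   vectors over positions) and \code{overall_bound}.
#' @export
bound_for_order <- function(table, order) {
  stopifnot(inherits(table, "rate_table"))
  order <- as.character(order)
  check_order_in_table(table, order)
  m <- length(order)
  fc <- chain <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (i < m) fc[i] <- table$FC[order[i], order[i + 1L]]
    if (i > 1L) {
      chain[i] <- min(vapply(seq_len(i - 1L), function(k) {
        table$SC[order[k], order[k + 1L], order[i]]
      }, numeric(1L)))
    }
  }
  class_bound <- pmin(fc, chain, na.rm = TRUE)
  names(fc) <- names(chain) <- names(class_bound) <- order
  structure(list(order = order, fc_bound = fc, chain_bound = chain,
                 class_bound = class_bound,
                 overall_bound = min(class_bound)),
            class = "bound_report")
}

check_order_in_table <- function(table, order) {
  if (length(order) < 2L) stop("an order needs at least 2 labels")
  if (anyDuplicated(order)) stop("repeated labels in order")
  unknown <- setdiff(order, table$labels)
  if (length(unknown)) {
    stop("label(s) missing from rate table: ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.bound_report <- function(x, ...) {
  cat("bound_report for ", order_string(x$order), "\n", sep = "")
  cat("  overall bound on p*: ", format_pct(x$overall_bound), "\n", sep = "")
  df <- data.frame(class = x$order,
                   fc_bound = format_pct(x$fc_bound),
                   chain_bound = format_pct(x$chain_bound),
                   class_bound = format_pct(x$class_bound))
  print(df, row.names = FALSE)
  invisible(x)
}

format_pct <- function(x) ifelse(is.na(x), "-", sprintf("%.1f%%", 100 * x))

#' Evaluate an ordinal cascade under the shared cross-validation
#'
#' Classifies the held-out samples of every (repeat, fold) cell with the
#' cascade built from the \emph{same} fitted fold models that produced the
#' rate table (via the per-sample prediction cache), then aggregates
#' class-wise sensitivities by unweighted mean over cells and reports the
#' minimal class-wise sensitivity \eqn{p^*}, the correctness measure of the
#' assumed order. For partial orders, samples of foreign classes are ignored.
#'
#' @param dataset the [labeled_dataset()] the table was trained on.
#' @param order character vector of labels to evaluate as a cascade.
#' @param folds the shared [make_folds()] assignment.
#' @param table a \code{rate_table} with its prediction cache
#'   (\code{cache_predictions = TRUE}).
#' @return An object of class \code{sensitivity_report}: list with
#'   \code{order}, \code{class_sensitivities} (named, per position),
#'   \code{min_sensitivity}, and the matching \code{bound_report} in
#'   \code{$bounds} for side-by-side reporting.
#' @export
evaluate_cascade <- function(dataset, order, folds, table) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(table, "rate_table"))
  check_folds_match(folds, dataset)
  if (is.null(table$pred)) {
    stop("rate table has no prediction cache; retrain with ",
         "cache_predictions = TRUE")
  }
  if (!is.null(table$folds) &&
      !identical(table$folds$assignment, folds$assignment)) {
    stop("fold assignment differs from the one the rate table was trained on")
  }
  order <- as.character(order)
  check_order_in_table(table, order)
  unknown <- setdiff(order, dataset$label_space)
  if (length(unknown)) {
    stop("label(s) not in dataset: ", paste(unknown, collapse = ", "))
  }
  m <- length(order)
  sel <- which(dataset$labels %in% order)
  lab_sel <- dataset$labels[sel]
  sens_sum <- stats::setNames(numeric(m), order)
  sens_cells <- stats::setNames(numeric(m), order)
  for (rep_i in seq_len(folds$repeats)) {
    # first adjacent pair predicting its first class determines the label
    firstmat <- vapply(seq_len(m - 1L), function(k) {
      table$pred[order[k], order[k + 1L], rep_i, sel]
    }, logical(length(sel)))
    pos <- max.col(cbind(firstmat + 0, 1), ties.method = "first")
    pred_label <- order[pos]
    fold_of <- folds$assignment[rep_i, sel]
    for (i in seq_len(m)) {
      in_class <- lab_sel == order[i]
      per_fold <- tapply(pred_label[in_class] == order[i],
                         fold_of[in_class], mean)
      sens_sum[i] <- sens_sum[i] + sum(per_fold)
      sens_cells[i] <- sens_cells[i] + length(per_fold)
    }
  }
  class_sens <- sens_sum / sens_cells
  structure(list(order = order,
                 class_sensitivities = class_sens,
                 min_sensitivity = min(class_sens),
                 bounds = bound_for_order(table, order)),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("sensitivity_report for ", order_string(x$order), "\n", sep = "")
  cat("  minimal class-wise sensitivity p*: ",
      format_pct(x$min_sensitivity),
      "   (bound: ", format_pct(x$bounds$overall_bound), ")\n", sep = "")
  df <- data.frame(class = x$order,
                   sensitivity = format_pct(x$class_sensitivities),
                   bound = format_pct(x$bounds$class_bound))
  print(df, row.names = FALSE)
  invisible(x)
}
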
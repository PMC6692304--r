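#' Labeled dataset container
#'
#' Bundles a real-valued feature matrix (samples in rows) with one categorical
#' class label per sample and an optional per-sample group identifier (e.g. a
#' subject id for paired designs). All downstream steps — pairwise training,
#' cascade evaluation, order screening — operate on this container.
#'
#' @param features numeric matrix, samples x features. Row names are taken as
#'   sample ids (generated if absent); no missing values are allowed.
#' @param labels character or factor vector of class labels, one per row of
#'   \code{features}. The label space is the set of distinct labels in order
#'   of first appearance (or the factor level order for factors).
#' @param groups optional vector of group ids, one per sample. Samples sharing
#'   a group id are kept in the same cross-validation fold.
#'
#' @return An object of class \code{labeled_dataset}: a list with elements
#'   \code{features}, \code{labels}, \code{label_space}, \code{groups}.
#' @examples
#' d <- labeled_dataset(matrix(rnorm(8), 4, 2), c("a", "a", "b", "b"))
#' d$label_space
#' @export
labeled_dataset <- function(features, labels, groups = NULL) {
  if (!is.matrix(features)) features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyNA(features)) {
    bad <- which(apply(features, 1L, anyNA))[1L]
    stop("feature matrix contains missing values (first offending sample: ",
         rownames(features)[bad] %||% bad, ")")
  }
  if (is.factor(labels)) {
    label_space <- levels(droplevels(labels))
    labels <- as.character(labels)
  } else {
    labels <- as.character(labels)
    label_space <- unique(labels)
  }
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop("unlabeled sample(s): ",
         paste(utils::head(which(is.na(labels) | !nzchar(labels)), 5L),
               collapse = ", "))
  }
  if (length(labels) != nrow(features)) {
    stop("number of labels (", length(labels),
         ") does not match number of samples (", nrow(features), ")")
  }
  if (length(label_space) < 2L) stop("need at least 2 distinct class labels")
  if (is.null(rownames(features))) {
    rownames(features) <- paste0("s", seq_len(nrow(features)))
  }
  if (anyDuplicated(rownames(features))) {
    stop("duplicated sample ids: ",
         paste(unique(rownames(features)[duplicated(rownames(features))]),
               collapse = ", "))
  }
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (length(groups) != nrow(features)) {
      stop("number of group ids does not match number of samples")
    }
  }
  structure(
    list(features = features, labels = labels,
         label_space = label_space, groups = groups),
    class = "labeled_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset: ", nrow(x$features), " samples x ",
      ncol(x$features), " features, ", length(x$label_space),
      " classes\n", sep = "")
  tab <- table(factor(x$labels, levels = x$label_space))
  cat("  classes:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  if (!is.null(x$groups)) {
    cat("  groups: ", length(unique(x$groups)), " group ids\n", sep = "")
  }
  invisible(x)
}

#' Read a labeled dataset from a delimited text matrix
#'
#' Reads a numeric matrix from TSV/CSV (header row of feature ids, first
#' column sample ids) together with class labels, which can live either in a
#' named column of the same file or in a separate two-column sample-to-label
#' file. Series-matrix style files with samples in columns are supported via
#' \code{orientation = "samples_in_columns"}.
#'
#' @param path path to the delimited matrix file.
#' @param label_column name of the column of \code{path} holding class labels
#'   (used when labels are stored alongside the features).
#' @param label_file path to a two-column delimited file (sample id, label);
#'   alternative to \code{label_column}.
#' @param group_column optional name of a column holding group ids.
#' @param orientation \code{"samples_in_rows"} (default) or
#'   \code{"samples_in_columns"}.
#' @param sep field separator; defaults to tab.
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(path, label_column = NULL, label_file = NULL,
                         group_column = NULL,
                         orientation = c("samples_in_rows", "samples_in_columns"),
                         sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label_column) && is.null(label_file)) {
    stop("labels must be supplied via label_column or label_file")
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           row.names = 1L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (orientation == "samples_in_columns") {
    # label/group columns only make sense with samples in rows
    raw <- as.data.frame(t(as.matrix(raw)), stringsAsFactors = FALSE,
                         check.names = FALSE)
  }
  labels <- NULL
  groups <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% colnames(raw)) {
      stop("label column '", label_column, "' not found in ", path)
    }
    labels <- as.character(raw[[label_column]])
    raw <- raw[, setdiff(colnames(raw), label_column), drop = FALSE]
  }
  if (!is.null(group_column)) {
    if (!group_column %in% colnames(raw)) {
      stop("group column '", group_column, "' not found in ", path)
    }
    groups <- as.character(raw[[group_column]])
    raw <- raw[, setdiff(colnames(raw), group_column), drop = FALSE]
  }
  feat <- as.matrix(raw)
  if (!is.numeric(feat)) {
    bad <- colnames(raw)[!vapply(raw, is.numeric, logical(1L))]
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(label_file)) {
    lab <- utils::read.table(label_file, header = FALSE, sep = sep,
                             stringsAsFactors = FALSE)
    if (ncol(lab) < 2L) stop("label file must have two columns: sample, label")
    idx <- match(rownames(feat), as.character(lab[[1L]]))
    if (anyNA(idx)) {
      stop("missing label for sample(s): ",
           paste(utils::head(rownames(feat)[is.na(idx)], 5L), collapse = ", "))
    }
    labels <- as.character(lab[[2L]])[idx]
  }
  labeled_dataset(feat, labels, groups)
}

#' Write a labeled dataset to a delimited text file
#'
#' Writes the feature matrix with sample ids in the first column, feature ids
#' in the header, and the labels (plus groups, if present) as trailing
#' columns. [read_dataset()] on the written file reproduces the dataset.
#'
#' @param dataset a [labeled_dataset()].
#' @param path output path.
#' @param sep field separator; defaults to tab.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(dataset, path, sep = "\t") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- data.frame(sample = rownames(dataset$features),
                   dataset$features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$label <- dataset$labels
  if (!is.null(dataset$groups)) df$group <- dataset$groups
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Conditional prediction rate
#'
#' Fraction of predicted labels equal to a target label, the empirical
#' estimate of the probability that a classifier assigns \code{target} to a
#' sample of the evaluated class. Depending on the caller's context this is a
#' sensitivity (evaluation class equals target), a confusion (both inside the
#' classifier's label space) or an external rate (evaluation class foreign to
#' the classifier).
#'
#' @param predicted vector of predicted labels for samples of one class.
#' @param target the label whose prediction rate is sought.
#' @return a rate in \[0, 1\].
#' @examples
#' conditional_prediction_rate(c("a", "a", "b"), "a") # 2/3
#' @export
conditional_prediction_rate <- function(predicted, target) {
  if (length(predicted) == 0L) stop("rate undefined for empty prediction list")
  mean(as.character(predicted) == as.character(target))
}
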
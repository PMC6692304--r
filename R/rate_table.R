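#' Train all pairwise base classifiers and memorise their rate table
#'
#' For every unordered class pair, one binary classifier is fitted per
#' (repeat, fold) cell of the shared cross-validation on the training-portion
#' samples of the two classes only, and evaluated on the test-portion samples
#' of \emph{all} classes. Both ordered directions of a pair share the fitted
#' decision boundary with first/second roles swapped, so the table covers all
#' \eqn{(m-1)m} ordered pairs.
#'
#' Two families of held-out rates are memorised, averaged by unweighted mean
#' over the repeat x fold cells:
#' \describe{
#'   \item{\code{FC[i, j]}}{first-class sensitivity: rate at which held-out
#'     samples of class \eqn{y_i} are predicted \eqn{y_i} by the (i, j)
#'     classifier.}
#'   \item{\code{SC[i, j, r]}}{pass-on rate: rate at which held-out samples of
#'     class \eqn{y_r} are predicted as the second class \eqn{y_j}; defined
#'     for every class r, including r = i (then \code{1 - FC[i, j]}) and
#'     r = j (then the pair's second-class sensitivity). For r outside the
#'     pair it is an external rate, measured on the test portion of class r
#'     in the same folds as every other rate.}
#' }
#' The per-sample held-out predictions of every pair are cached
#' (\code{$pred}), so any ordinal cascade over these classes can later be
#' evaluated from the identical fitted fold models without refitting — this
#' is what keeps exhaustive order screening tractable and makes the
#' sensitivity bounds dominate the evaluated cascade rates exactly rather
#' than approximately.
#'
#' @param dataset a [labeled_dataset()].
#' @param folds a [make_folds()] assignment for the same dataset.
#' @param learner a [base_learner()]; default linear SVM with cost 1.
#' @param cache_predictions keep the per-sample prediction cache (default
#'   TRUE; set FALSE to save memory when only bounds/screening are needed).
#' @return An object of class \code{rate_table}: list with \code{labels},
#'   \code{FC} (m x m matrix, diagonal NA), \code{SC} (m x m x m array),
#'   \code{pred} (logical \[m, m, repeats, samples\] predicted-first-class
#'   cache, or NULL), \code{folds}, \code{provenance}.
#' @export
train_pairwise_table <- function(dataset, folds, learner = svm_learner(),
                                 cache_predictions = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(learner, "base_learner"))
  check_folds_match(folds, dataset)
  labels <- dataset$label_space
  m <- length(labels)
  n <- nrow(dataset$features)
  cls <- dataset$labels
  # pred[i, j, rep, s]: TRUE if the (i, j) model of the fold holding sample s
  # as a test sample (in this repeat) predicted the first class y_i
  pred <- array(NA, dim = c(m, m, folds$repeats, n),
                dimnames = list(labels, labels, NULL, rownames(dataset$features)))
  for (rep_i in seq_len(folds$repeats)) {
    fold_of <- folds$assignment[rep_i, ]
    for (f in seq_len(folds$folds)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      for (i in seq_len(m - 1L)) {
        for (j in seq((i + 1L), m)) {
          tri <- train[cls[train] %in% labels[c(i, j)]]
          if (!any(cls[tri] == labels[i]) || !any(cls[tri] == labels[j])) {
            stop("training portion of repeat ", rep_i, ", fold ", f,
                 " lacks a sample of pair (", labels[i], ", ", labels[j], ")")
          }
          model <- tryCatch(
            learner$fit(dataset$features[tri, , drop = FALSE], cls[tri]),
            error = function(e) stop("learner failed on pair (", labels[i],
                                     ", ", labels[j], "): ",
                                     conditionMessage(e)))
          p <- learner$predict(model,
                               dataset$features[test, , drop = FALSE])
          first <- p == labels[i]
          pred[i, j, rep_i, test] <- first
          pred[j, i, rep_i, test] <- !first
        }
      }
    }
  }
  rates <- rates_from_predictions(pred, cls, labels, folds)
  structure(
    list(labels = labels, FC = rates$FC, SC = rates$SC,
         pred = if (cache_predictions) pred else NULL,
         folds = folds,
         provenance = list(
           learner = learner$name,
           hyperparameters = learner$hyperparameters,
           n_samples = n, n_features = ncol(dataset$features),
           class_sizes = as.list(table(factor(cls, levels = labels))),
           fold_seed = folds$seed, repeats = folds$repeats,
           folds = folds$folds)),
    class = "rate_table"
  )
}

# Per-fold class-conditional rates, averaged unweighted over repeat x fold
rates_from_predictions <- function(pred, cls, labels, folds) {
  m <- length(labels)
  FC <- matrix(NA_real_, m, m, dimnames = list(labels, labels))
  SC <- array(NA_real_, dim = c(m, m, m),
              dimnames = list(labels, labels, labels))
  class_idx <- lapply(labels, function(l) which(cls == l))
  n_cells <- folds$repeats * folds$folds
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      first_rate <- numeric(m) # per class r: mean per-fold rate predicted y_i
      for (r in seq_len(m)) {
        sel <- class_idx[[r]]
        acc <- 0
        for (rep_i in seq_len(folds$repeats)) {
          fold_of <- folds$assignment[rep_i, sel]
          v <- pred[i, j, rep_i, sel]
          acc <- acc + sum(tapply(v, fold_of, mean))
        }
        first_rate[r] <- acc / n_cells
      }
      FC[i, j] <- first_rate[i]
      SC[i, j, ] <- 1 - first_rate
    }
  }
  list(FC = FC, SC = SC)
}

#' Assemble a rate table from precomputed rates
#'
#' Constructor used when rates come from elsewhere (deserialisation, or
#' synthetic tables in property checks) rather than from
#' [train_pairwise_table()]. Enforces the table invariants: all rates in
#' \[0, 1\], and \code{FC[i, j] + SC[i, j, i] = 1} for every ordered pair
#' (the binary outputs partition the held-out samples of the first class).
#'
#' @param labels character vector of class labels (length m >= 2).
#' @param FC m x m numeric matrix of first-class sensitivities (diagonal
#'   ignored).
#' @param SC m x m x m numeric array of pass-on rates.
#' @param provenance optional provenance list.
#' @return A \code{rate_table} (without a prediction cache).
#' @export
rate_table <- function(labels, FC, SC, provenance = list()) {
  labels <- as.character(labels)
  m <- length(labels)
  if (m < 2L) stop("need at least 2 labels")
  stopifnot(is.matrix(FC), all(dim(FC) == c(m, m)),
            is.array(SC), all(dim(SC) == c(m, m, m)))
  off <- upper.tri(FC) | lower.tri(FC)
  if (any(FC[off] < 0 | FC[off] > 1, na.rm = FALSE) || anyNA(FC[off])) {
    stop("FC rates must be in [0, 1] for all ordered pairs")
  }
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    if (anyNA(SC[i, j, ]) || any(SC[i, j, ] < 0 | SC[i, j, ] > 1)) {
      stop("SC rates must be in [0, 1] for all ordered pairs")
    }
    if (abs(FC[i, j] + SC[i, j, i] - 1) > 1e-8) {
      stop("FC[i, j] + SC[i, j, i] must equal 1 (pair ",
           labels[i], ", ", labels[j], ")")
    }
  }
  dimnames(FC) <- list(labels, labels)
  dimnames(SC) <- list(labels, labels, labels)
  structure(list(labels = labels, FC = FC, SC = SC, pred = NULL,
                 folds = NULL, provenance = provenance),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  m <- length(x$labels)
  cat("rate_table: ", m, " classes, ", (m - 1L) * m,
      " ordered pairs", sep = "")
  if (!is.null(x$provenance$learner)) {
    cat(", learner ", x$provenance$learner, sep = "")
  }
  cat("\n  adjacent-pair FC range: [",
      sprintf("%.3f", min(x$FC, na.rm = TRUE)), ", ",
      sprintf("%.3f", max(x$FC, na.rm = TRUE)), "]\n", sep = "")
  if (!is.null(x$pred)) cat("  per-sample prediction cache present\n")
  invisible(x)
}

#' Serialise a rate table to JSON
#'
#' Writes labels, FC, SC and provenance as a self-describing JSON document so
#' screening can run without refitting. Rates are written at full floating
#' precision and round-trip bit-exactly. The per-sample prediction cache is
#' not serialised; a table read back supports bounds and screening but not
#' cascade cross-checking (which needs the cached fold models).
#'
#' @param table a \code{rate_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_rate_table <- function(table, path) {
  stopifnot(inherits(table, "rate_table"))
  labels <- table$labels
  m <- length(labels)
  pairs <- which(row(table$FC) != col(table$FC), arr.ind = TRUE)
  fc_df <- data.frame(first = labels[pairs[, 1L]],
                      second = labels[pairs[, 2L]],
                      rate = table$FC[pairs])
  sc_df <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    data.frame(first = labels[i], second = labels[j],
               eval_class = labels, rate = table$SC[i, j, ])
  }))
  # digits = I(17): significant digits, enough for exact double round-trip
  jsonlite::write_json(
    list(labels = labels, FC = fc_df, SC = sc_df,
         provenance = table$provenance),
    path, digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- as.character(doc$labels)
  m <- length(labels)
  FC <- matrix(NA_real_, m, m, dimnames = list(labels, labels))
  FC[cbind(match(doc$FC$first, labels), match(doc$FC$second, labels))] <-
    as.numeric(doc$FC$rate)
  SC <- array(NA_real_, dim = c(m, m, m),
              dimnames = list(labels, labels, labels))
  SC[cbind(match(doc$SC$first, labels), match(doc$SC$second, labels),
           match(doc$SC$eval_class, labels))] <- as.numeric(doc$SC$rate)
  rate_table(labels, FC, SC, provenance = as.list(doc$provenance))
}

#' Training-effort counts for exhaustive order screening
#'
#' \code{count_precalc_trainings(n)} is the number of binary base classifiers
#' that must be fitted when every ordered class pair is trained once and
#' reused across all cascades: \eqn{(n-1) n}. \code{count_denovo_trainings(n)}
#' is the cost of training every one of the \eqn{n!} cascades from scratch,
#' each needing \eqn{n-1} base classifiers: \eqn{(n-1) n!}. Their ratio is
#' \eqn{(n-1)!}: at 10 classes, 90 fits instead of more than
#' \eqn{3 \cdot 10^7}.
#'
#' @param n_classes number of classes (>= 2).
#' @return a count (numeric, since \eqn{(n-1) n!} overflows integers quickly).
#' @examples
#' count_precalc_trainings(10) # 90
#' count_denovo_trainings(10)  # 9 * 10!
#' @export
count_precalc_trainings <- function(n_classes) {
  n <- check_n_classes(n_classes)
  (n - 1) * n
}

#' @rdname count_precalc_trainings
#' @export
count_denovo_trainings <- function(n_classes) {
  n <- check_n_classes(n_classes)
  (n - 1) * factorial(n)
}

check_n_classes <- function(n_classes) {
  if (length(n_classes) != 1L || is.na(n_classes) || n_classes < 2 ||
      n_classes != round(n_classes)) {
    stop("n_classes must be a single integer >= 2")
  }
  as.numeric(n_classes)
}
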
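#' Repeated stratified cross-validation folds
#'
#' Builds the shared fold structure on which every base-classifier rate and
#' every cascade evaluation is computed. One global assignment is used per
#' analysis run: the sensitivity bounds hold per test set, so computing all
#' rates and all cascade sensitivities on identical held-out sets keeps the
#' bound-dominance exact after averaging over folds.
#'
#' Stratification is by class: within each repeat, the samples of each class
#' are dealt into the folds as evenly as possible, so every fold's test set
#' contains at least one sample of every class. If \code{dataset$groups} is
#' present, whole groups are assigned to folds (a group never spans folds
#' within a repeat); each group must be label-pure.
#'
#' @param dataset a [labeled_dataset()].
#' @param repeats number of independent repeats (default 10).
#' @param folds number of folds per repeat (default 10, must be >= 2).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return An object of class \code{fold_assignment}: list with
#'   \code{repeats}, \code{folds}, \code{seed}, and \code{assignment}, an
#'   integer matrix (repeats x samples) of fold indices.
#' @export
make_folds <- function(dataset, repeats = 10L, folds = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  repeats <- as.integer(repeats); folds <- as.integer(folds)
  if (repeats < 1L) stop("repeats must be >= 1")
  if (folds < 2L) stop("folds must be >= 2 (no held-out split otherwise)")
  n <- nrow(dataset$features)
  cls <- factor(dataset$labels, levels = dataset$label_space)
  counts <- table(cls)
  if (any(counts < folds)) {
    small <- names(counts)[counts < folds]
    stop("class(es) with fewer samples than folds: ",
         paste(small, collapse = ", "))
  }
  units <- seq_len(n)
  unit_class <- cls
  if (!is.null(dataset$groups)) {
    g <- dataset$groups
    pure <- tapply(as.character(cls), g, function(v) length(unique(v)) == 1L)
    if (!all(pure)) {
      stop("group(s) span multiple classes: ",
           paste(names(pure)[!pure], collapse = ", "))
    }
    units <- split(seq_len(n), g)
    unit_class <- factor(vapply(units, function(i) as.character(cls[i[1L]]),
                                character(1L)),
                         levels = dataset$label_space)
    gcounts <- table(unit_class)
    if (any(gcounts < folds)) {
      stop("class(es) with fewer groups than folds: ",
           paste(names(gcounts)[gcounts < folds], collapse = ", "))
    }
  } else {
    units <- as.list(units)
  }
  set.seed(as.integer(seed))
  assignment <- matrix(NA_integer_, nrow = repeats, ncol = n)
  for (r in seq_len(repeats)) {
    for (cl in levels(unit_class)) {
      idx <- which(unit_class == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of_unit <- rep_len(sample.int(folds), length(idx))
      for (k in seq_along(idx)) {
        assignment[r, units[[idx[k]]]] <- fold_of_unit[k]
      }
    }
  }
  structure(
    list(repeats = repeats, folds = folds, seed = as.integer(seed),
         assignment = assignment, n_samples = n),
    class = "fold_assignment"
  )
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("fold_assignment: ", x$repeats, " repeats x ", x$folds,
      " folds over ", x$n_samples, " samples (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

check_folds_match <- function(folds, dataset) {
  if (!inherits(folds, "fold_assignment")) stop("not a fold_assignment")
  if (folds$n_samples != nrow(dataset$features)) {
    stop("fold assignment covers ", folds$n_samples,
         " samples but dataset has ", nrow(dataset$features))
  }
  invisible(TRUE)
}
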
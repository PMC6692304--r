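#' Exhaustive order screening with bound-based pruning
#'
#' Depth-first recursive enumeration of all total orders of the class labels
#' (or of a subset, for partial-cascade screening). The first position is
#' filled unconditionally; extending a partial order ending in class
#' \eqn{y_i} by class \eqn{y_j} requires the memorised rates of the
#' \eqn{(i, j)} base classifier to certify the sensitivity threshold:
#' \code{FC[i, j] >= t} and \code{SC[i, j, r] >= t} for every class r still
#' to be placed (including \eqn{y_j} itself; see \code{inclusive}). A failed
#' check prunes the whole subtree — \eqn{(remaining - 1)!} full orders are
#' rejected without being enumerated. With the inclusive check set, the
#' screen's checks coincide exactly with the terms of the per-order
#' sensitivity bound, so the candidates are precisely the orders whose
#' [bound_for_order()] is >= t. Candidates are emitted in lexicographic
#' order of label-space index; surviving candidates still require a
#' [cross_check()], since the bound does not guarantee \eqn{p^* \ge t}.
#'
#' @param table a \code{rate_table}.
#' @param threshold sensitivity threshold t in \[0, 1\]; comparisons are
#'   \code{>= t} (ties pass).
#' @param labels optional subset of the table's labels (>= 2) to screen
#'   partial cascades over; default all labels.
#' @param inclusive if TRUE (default) the pass-on check at each extension
#'   ranges over the remaining labels including the one being placed, which
#'   matches the chain bound term for the placed class; \code{FALSE} gives
#'   the laxer reading that only constrains classes placed later.
#' @return An object of class \code{screen_result}: list with
#'   \code{candidates} (list of orders), \code{bounds} (per candidate
#'   overall bound), \code{rejected_count}, \code{n_orders} (m!),
#'   \code{lookups} (number of rate comparisons performed),
#'   \code{threshold}, \code{labels}, \code{cross_check} (NULL until
#'   [cross_check()] runs).
#' @export
cascades_screen <- function(table, threshold, labels = NULL,
                            inclusive = TRUE) {
  stopifnot(inherits(table, "rate_table"))
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single rate in [0, 1]")
  }
  labels <- resolve_subset(table, labels)
  m <- length(labels)
  env <- new.env(parent = emptyenv())
  env$candidates <- vector("list", 64L)
  env$n_cand <- 0L
  env$rejected <- 0
  env$lookups <- 0
  recurse <- function(prefix, last, remaining) {
    if (!length(remaining)) {
      env$n_cand <- env$n_cand + 1L
      if (env$n_cand > length(env$candidates)) {
        length(env$candidates) <- 2L * length(env$candidates)
      }
      env$candidates[[env$n_cand]] <- prefix
      return(invisible())
    }
    for (j in remaining) {
      if (is.null(last)) {
        recurse(c(prefix, j), j, setdiff(remaining, j))
        next
      }
      check_set <- if (inclusive) remaining else setdiff(remaining, j)
      ok <- {
        env$lookups <- env$lookups + 1
        table$FC[last, j] >= threshold
      }
      if (ok) {
        for (r in check_set) {
          env$lookups <- env$lookups + 1
          if (table$SC[last, j, r] < threshold) { ok <- FALSE; break }
        }
      }
      if (ok) {
        recurse(c(prefix, j), j, setdiff(remaining, j))
      } else {
        env$rejected <- env$rejected + factorial(length(remaining) - 1L)
      }
    }
  }
  recurse(character(0L), NULL, labels)
  candidates <- env$candidates[seq_len(env$n_cand)]
  bounds <- vapply(candidates, function(o) bound_for_order(table, o)$overall_bound,
                   numeric(1L))
  structure(list(candidates = candidates, bounds = bounds,
                 rejected_count = env$rejected,
                 n_orders = factorial(m),
                 lookups = env$lookups,
                 threshold = threshold, labels = labels,
                 inclusive = inclusive,
                 cross_check = NULL,
                 provenance = table$provenance),
            class = "screen_result")
}

resolve_subset <- function(table, labels) {
  if (is.null(labels)) return(table$labels)
  labels <- as.character(labels)
  unknown <- setdiff(labels, table$labels)
  if (length(unknown)) {
    stop("label(s) missing from rate table: ", paste(unknown, collapse = ", "))
  }
  if (length(labels) < 2L) stop("label subset needs at least 2 labels")
  if (anyDuplicated(labels)) stop("duplicated labels in subset")
  # keep label-space order so candidate emission is lexicographic
  table$labels[table$labels %in% labels]
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result: threshold t = ", x$threshold, ", ",
      length(x$labels), " classes, ", format(x$n_orders, big.mark = ","),
      " orders\n", sep = "")
  cat("  candidates: ", length(x$candidates), "   rejected: ",
      format(x$rejected_count, big.mark = ","), " (",
      sprintf("%.1f%%", 100 * x$rejected_count / x$n_orders),
      ")   rate lookups: ", x$lookups, "\n", sep = "")
  if (length(x$candidates)) {
    for (i in seq_along(x$candidates)) {
      line <- paste0("  ", order_string(x$candidates[[i]]), "  bound ",
                     format_pct(x$bounds[i]))
      if (!is.null(x$cross_check)) {
        line <- paste0(line, "  p* ", format_pct(x$cross_check$min_sensitivity[i]),
                       if (x$cross_check$pass[i]) "  [pass]" else "  [fail]")
      }
      cat(line, "\n")
    }
  }
  invisible(x)
}

#' Brute-force screening oracle
#'
#' Enumerates every permutation of the label subset, computes
#' [bound_for_order()] directly and keeps the orders whose overall bound
#' meets the threshold. Pruning-free ground truth for [cascades_screen()];
#' guarded to small label sets.
#'
#' @inheritParams cascades_screen
#' @return list of candidate orders (character vectors), in lexicographic
#'   order of label-space index.
#' @export
brute_force_screen <- function(table, threshold, labels = NULL) {
  stopifnot(inherits(table, "rate_table"))
  labels <- resolve_subset(table, labels)
  if (length(labels) > 8L) {
    stop("brute force is guarded to at most 8 labels (factorial blow-up)")
  }
  perms <- permutations_of(labels)
  keep <- vapply(perms, function(o) {
    bound_for_order(table, o)$overall_bound >= threshold
  }, logical(1L))
  perms[keep]
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (tail in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], tail)
    }
  }
  out
}

#' Cross-check surviving candidates by full cascade evaluation
#'
#' Passing the rate-table bounds does not guarantee that a candidate order
#' actually attains \eqn{p^* \ge t}: each survivor is therefore evaluated as
#' a full cascade on the shared folds and marked pass/fail against the
#' screening threshold. Both the bound and the evaluated \eqn{p^*} are kept
#' for side-by-side reporting.
#'
#' @param result a [cascades_screen()] result.
#' @param dataset,folds,table the dataset, shared fold assignment, and rate
#'   table (with prediction cache) of the same run.
#' @return the \code{screen_result} completed with a \code{cross_check}
#'   data frame (order, bound, min_sensitivity, pass) and a
#'   \code{reports} list of [evaluate_cascade()] outputs.
#' @export
cross_check <- function(result, dataset, folds, table) {
  stopifnot(inherits(result, "screen_result"))
  reports <- lapply(result$candidates, function(o) {
    evaluate_cascade(dataset, o, folds, table)
  })
  min_sens <- vapply(reports, `[[`, numeric(1L), "min_sensitivity")
  result$cross_check <- data.frame(
    order = vapply(result$candidates, order_string, character(1L)),
    bound = result$bounds,
    min_sensitivity = if (length(min_sens)) min_sens else numeric(0L),
    pass = if (length(min_sens)) min_sens >= result$threshold else logical(0L),
    stringsAsFactors = FALSE)
  result$reports <- reports
  result
}

#' Maximum certified bound over all orders
#'
#' Exact maximisation of [bound_for_order()]'s overall bound over all
#' permutations of the label subset, by depth-first branch and bound: the
#' running minimum of the certified terms along a partial order can only
#' decrease when the order is extended (prefix monotonicity), so any prefix
#' whose running minimum is already at or below the best complete order found
#' can be discarded. Children are explored best-first. Equivalently, this is
#' the largest threshold at which [cascades_screen()] still returns a
#' candidate.
#'
#' @param table a \code{rate_table}.
#' @param labels optional label subset (default all).
#' @param exclude optional list of complete orders (character vectors) that
#'   may not supply the maximum, e.g. already-reported candidates.
#' @return list with \code{max_bound} and \code{order}, the maximising order
#'   (NULL if every order is excluded).
#' @export
max_cascade_bound <- function(table, labels = NULL, exclude = NULL) {
  stopifnot(inherits(table, "rate_table"))
  labels <- resolve_subset(table, labels)
  exclude_keys <- vapply(exclude %||% list(), order_string, character(1L))
  env <- new.env(parent = emptyenv())
  env$best <- -Inf
  env$best_order <- NULL
  recurse <- function(prefix, last, remaining, cur) {
    if (!length(remaining)) {
      if (!(order_string(prefix) %in% exclude_keys) && cur > env$best) {
        env$best <- cur
        env$best_order <- prefix
      }
      return(invisible())
    }
    vals <- vapply(remaining, function(j) {
      if (is.null(last)) return(cur)
      min(cur, table$FC[last, j], min(table$SC[last, j, remaining]))
    }, numeric(1L))
    for (j in remaining[order(vals, decreasing = TRUE)]) {
      v <- vals[[match(j, remaining)]]
      if (v > env$best) {
        recurse(c(prefix, j), j, setdiff(remaining, j), v)
      }
    }
  }
  recurse(character(0L), NULL, labels, Inf)
  list(max_bound = if (is.finite(env$best)) env$best else NA_real_,
       order = env$best_order)
}

#' Worst-case rate-lookup count of the recursive screen
#'
#' Closed form \eqn{f(m) = \sum_{k=2}^{m} k \binom{m}{k+1}} for the number of
#' rate-table comparisons the recursive screen needs in the worst case; with
#' early stopping the realised count collapses far below it on separable
#' data.
#'
#' @param n_classes number of classes (>= 2).
#' @return the worst-case comparison count (0 for two classes).
#' @examples
#' worst_case_lookups(4) # 2*choose(4,3) + 3*choose(4,4) = 11
#' @export
worst_case_lookups <- function(n_classes) {
  n <- check_n_classes(n_classes)
  k <- seq(2, n)
  sum(k * choose(n, k + 1))
}
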
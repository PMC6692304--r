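# Shared fixtures: all data is generated in code, seeds fixed.

# A valid random rate table: FC free in [0,1], SC[i,j,i] = 1 - FC[i,j]
# (binary conservation), all other SC entries free in [0,1].
random_rate_table <- function(m, seed) {
  set.seed(seed)
  labels <- paste0("c", seq_len(m))
  FC <- matrix(stats::runif(m * m), m, m)
  diag(FC) <- NA_real_
  SC <- array(stats::runif(m * m * m), dim = c(m, m, m))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) SC[i, j, i] <- 1 - FC[i, j]
  }
  rate_table(labels, FC, SC)
}

# Small, well-separated 1-D dataset: class k occupies [2^k, 2^k + 0.2].
# Geometric spacing keeps every pairwise decision boundary clear of all
# intermediate classes, so held-out rates are exactly 0 or 1 per fold and
# the screen's outcome is derivable by hand.
separated_dataset <- function(n_classes = 3L, n_per_class = 12L) {
  x <- unlist(lapply(seq_len(n_classes), function(k) {
    2^k + seq(0, 0.2, length.out = n_per_class)
  }))
  labeled_dataset(matrix(x, ncol = 1L, dimnames = list(NULL, "x")),
                  rep(paste0("y", seq_len(n_classes)), each = n_per_class))
}

# Deterministic 1-D threshold model: predicts `second` iff x > threshold
threshold_model <- function(threshold, first, second) {
  force(threshold); force(first); force(second)
  function(features) ifelse(features[, 1L] > threshold, second, first)
}

# Independent oracle for the overall bound: flat enumeration of every
# first-class term and every chain term of the order, minimum over all.
oracle_overall_bound <- function(table, ord) {
  m <- length(ord)
  terms <- c()
  for (i in seq_len(m - 1L)) {
    terms <- c(terms, table$FC[ord[i], ord[i + 1L]])
  }
  for (i in 2:m) {
    for (k in seq_len(i - 1L)) {
      terms <- c(terms, table$SC[ord[k], ord[k + 1L], ord[i]])
    }
  }
  min(terms)
}

# Independent oracle for the fusion rule: per-sample sequential evaluation
oracle_cascade_predict <- function(features, ord, models) {
  vapply(seq_len(nrow(features)), function(s) {
    for (k in seq_along(models)) {
      p <- models[[k]](features[s, , drop = FALSE])
      if (p == ord[k]) return(ord[k])
    }
    ord[length(ord)]
  }, character(1L))
}

# Small trained pipeline shared by several tests (built once per run)
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- gen_linear(n_classes = 4L, n_per_class = 20L, sd = 0.2, seed = 1L)
      fa <- make_folds(d, repeats = 3L, folds = 4L, seed = 1L)
      tab <- train_pairwise_table(d, fa)
      cache <<- list(dataset = d, folds = fa, table = tab)
    }
    cache
  }
})
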
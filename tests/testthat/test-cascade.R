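test_that("cascade fusion follows the first-firing classifier", {
  ord <- paste0("y", 1:4)
  models <- list(threshold_model(1.5, "y1", "y2"),
                 threshold_model(2.5, "y2", "y3"),
                 threshold_model(3.5, "y3", "y4"))
  # sample at 2.2: first model passes it on, second fires
  expect_identical(predict_cascade(matrix(2.2), ord, models), "y2")
  # all models pass on -> last label of the order
  expect_identical(predict_cascade(matrix(9), ord, models), "y4")
  # verify against an independent per-sample sequential oracle on a grid
  xs <- matrix(seq(0, 5, by = 0.13), ncol = 1L)
  expect_identical(predict_cascade(xs, ord, models),
                   oracle_cascade_predict(xs, ord, models))
})

test_that("a two-class cascade is the base classifier itself", {
  mod <- threshold_model(1, "a", "b")
  xs <- matrix(c(0.2, 0.9, 1.4, 3), ncol = 1L)
  expect_identical(predict_cascade(xs, c("a", "b"), list(mod)),
                   as.character(mod(xs)))
})

test_that("missing or foreign pair models are reported by name", {
  models <- list("y1<y2" = threshold_model(1.5, "y1", "y2"))
  expect_error(predict_cascade(matrix(1), paste0("y", 1:3), models),
               "y2<y3")
  bad <- list(function(features) rep("zz", nrow(features)))
  expect_error(predict_cascade(matrix(1), c("y1", "y2"), bad), "foreign")
})

test_that("bound report composes FC and chain terms as stated", {
  m <- 4L
  FC <- matrix(1, m, m); diag(FC) <- NA
  SC <- array(1, dim = c(m, m, m))
  for (i in 1:m) for (j in 1:m) if (i != j) SC[i, j, i] <- 0
  perfect <- rate_table(paste0("y", 1:m), FC, SC)
  for (ord in list(paste0("y", 1:4), paste0("y", c(3, 1, 4, 2)))) {
    b <- bound_for_order(perfect, ord)
    expect_equal(b$overall_bound, 1)
  }
  b <- bound_for_order(perfect, paste0("y", 1:4))
  expect_true(is.na(b$fc_bound[4L]))    # last position: no first-class term
  expect_true(is.na(b$chain_bound[1L])) # first position: no predecessors
  expect_equal(unname(b$class_bound[1L]), unname(b$fc_bound[1L]))
})

test_that("overall bound equals flat enumeration of all constraint terms", {
  for (seed in 1:5) {
    tab <- random_rate_table(5L, seed = 100 + seed)
    set.seed(seed)
    for (k in 1:10) {
      ord <- sample(tab$labels)
      expect_equal(bound_for_order(tab, ord)$overall_bound,
                   oracle_overall_bound(tab, ord))
    }
    sub <- sample(tab$labels, 3L)
    expect_equal(bound_for_order(tab, sub)$overall_bound,
                 oracle_overall_bound(tab, sub))
  }
})

test_that("evaluated sensitivities match refitted fold models exactly", {
  # independent route: refit each fold's adjacent-pair SVMs and run the
  # fusion rule through predict_cascade, then average per-fold sensitivities
  fx <- pipeline_fixture()
  d <- fx$dataset; fa <- fx$folds; tab <- fx$table
  ord <- c("y2", "y1", "y3", "y4") # deliberately wrong order
  rep_direct <- local({
    sens_sum <- setNames(numeric(4L), ord); cells <- 0L
    for (r in seq_len(fa$repeats)) for (f in seq_len(fa$folds)) {
      test <- which(fa$assignment[r, ] == f)
      train <- which(fa$assignment[r, ] != f)
      models <- lapply(1:3, function(k) {
        tri <- train[d$labels[train] %in% ord[c(k, k + 1L)]]
        fit <- e1071::svm(d$features[tri, , drop = FALSE],
                          factor(d$labels[tri]), kernel = "linear",
                          cost = 1, scale = FALSE)
        function(features) as.character(predict(fit, features))
      })
      p <- oracle_cascade_predict(d$features[test, , drop = FALSE], ord, models)
      for (i in seq_along(ord)) {
        sel <- d$labels[test] == ord[i]
        sens_sum[i] <- sens_sum[i] + mean(p[sel] == ord[i])
      }
      cells <- cells + 1L
    }
    sens_sum / cells
  })
  rep_pkg <- evaluate_cascade(d, ord, fa, tab)
  expect_equal(rep_pkg$class_sensitivities, rep_direct)
  expect_equal(rep_pkg$min_sensitivity, min(rep_direct))
})

test_that("two-class cascade evaluation reproduces the pair's CV rates", {
  fx <- pipeline_fixture()
  rep2 <- evaluate_cascade(fx$dataset, c("y1", "y2"), fx$folds, fx$table)
  expect_equal(unname(rep2$class_sensitivities["y1"]),
               fx$table$FC["y1", "y2"])
  expect_equal(unname(rep2$class_sensitivities["y2"]),
               fx$table$SC["y1", "y2", "y2"])
})

test_that("an unreachable class drives the minimal sensitivity to zero", {
  # wrong order starts with y2: the (y2, y3) classifier claims everything
  # below the y2/y3 gap, so y1 samples never reach their own classifier
  d <- separated_dataset(n_classes = 3L, n_per_class = 12L)
  fa <- make_folds(d, repeats = 2L, folds = 3L, seed = 6L)
  tab <- train_pairwise_table(d, fa)
  rep_ <- evaluate_cascade(d, c("y2", "y3", "y1"), fa, tab)
  expect_equal(unname(rep_$class_sensitivities["y1"]), 0)
  expect_equal(rep_$min_sensitivity, 0)
})

test_that("cascade sensitivities never exceed their certified bounds", {
  d <- gen_linear(n_classes = 6L, n_per_class = 25L, sd = 0.6, seed = 1L)
  fa <- make_folds(d, repeats = 3L, folds = 5L, seed = 1L)
  tab <- train_pairwise_table(d, fa)
  set.seed(1)
  for (k in seq_len(100L)) {
    ord <- sample(tab$labels, sample(3:6, 1L))
    rep_ <- evaluate_cascade(d, ord, fa, tab)
    b <- rep_$bounds
    expect_true(all(rep_$class_sensitivities <= b$class_bound + 1e-12))
    expect_lte(rep_$min_sensitivity, b$overall_bound + 1e-12)
  }
})

test_that("appending a class never increases the overall bound", {
  tab <- random_rate_table(6L, seed = 31L)
  set.seed(31)
  for (k in 1:25) {
    ord <- sample(tab$labels, 6L)
    bounds <- vapply(2:6, function(l) {
      bound_for_order(tab, ord[seq_len(l)])$overall_bound
    }, numeric(1L))
    expect_true(all(diff(bounds) <= 1e-12))
  }
})

test_that("cascade predictions stay inside the order and partition the set", {
  fx <- pipeline_fixture()
  ord <- c("y1", "y3", "y4") # partial cascade, y2 foreign
  rep_ <- evaluate_cascade(fx$dataset, ord, fx$folds, fx$table)
  expect_identical(names(rep_$class_sensitivities), ord)
  models <- list(threshold_model(2, "y1", "y3"),
                 threshold_model(3.5, "y3", "y4"))
  p <- predict_cascade(fx$dataset$features, ord, models)
  expect_true(all(p %in% ord))
  fr <- vapply(ord, function(l) mean(p == l), numeric(1L))
  expect_equal(sum(fr), 1)
})
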
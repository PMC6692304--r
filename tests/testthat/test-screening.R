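test_that("a vacuous threshold keeps all m! orders", {
  tab <- random_rate_table(4L, seed = 1L)
  res <- cascades_screen(tab, 0)
  expect_equal(length(res$candidates), factorial(4))
  expect_equal(res$rejected_count, 0)
  # lexicographic emission by label-space index
  expect_identical(res$candidates[[1L]], tab$labels)
})

test_that("screen and brute force agree on random tables at all thresholds", {
  for (trial in 1:20) {
    tab <- random_rate_table(5L, seed = 200 + trial)
    # probe at every distinct rate value (tie boundaries included) plus 0, 1
    ts <- sort(unique(c(0, 1, as.vector(tab$FC)[!is.na(as.vector(tab$FC))],
                        sample(as.vector(tab$SC), 20L))))
    ts <- ts[ts >= 0 & ts <= 1]
    for (t in ts[seq(1, length(ts), length.out = 7L)]) {
      got <- cascades_screen(tab, t)
      want <- brute_force_screen(tab, t)
      expect_identical(lapply(got$candidates, as.character), want)
      expect_equal(length(got$candidates) + got$rejected_count,
                   factorial(5))
    }
  }
})

test_that("ties pass: a table with all rates at t keeps every order", {
  m <- 4L
  FC <- matrix(0.5, m, m); diag(FC) <- NA
  SC <- array(0.5, dim = c(m, m, m))
  tab <- rate_table(paste0("y", 1:m), FC, SC)
  res <- cascades_screen(tab, 0.5)
  expect_equal(length(res$candidates), factorial(m))
})

test_that("two-class screening returns both directions when rates allow", {
  FC <- matrix(c(NA, 0.9, 0.8, NA), 2L, 2L, byrow = TRUE)
  SC <- array(NA_real_, dim = c(2L, 2L, 2L))
  SC[1, 2, ] <- c(1 - FC[1, 2], 0.85)
  SC[2, 1, ] <- c(0.9, 1 - FC[2, 1])
  tab <- rate_table(c("a", "b"), FC, SC)
  res <- cascades_screen(tab, 0.5)
  expect_equal(length(res$candidates), 2L)
})

test_that("pruned subtrees are counted analytically", {
  tab <- random_rate_table(6L, seed = 77L)
  for (t in c(0.3, 0.6, 0.9)) {
    res <- cascades_screen(tab, t)
    expect_equal(length(res$candidates) + res$rejected_count, factorial(6))
    expect_equal(length(res$candidates),
                 length(brute_force_screen(tab, t)))
  }
})

test_that("candidate sets nest across the threshold grid", {
  tab <- random_rate_table(5L, seed = 55L)
  grid <- seq(1, 0.5, by = -0.05)
  prev <- NULL
  for (t in grid) {
    cur <- vapply(cascades_screen(tab, t)$candidates, order_string,
                  character(1L))
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("label-subset screening covers exactly the subset's factorial", {
  tab <- random_rate_table(5L, seed = 9L)
  sub <- tab$labels[c(2L, 4L, 5L)]
  res <- cascades_screen(tab, 0, labels = sub)
  expect_equal(res$n_orders, 6)
  expect_equal(length(res$candidates), 6L)
  expect_true(all(vapply(res$candidates, function(o) {
    setequal(o, sub)
  }, logical(1L))))
  expect_error(cascades_screen(tab, 0, labels = tab$labels[1L]), "at least 2")
  expect_error(cascades_screen(tab, 1.5), "\\[0, 1\\]")
})

test_that("cross-check keeps bound and evaluated p* side by side", {
  d <- separated_dataset(n_classes = 4L, n_per_class = 9L)
  fa <- make_folds(d, repeats = 2L, folds = 3L, seed = 3L)
  tab <- train_pairwise_table(d, fa)
  res <- cascades_screen(tab, 0.5)
  res <- cross_check(res, d, fa, tab)
  expect_s3_class(res$cross_check, "data.frame")
  expect_equal(nrow(res$cross_check), length(res$candidates))
  # dominance: evaluated p* never exceeds the certified bound
  expect_true(all(res$cross_check$min_sensitivity <=
                    res$cross_check$bound + 1e-12))
  # the perfectly separable identity order survives with bound = p* = 1
  idx <- match(order_string(tab$labels), res$cross_check$order)
  expect_false(is.na(idx))
  expect_equal(res$cross_check$bound[idx], 1)
  expect_equal(res$cross_check$min_sensitivity[idx], 1)
  expect_true(res$cross_check$pass[idx])
})

test_that("branch-and-bound maximum matches brute-force enumeration", {
  for (trial in 1:8) {
    tab <- random_rate_table(5L, seed = 300 + trial)
    perms <- ocscreen:::permutations_of(tab$labels)
    bounds <- vapply(perms, function(o) {
      bound_for_order(tab, o)$overall_bound
    }, numeric(1L))
    got <- max_cascade_bound(tab)
    expect_equal(got$max_bound, max(bounds))
    expect_equal(bound_for_order(tab, got$order)$overall_bound,
                 got$max_bound)
    # exclusion: drop every order attaining the maximum
    top <- perms[bounds == max(bounds)]
    got2 <- max_cascade_bound(tab, exclude = top)
    expect_equal(got2$max_bound, max(bounds[bounds < max(bounds)]))
  }
})

test_that("worst-case lookup formula matches term-by-term evaluation", {
  expect_equal(worst_case_lookups(2), 0)
  expect_equal(worst_case_lookups(4), 2 * choose(4, 3) + 3 * choose(4, 4))
  expect_equal(worst_case_lookups(4), 11)
  direct <- function(n) {
    tot <- 0
    for (k in 2:n) tot <- tot + k * choose(n, k + 1)
    tot
  }
  for (n in 2:12) expect_equal(worst_case_lookups(n), direct(n))
  expect_error(worst_case_lookups(1), ">= 2")
})

test_that("early stopping collapses the lookup count on separable data", {
  d <- separated_dataset(n_classes = 6L, n_per_class = 9L)
  fa <- make_folds(d, repeats = 2L, folds = 3L, seed = 8L)
  tab <- train_pairwise_table(d, fa)
  res <- cascades_screen(tab, 0.5)
  # on a geometrically spaced 1-D chain exactly the orders that take a
  # descending prefix off the top and ascend through the rest survive:
  # (1..6), (6,1..5), (6,5,1..4), ..., (6,5,4,3,2,1) — m of them, all
  # separable, so each classifies perfectly
  expect_equal(length(res$candidates), 6L)
  strs <- vapply(res$candidates, order_string, character(1L))
  want <- vapply(0:5, function(p) {
    order_string(paste0("y", c(rev(seq_len(6))[seq_len(p)],
                               seq_len(6L - p))))
  }, character(1L))
  expect_setequal(strs, want)
  expect_true(order_string(paste0("y", 1:6)) %in% strs)
  expect_true(order_string(paste0("y", 6:1)) %in% strs)
  # pruning collapses the lookup count far below the unpruned enumeration
  expect_lt(res$lookups, cascades_screen(tab, 0)$lookups / 3)
})
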
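test_that("weighted kappa handles perfect, chance and degenerate agreement", {
  expect_identical(weighted_kappa(1:5, 1:5, scale = 1:5)$kappa, 1)
  # balanced 2x2 independence: kappa 0
  expect_equal(weighted_kappa(c(1, 1, 2, 2), c(1, 2, 1, 2), scale = 1:2)$kappa,
               0)
  # both raters constant and equal: degenerate, kappa 1 by convention
  r <- weighted_kappa(rep(2, 4), rep(2, 4), scale = 1:5)
  expect_true(r$degenerate)
  expect_identical(r$kappa, 1)
  # single-category scale is the extreme degenerate case
  r2 <- weighted_kappa(c(1, 1, 1), c(1, 1, 1), scale = 1)
  expect_true(r2$degenerate)
  expect_identical(r2$kappa, 1)
  expect_error(weighted_kappa(1:3, 1:2), "length")
  expect_error(weighted_kappa(c(1, 9), c(1, 2), scale = 1:5), "scale")
})

test_that("weighted kappa equals the textbook formula on a 2x2 table", {
  # counts ((45,15),(25,15)): po = .6, pe = .6*.7 + .4*.3 = .54
  tab <- matrix(c(45, 25, 15, 15), 2)
  v <- expand_table(tab)
  expect_equal(weighted_kappa(v$ratings, v$reference, scale = 1:2)$kappa,
               (0.6 - 0.54) / (1 - 0.54), tolerance = 1e-12)
  expect_equal(weighted_kappa(v$ratings, v$reference, scale = 1:2)$kappa,
               oracle_kappa_table(tab), tolerance = 1e-12)
})

test_that("quadratic weights square the linear disagreement weights", {
  set.seed(42)
  x <- sample(1:5, 60, TRUE)
  y <- sample(1:5, 60, TRUE)
  lin <- weighted_kappa(x, y, scale = 1:5, weights = "linear")$kappa
  quad <- weighted_kappa(x, y, scale = 1:5, weights = "quadratic")$kappa
  tab <- table(factor(x, levels = 1:5), factor(y, levels = 1:5))
  expect_equal(quad, oracle_kappa_table(tab, "quadratic"), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(lin, quad)))
})

test_that("kappa is invariant under an order-preserving relabeling", {
  set.seed(7)
  x <- sample(1:5, 80, TRUE)
  y <- sample(1:5, 80, TRUE)
  k1 <- weighted_kappa(x, y, scale = 1:5)$kappa
  relab <- c(10, 20, 30, 40, 50)  # same order, equally spaced
  k2 <- weighted_kappa(relab[x], relab[y], scale = relab)$kappa
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("category merging recodes onto the partition blocks", {
  # scores (1,2) vs (2,1): both in block {1,2} -> perfect after merging
  expect_equal(merge_and_rate(c(1, 2), c(2, 1), "12|3|45", scale = 1:5)$kappa, 1)
  # identity partition reproduces the unmerged kappa
  set.seed(3)
  x <- sample(1:5, 100, TRUE)
  y <- sample(1:5, 100, TRUE)
  expect_equal(merge_and_rate(x, y, "1|2|3|4|5", scale = 1:5)$kappa,
               weighted_kappa(x, y, scale = 1:5)$kappa, tolerance = 1e-12)
  expect_error(merge_and_rate(x, y, "12|3|4", scale = 1:5), "partition")
  expect_error(merge_and_rate(x, y, "12|23|45", scale = 1:5), "partition")
})

test_that("observer gate is inclusive at the threshold", {
  g <- gate_observers(c(a = 0.61, b = 0.55, c = 1.0, d = 0.609))
  expect_setequal(g$passed, c("a", "c"))
  expect_setequal(g$failed, c("b", "d"))
  empty <- gate_observers(stats::setNames(numeric(0), character(0)))
  expect_length(empty$passed, 0)
  expect_length(empty$failed, 0)
})

test_that("kappa_by_observer gates a simulated rater panel end to end", {
  tab <- simulate_raters(6, 120, adjacent_confusion(), seed = 5)
  k <- kappa_by_observer(tab, scale = 1:5)
  expect_equal(nrow(k), 6)
  expect_true(all(k$kappa >= -1 & k$kappa <= 1))
  km <- kappa_by_observer(tab, scale = 1:5, partition = "12|3|45")
  g <- gate_observers(km)
  expect_setequal(c(g$passed, g$failed), unique(tab$observer_id))
})

test_that("Landis-Koch labels band the kappa scale", {
  expect_equal(landis_koch(c(-0.2, 0, 0.1, 0.35, 0.5, 0.61, 0.8, 0.95)),
               c("poor", "poor", "slight", "fair", "moderate", "substantial",
                 "substantial", "almost perfect"))
})
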
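test_that("weighted kappa reproduces hand-computed values", {
  # perfect agreement
  a <- c(1, 2, 3, 4, 2, 3)
  expect_equal(linear_weighted_kappa(a, a)$kappa, 1)
  # hand evaluation: po = 2/3, pe = 5/6, kappa = -1
  expect_equal(linear_weighted_kappa(c(1, 2), c(2, 1))$kappa, -1)
  # symmetry
  set.seed(1)
  x <- sample(1:4, 60, TRUE); y <- sample(1:4, 60, TRUE)
  expect_equal(linear_weighted_kappa(x, y)$kappa,
               linear_weighted_kappa(y, x)$kappa)
  # invariance under order-reversing relabelling (|i - j| preserved)
  expect_equal(linear_weighted_kappa(5 - x, 5 - y)$kappa,
               linear_weighted_kappa(x, y)$kappa)
  # identity weights reduce to unweighted Cohen's kappa
  po <- mean(x == y)
  pe <- sum(table(factor(x, 1:4)) / 60 * table(factor(y, 1:4)) / 60)
  expect_equal(linear_weighted_kappa(x, y, weights = "identity")$kappa,
               (po - pe) / (1 - pe))
  # CI brackets the point estimate
  k <- linear_weighted_kappa(x, y)
  expect_lte(k$ci95[1], k$kappa)
  expect_gte(k$ci95[2], k$kappa)
})

test_that("weighted kappa rejects malformed input and flags degeneracy", {
  expect_error(linear_weighted_kappa(1:3, 1:4), "differ in length")
  expect_error(linear_weighted_kappa(c(1, 5), c(1, 2)), "1..4")
  expect_error(linear_weighted_kappa(1, 1), "at least 2")
  d <- linear_weighted_kappa(c(1, 1, 1), c(1, 1, 1))
  expect_true(d$degenerate)
  expect_true(is.na(d$kappa))
})

test_that("ICC reproduces hand-computed ANOVA results", {
  # identical rater columns: perfect reliability in both forms
  tab <- rating_table(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(icc_single(tab, "C1")$icc, 1)
  expect_equal(icc_single(tab, "A1")$icc, 1)
  # 3 subjects x 2 raters with a constant offset: MSR = 2, MSC = 1.5,
  # MSE = 0, so ICC(C,1) = 1 and ICC(A,1) = 2 / (2 + (2/3) * 1.5) = 2/3
  off <- rating_table(matrix(c(1, 2, 3, 2, 3, 4), 3, 2))
  expect_equal(icc_single(off, "C1")$icc, 1)
  expect_equal(icc_single(off, "A1")$icc, 2 / 3)
  expect_equal(unname(icc_single(off, "A1")$ms),
               c(2, 1.5, 0))
  # constant table is degenerate
  con <- icc_single(rating_table(matrix(2, 4, 2)), "C1")
  expect_true(con$degenerate)
  # CI brackets the point estimate on a noisy table
  set.seed(2)
  tb <- rating_table(matrix(sample(1:4, 30, TRUE), 10, 3))
  for (form in c("C1", "A1")) {
    r <- icc_single(tb, form)
    expect_lte(r$ci95[1], r$icc)
    expect_gte(r$ci95[2], r$icc)
  }
  expect_error(icc_single(rating_table(cbind(1:4, 1:4))[, 1, drop = FALSE]),
               "2 raters")
})

test_that("kappa and ICC match the independent reference implementations", {
  set.seed(123)
  tables <- lapply(1:50, function(i) {
    n <- sample(15:60, 1)
    base <- sample(1:4, n, TRUE)
    wobble <- function() pmin(pmax(base + sample(-1:1, n, TRUE), 1), 4)
    cbind(a = base, b = wobble(), c = wobble())
  })
  oracle <- python_agreement_oracle(tables)
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    k <- linear_weighted_kappa(tb[, 1], tb[, 2])
    expect_equal(k$kappa, oracle$kappa[i], tolerance = 1e-6)
    expect_equal(k$se, oracle$se[i], tolerance = 1e-6)
    rt <- rating_table(tb)
    expect_equal(icc_single(rt, "C1")$icc, oracle$c1[i], tolerance = 1e-6)
    expect_equal(icc_single(rt, "A1")$icc, oracle$a1[i], tolerance = 1e-6)
  }
})

test_that("per-fold kappa reports cover all rater pairs and pool correctly", {
  set.seed(7)
  n <- 60
  tb <- rating_table(cbind(m = sample(1:4, n, TRUE),
                           s1 = sample(1:4, n, TRUE),
                           s2 = sample(1:4, n, TRUE)),
                     video_id = rep(sprintf("v%d", 1:6), each = 10))
  folds <- rep(1:3, each = 20)
  rep1 <- per_fold_kappa_report(tb, folds)
  expect_setequal(unique(rep1$fold), c("1", "2", "3", "pooled"))
  expect_equal(nrow(rep1), 3 * 4) # 3 pairs x (3 folds + pooled)
  # pooled equals a direct computation on the concatenation
  direct <- linear_weighted_kappa(tb[, "m"], tb[, "s2"])
  got <- rep1[rep1$rater_a == "m" & rep1$rater_b == "s2" &
                rep1$fold == "pooled", ]
  expect_equal(got$kappa, direct$kappa)
  # single fold: pooled result equals the per-fold result
  rep2 <- per_fold_kappa_report(tb, rep(1L, n))
  by_pair <- split(rep2, paste(rep2$rater_a, rep2$rater_b))
  for (p in by_pair) expect_equal(p$kappa[1], p$kappa[2])
  # permuting fold labels leaves the pooled value unchanged
  rep3 <- per_fold_kappa_report(tb, rep(c(3, 1, 2), each = 20))
  expect_equal(rep3[rep3$fold == "pooled", "kappa"],
               rep1[rep1$fold == "pooled", "kappa"])
  expect_error(per_fold_kappa_report(tb, c(rep(1, 59), 2)), "fewer than 2")
})

test_that("rating tables validate and read from long and wide CSV", {
  expect_error(rating_table(cbind(c(1, NA), c(1, 2))), "complete")
  expect_error(rating_table(cbind(c(0, 1), c(1, 2))), "1..4")
  expect_error(rating_table(matrix(1, 1, 2)), "at least 2")

  wide <- data.frame(frame_id = c("f1", "f2", "f3"), video_id = "v1",
                     expert1 = c(1L, 3L, 4L), expert2 = c(2L, 3L, 4L))
  wp <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, wp, row.names = FALSE)
  rw <- read_ratings(wp, "wide")
  expect_equal(unclass(rw)[, "expert1"], c(1L, 3L, 4L), ignore_attr = TRUE)

  long <- data.frame(frame_id = rep(c("f1", "f2", "f3"), 2),
                     video_id = "v1",
                     rater = rep(c("expert1", "expert2"), each = 3),
                     score = c(1L, 3L, 4L, 2L, 3L, 4L))
  lp <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, lp, row.names = FALSE)
  rl <- read_ratings(lp, "long")
  expect_equal(unname(unclass(rl)[, ]), unname(unclass(rw)[, ]))

  # named categories decode through the scale levels
  named <- data.frame(frame_id = c("f1", "f2"), video_id = "v1",
                      expert1 = c("Poor", "Excellent"),
                      expert2 = c("Fair", "Good"))
  np <- withr::local_tempfile(fileext = ".csv")
  write.csv(named, np, row.names = FALSE)
  rn <- read_ratings(np, "wide")
  expect_equal(unname(unclass(rn)[, ]), cbind(c(1L, 4L), c(2L, 3L)))
})
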
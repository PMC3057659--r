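test_that("agreement tables cross-tabulate in the fixed orientation", {
  # reconstruct a paired-rater series with known cell counts
  a <- 49; b <- 22; cc <- 26; d <- 72
  r1 <- c(rep("floating", a), rep("sunken", b), rep("floating", cc),
          rep("sunken", d))
  r2 <- c(rep("floating", a), rep("floating", b), rep("sunken", cc),
          rep("sunken", d))
  tab <- agreement_table(r1, r2)
  expect_equal(unname(tab$counts), c(49, 22, 26, 72))
  # identical raters put everything on the diagonal
  same <- agreement_table(r1, r1)
  expect_equal(unname(same$counts[c("b", "c")]), c(0, 0))
  # swapping rater order transposes the off-diagonal only
  swapped <- agreement_table(r2, r1)
  expect_equal(unname(swapped$counts), c(49, 26, 22, 72))
  expect_error(agreement_table(r1, r2[-1]), "same length")
  expect_error(agreement_table(c("floating", "mid"), c("sunken", "sunken")),
               "binary")
})

test_that("accuracy is the concordant fraction", {
  expect_equal(accuracy(agreement_counts(49, 22, 26, 72)), 121 / 169)
  expect_equal(accuracy(agreement_counts(5, 0, 0, 9)), 1)
  expect_equal(accuracy(agreement_counts(0, 4, 7, 0)), 0)
  expect_error(accuracy(agreement_counts(0, 0, 0, 0)), "empty")
})

test_that("MCC matches the closed formula and its conventions", {
  expect_equal(round(mcc(agreement_counts(49, 22, 26, 72)), 2), 0.42)
  expect_equal(mcc(agreement_counts(8, 0, 0, 11)), 1)
  # long-form arithmetic oracle for a generic table
  a <- 10; b <- 5; cc <- 3; d <- 12
  byhand <- (a * d - b * cc) /
    sqrt((a + b) * (a + cc) * (d + b) * (d + cc))
  expect_equal(mcc(agreement_counts(a, b, cc, d)), byhand)
  # zero marginal -> 0 by convention
  expect_equal(mcc(agreement_counts(0, 0, 5, 7)), 0)
})

test_that("accuracy and MCC are invariant to relabeling both raters", {
  set.seed(12)
  for (i in 1:20) {
    cnt <- sample(0:50, 4, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    t1 <- agreement_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    t2 <- agreement_counts(cnt[4], cnt[3], cnt[2], cnt[1])
    expect_equal(accuracy(t1), accuracy(t2))
    expect_equal(mcc(t1), mcc(t2))
    expect_gte(mcc(t1), -1); expect_lte(mcc(t1), 1)
  }
})

test_that("MCC equals the Pearson correlation of the binary labels", {
  set.seed(19)
  for (i in 1:15) {
    n <- sample(20:200, 1)
    x <- sample(c("floating", "sunken"), n, replace = TRUE)
    y <- ifelse(runif(n) < 0.7, x,
                sample(c("floating", "sunken"), n, replace = TRUE))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    m <- mcc(agreement_table(x, y))
    r <- cor(as.numeric(x == "sunken"), as.numeric(y == "sunken"))
    expect_equal(m, r, tolerance = 1e-12)
  }
})

test_that("pearson_r reproduces the definitional sums", {
  x <- c(0.2, 0.5, 0.9, 0.4, 0.7, 0.1, 0.6, 0.3, 0.8, 0.45)
  y <- c(0.25, 0.52, 0.8, 0.45, 0.66, 0.2, 0.55, 0.42, 0.9, 0.4)
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(pearson_r(x, y), num / den)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, n)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("the two-sample t-test behaves canonically", {
  g <- c(1.2, 3.4, 2.2, 4.1, 2.8)
  same <- welch_ttest(g, g)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  set.seed(101)
  a <- rnorm(30, 0, 1)
  b <- rnorm(30, 3, 1)     # 3 pooled SDs apart
  res <- welch_ttest(a, b)
  expect_lt(res$p_value, 0.05)
  flipped <- welch_ttest(b, a)
  expect_equal(flipped$t, -res$t)
  expect_equal(flipped$p_value, res$p_value)
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
  # pooled form agrees with stats::t.test var.equal
  ref <- t.test(a, b, var.equal = TRUE)
  pooled <- welch_ttest(a, b, var_equal = TRUE)
  expect_equal(pooled$t, unname(ref$statistic))
  expect_equal(pooled$p_value, ref$p.value)
})

test_that("well-separated groups reject in essentially every draw", {
  set.seed(55)
  rejections <- replicate(100, {
    a <- rnorm(30, 0, 1)
    b <- rnorm(30, 3, 1)
    welch_ttest(a, b)$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.99)
})
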
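test_that("the single-threshold rule assigns the boundary to floating", {
  expect_equal(classify_single(0.45, 0.45), "floating")
  expect_equal(classify_single(0.3, 0.45), "floating")
  expect_equal(classify_single(0.9, 0.45), "sunken")
  expect_equal(classify_single(c(0, 0.45, 0.450001, 1), 0.45),
               c("floating", "floating", "sunken", "sunken"))
})

test_that("the dual rule carves out a middle-depth band", {
  expect_equal(classify_dual(0.60, 0.58, 0.68), "middle_depth")
  expect_equal(classify_dual(0.58, 0.58, 0.68), "floating")
  expect_equal(classify_dual(0.68, 0.58, 0.68), "middle_depth")
  expect_equal(classify_dual(0.69, 0.58, 0.68), "sunken")
  expect_error(classify_dual(0.5, 0.7, 0.6), "must not exceed")
})

test_that("equal dual thresholds reduce exactly to the single rule", {
  cfs <- seq(0, 1, by = 0.001)
  for (c0 in c(0, 0.25, 0.5, 0.58, 1)) {
    expect_equal(classify_dual(cfs, c0, c0), classify_single(cfs, c0))
  }
})

test_that("every subject receives exactly one of the three labels", {
  set.seed(13)
  cfs <- runif(300)
  lab <- classify_dual(cfs, 0.4, 0.7)
  counts <- table(factor(lab, levels = c("floating", "sunken",
                                         "middle_depth")))
  expect_equal(sum(counts), 300L)
  expect_true(all(lab %in% c("floating", "sunken", "middle_depth")))
})

test_that("selection rate counts only decided subjects", {
  labels <- c(rep("floating", 40), rep("sunken", 47),
              rep("middle_depth", 34))
  expect_equal(selection_rate(labels), 87 / 121)
  expect_equal(selection_rate(rep("floating", 10)), 1)
  expect_equal(selection_rate(rep("middle_depth", 10)), 0)
  expect_error(selection_rate(character(0)), "non-empty")
  expect_error(selection_rate(c("floating", "deep")), "unknown")
})

test_that("single-threshold sweep matches a brute-force recount", {
  set.seed(99)
  n <- 200
  cfs <- round(runif(n), 3)
  ref <- sample(c("floating", "sunken"), n, replace = TRUE)
  sw <- sweep_single(cfs, ref, grid_step = 0.01)
  # independent naive recount at every grid threshold
  for (r in seq(1, nrow(sw), by = 7)) {
    cs <- sw$c_star[r]
    nf <- ns <- 0
    for (i in seq_len(n)) {
      pred <- if (cfs[i] <= cs) "floating" else "sunken"
      if (pred == ref[i]) {
        if (pred == "floating") nf <- nf + 1 else ns <- ns + 1
      }
    }
    expect_equal(sw$n_concordant_floating[r], nf)
    expect_equal(sw$n_concordant_sunken[r], ns)
    expect_equal(sw$accuracy[r], (nf + ns) / n)
  }
})

test_that("concordant counts are monotone in the discriminant", {
  set.seed(17)
  cfs <- runif(150)
  ref <- ifelse(cfs + rnorm(150, 0, 0.3) < 0.5, "floating", "sunken")
  sw <- sweep_single(cfs, ref)
  expect_true(all(diff(sw$n_concordant_floating) >= 0))
  expect_true(all(diff(sw$n_concordant_sunken) <= 0))
})

test_that("a self-consistent reference yields perfect accuracy and MCC", {
  set.seed(23)
  cfs <- runif(80)
  ref <- classify_single(cfs, 0.53)
  sw <- sweep_single(cfs, ref)
  row <- sw[sw$c_star == 0.53, ]
  expect_equal(row$accuracy, 1)
  expect_equal(row$mcc, 1)
})

test_that("the dual-sweep diagonal reproduces the single sweep", {
  set.seed(5)
  cfs <- runif(60)
  ref <- sample(c("floating", "sunken"), 60, replace = TRUE)
  single <- sweep_single(cfs, ref, grid_step = 0.05)
  dual <- sweep_dual(cfs, ref, grid_step = 0.05)
  diag <- dual$table[dual$table$c_f == dual$table$c_s, ]
  diag <- diag[order(diag$c_f), ]
  expect_equal(diag$n_decided, rep(60L, nrow(diag)))
  expect_equal(diag$n_concordant, single$n_concordant)
  expect_equal(diag$accuracy, single$accuracy)
})

test_that("the frontier matches exhaustive enumeration", {
  set.seed(71)
  n <- 50
  cfs <- round(runif(n), 2)
  ref <- ifelse(cfs + rnorm(n, 0, 0.25) < 0.5, "floating", "sunken")
  step <- 0.02
  res <- sweep_dual(cfs, ref, grid_step = step)
  # oracle: enumerate every pair on the same grid independently
  grid <- seq(0, 1, by = step)
  best <- new.env()
  for (cf in grid) for (cs in grid[grid >= cf]) {
    dec <- cfs <= cf | cfs > cs
    con <- sum((cfs <= cf) & ref == "floating") +
      sum((cfs > cs) & ref == "sunken")
    key <- as.character(sum(dec))
    cur <- best[[key]]
    if (is.null(cur) || con > cur) best[[key]] <- con
  }
  for (r in seq_len(nrow(res$frontier))) {
    nd <- res$frontier$n_decided[r]
    expect_equal(res$frontier$n_concordant[r], best[[as.character(nd)]])
  }
})

test_that("widening the reject band never increases decisions", {
  set.seed(8)
  cfs <- runif(100)
  center <- 0.5
  widths <- seq(0, 0.4, by = 0.05)
  n_dec <- vapply(widths, function(w) {
    sum(classify_dual(cfs, center - w, center + w) != "middle_depth")
  }, numeric(1))
  expect_true(all(diff(n_dec) <= 0))
})

test_that("sweeps are deterministic", {
  set.seed(44)
  cfs <- runif(40)
  ref <- sample(c("floating", "sunken"), 40, replace = TRUE)
  expect_identical(sweep_single(cfs, ref), sweep_single(cfs, ref))
  expect_identical(sweep_dual(cfs, ref)$table, sweep_dual(cfs, ref)$table)
})

test_that("sweeps reject non-binary references", {
  expect_error(sweep_single(c(0.1, 0.9), c("floating", "middle_depth")),
               "binary")
})

test_that("the fitted classifier object behaves like a model fit", {
  set.seed(61)
  coh <- simulate_cohort(30, 40, seed = 61)
  d <- cohort_cfs(coh)
  fit <- cfs_classifier(d$cfs, d$reference, rule = "single")
  expect_s3_class(fit, "cfs_classifier")
  th <- coef(fit)
  expect_named(th, "c_star")
  expect_equal(predict(fit, c(th - 0.001, th + 0.001)),
               c("floating", "sunken"), ignore_attr = TRUE)
  expect_equal(fitted(fit), classify_single(d$cfs, th[["c_star"]]))
  s <- summary(fit)
  expect_equal(s$selection_rate, 1)
  expect_output(print(fit), "single-threshold")

  dual <- cfs_classifier(d$cfs, d$reference, rule = "dual",
                         min_selection_rate = 0.6)
  expect_named(coef(dual), c("c_f", "c_s"))
  expect_lte(coef(dual)[["c_f"]], coef(dual)[["c_s"]])
  sd_ <- summary(dual)
  expect_gte(sd_$selection_rate, 0.6)
  # the dual fit cannot be less accurate than the best single fit
  expect_gte(sd_$accuracy, max(fit$sweep$accuracy) - 1e-12)
})
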
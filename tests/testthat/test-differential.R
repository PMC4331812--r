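test_that("detection filter keeps a feature iff some time point has all replicates", {
  v <- matrix(1, 3, 10)
  # f1: complete at 25 DAF, missing elsewhere -> kept
  v[1, 3:10] <- NA
  # f2: one replicate missing at every time point -> dropped
  v[2, seq(1, 9, by = 2)] <- NA
  x <- make_om(v, reps = 2L)
  out <- detection_filter(x)
  expect_equal(rownames(out$matrix$values), c("f01", "f03"))
  expect_equal(out$dropped, "f02")
  # no missing values -> identity
  y <- make_om(matrix(runif(20) + 1, 2), reps = 2L)
  out2 <- detection_filter(y)
  expect_identical(out2$matrix$values, y$values)
  expect_length(out2$dropped, 0L)
})

test_that("ln/median centring gives zero per-sample medians", {
  x <- make_om(matrix(c(1, exp(1), exp(2)), 3, 10, byrow = FALSE),
               reps = 2L)
  z <- ln_median_center(x)
  expect_equal(unname(z$values[, 1]), c(-1, 0, 1))
  expect_equal(z$scale, "ln_centered")
  # all-equal column -> all zeros
  y <- make_om(matrix(5, 4, 10), reps = 2L)
  expect_true(all(ln_median_center(y)$values == 0))
  # random positive matrix: per-column median exactly 0
  set.seed(3)
  w <- ln_median_center(make_om(matrix(rexp(110) + 0.1, 11), reps = 2L))
  expect_equal(unname(apply(w$values, 2, median)), rep(0, 10))
})

test_that("the time-course F statistic matches an explicit sum-of-squares decomposition", {
  # balanced 2 replicates x 3 time points, values enumerated
  y <- c(1.2, 1.9, 2.8, 3.1, 7.4, 6.9)  # order: t1r1 t1r2 t2r1 t2r2 t3r1 t3r2
  x <- make_om(matrix(y, 1), times = c(25, 35, 50), reps = 2L,
               scale = "ln_centered")
  res <- timecourse_ftest(x)

  # independent oracle: balanced two-way additive ANOVA from first principles
  ymat <- matrix(y, nrow = 2)            # rows = replicates, cols = times
  gm <- mean(y)
  ss_time <- 2 * sum((colMeans(ymat) - gm)^2)
  ss_rep <- 3 * sum((rowMeans(ymat) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - ss_time - ss_rep
  F_oracle <- (ss_time / 2) / (ss_res / 2)
  expect_equal(res$F, F_oracle)
  expect_equal(res$df_num, 2L)
  expect_equal(res$df_den, 2L)
  expect_equal(res$p, pf(F_oracle, 2, 2, lower.tail = FALSE))
})

test_that("degenerate features get p = 1 and incomplete features are fit per feature", {
  v <- rbind(rep(3, 10), rnorm(10, 5), rnorm(10, 5))
  v[3, 2] <- NA
  x <- make_om(v, reps = 2L, scale = "ln_centered")
  res <- timecourse_ftest(x)
  expect_true(res$degenerate[1])
  expect_equal(res$p[1], 1)
  # missing-cell feature agrees with a direct lm/anova fit
  ok <- !is.na(v[3, ])
  tf <- factor(x$design$time[ok]); rf <- factor(x$design$replicate[ok])
  av <- anova(lm(v[3, ok] ~ rf), lm(v[3, ok] ~ rf + tf))
  expect_equal(res$p[3], av$`Pr(>F)`[2])
})

test_that("q-values match the step-down minimum and reduce to Benjamini-Hochberg", {
  expect_equal(as.numeric(storey_q(0.05, pi0_method = "fixed_1")), 0.05)
  expect_equal(as.numeric(storey_q(c(0.01, 0.02, 0.03, 0.04),
                                   pi0_method = "fixed_1")),
               rep(0.04, 4))  # min over j >= i of m p(j) / j, by hand
  set.seed(8)
  p <- c(runif(80), runif(20)^4)
  expect_equal(as.numeric(storey_q(p, pi0_method = "fixed_1")),
               p.adjust(p, "BH"))
  # permutation invariance
  perm <- sample(length(p))
  q <- as.numeric(storey_q(p, pi0_method = "lambda_0.5"))
  expect_equal(as.numeric(storey_q(p[perm], pi0_method = "lambda_0.5")),
               q[perm])
  # pi0 estimator and clipping
  expect_equal(attr(storey_q(p, pi0_method = "lambda_0.5"), "pi0"),
               min(1, sum(p > 0.5) / (0.5 * length(p))))
  expect_lte(max(as.numeric(storey_q(runif(50)))), 1)
  expect_error(storey_q(numeric(0)), "empty")
  expect_error(storey_q(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("q-values are monotone in ranked p", {
  set.seed(21)
  for (method in c("fixed_1", "lambda_0.5", "smoother")) {
    p <- runif(200)
    q <- as.numeric(storey_q(p, pi0_method = method))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q <= 1 & q >= 0))
  }
})
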
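test_that("MRPP degenerates to p = 1 when all samples are identical", {
  x <- make_om(matrix(2, 4, 6), times = c(25, 35, 50), reps = 2L,
               scale = "ln_centered")
  res <- mrpp_test(x, c("f01", "f02"), B = 99, seed = 1)
  expect_equal(res$delta, 0)
  expect_equal(res$p, 1)
  expect_gte(res$p, 1 / (99 + 1))
})

test_that("Monte-Carlo MRPP agrees with exhaustive enumeration and vegan", {
  set.seed(10)
  v <- rbind(rnorm(6), rnorm(6), rnorm(6) + rep(c(0, 1.2), each = 3),
             rnorm(6) + rep(c(0, 1.2), each = 3))
  x <- make_om(v, times = c(25, 50), reps = 3L, scale = "ln_centered")
  res <- mrpp_test(x, rownames(x$values), B = 3999, seed = 7)
  ex <- exhaustive_mrpp_p(x$values, as.integer(factor(x$design$time)))
  expect_equal(res$delta, ex$obs)
  expect_lt(abs(res$p - ex$p), 0.03)

  skip_if_not_installed("vegan")
  ref <- vegan::mrpp(t(x$values), factor(x$design$time),
                     permutations = 999, weight.type = 1)
  expect_equal(res$delta, ref$delta)
  expect_equal(res$A, ref$A, tolerance = 1e-10)
})

test_that("MRPP rejects untestable input and catalogs gain q-values", {
  x <- make_om(matrix(rnorm(40), 4), reps = 2L, scale = "ln_centered")
  expect_error(mrpp_test(x, "f01", B = 9), "testable")
  f <- tempfile()
  writeLines(c("f01\tcA", "f02\tcA", "f03\tcB", "f04\tcB", "f09\tcC"), f)
  cat_ <- read_catalog(f, rownames(x$values))
  res <- mrpp_catalog(x, cat_, B = 99, seed = 2)
  expect_equal(res$category_id, c("cA", "cB"))  # cC not testable
  expect_true(all(res$q >= res$p * 0 & res$q <= 1))
  # determinism
  res2 <- mrpp_catalog(x, cat_, B = 99, seed = 2)
  expect_identical(res, res2)
})

test_that("over-representation p equals the hypergeometric tail by direct summation", {
  bg <- sprintf("g%03d", 1:100)
  cat10 <- bg[1:10]
  sel <- c(bg[1:5], bg[90:94])  # overlap 5
  res <- fisher_overrep(sel, cat10, bg)
  expect_equal(unlist(res[c("a", "b", "c", "d")], use.names = FALSE),
               c(5L, 5L, 5L, 85L))
  direct <- sum(sapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k) / choose(100, 10)))
  expect_equal(res$p, direct)
  # selected = background -> p = 1
  expect_equal(fisher_overrep(bg, cat10, bg)$p, 1)
  # invariance under relabeling of features
  relab <- setNames(sprintf("x%03d", 1:100), bg)
  expect_equal(fisher_overrep(unname(relab[sel]), unname(relab[cat10]),
                              unname(relab))$p, res$p)
  expect_error(fisher_overrep(c(sel, "zz"), cat10, bg), "subset")
})

test_that("class-by-cluster tests detect association and pass the no-association case", {
  # class counts exactly proportional to cluster sizes -> p = 1 under the
  # proportionality null
  assign_ <- rep(1:2, c(20, 10))
  names(assign_) <- sprintf("m%02d", 1:30)
  classes <- rep(c("AA", "ST", "AA", "ST"), c(10, 10, 5, 5))
  names(classes) <- names(assign_)
  cc <- class_by_cluster_tests(assign_, classes, B = 1000, seed = 1,
                               per_class_null = "cluster_size")
  expect_equal(cc$per_class$p, c(1, 1))
  expect_equal(cc$overall$independence_mc$p, 1)
  # the exact Fisher variant agrees with fisher.test on the 2xJ table
  cc2 <- class_by_cluster_tests(assign_, classes, per_class_null = "fisher")
  tab <- rbind(c(10, 5), c(10, 5))
  expect_equal(cc2$per_class$p[1], fisher.test(rbind(tab[1, ], c(20, 10) - tab[1, ]))$p.value)
  # degenerate inputs error
  expect_error(class_by_cluster_tests(assign_[0], classes[0]), "share no")
  expect_error(class_by_cluster_tests(assign_[1], classes[1]), "at least 2")
})

test_that("small-instance exact 2xK p-values agree with brute-force enumeration", {
  # enumerate all 2x3 tables with the observed margins; two-sided Fisher
  # p sums the probabilities of tables at most as probable as the observed
  x <- c(6, 1, 1); rest <- c(2, 5, 5)
  cc <- class_by_cluster_tests(
    setNames(rep(1:3, times = x + rest), sprintf("f%02d", 1:20)),
    setNames(rep(c("A", "B", "A", "B", "A", "B"),
                 c(x[1], rest[1], x[2], rest[2], x[3], rest[3])),
             sprintf("f%02d", 1:20)),
    per_class_null = "fisher")
  pA <- cc$per_class$p[cc$per_class$class == "A"]
  colt <- x + rest; n1 <- sum(x)
  tabs <- expand.grid(a = 0:colt[1], b = 0:colt[2])
  tabs$c <- n1 - tabs$a - tabs$b
  tabs <- tabs[tabs$c >= 0 & tabs$c <= colt[3], ]
  prob <- apply(tabs, 1, function(t3)
    prod(choose(colt, c(t3["a"], t3["b"], t3["c"]))) /
      choose(sum(colt), n1))
  obs <- prob[tabs$a == x[1] & tabs$b == x[2]]
  expect_equal(pA, sum(prob[prob <= obs * (1 + 1e-7)]))
})
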
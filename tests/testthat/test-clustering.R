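test_that("profiles are replicate-averaged, standardized, and affine-invariant", {
  v <- matrix(rep(c(1, 2, 3, 4, 5), each = 2), 1, byrow = TRUE)
  x <- make_om(v, reps = 2L, scale = "ln_centered")
  pr <- make_profiles(x)
  expect_equal(mean(pr$profiles[1, ]), 0)
  expect_equal(sd(pr$profiles[1, ]), 1)
  # affine transforms of the input leave the standardized profile unchanged
  x2 <- make_om(3.7 * v + 11, reps = 2L, scale = "ln_centered")
  expect_equal(make_profiles(x2)$profiles, pr$profiles)
  # constant profiles are flagged and excluded
  x3 <- make_om(rbind(v, 2), reps = 2L, scale = "ln_centered")
  pr3 <- make_profiles(x3)
  expect_equal(pr3$constant, "f02")
  expect_equal(rownames(pr3$profiles), "f01")
})

test_that("PAM equals the exhaustive medoid optimum on small instances", {
  set.seed(14)
  for (rep_i in 1:5) {
    P <- matrix(rnorm(16), 8, 2,
                dimnames = list(sprintf("p%d", 1:8), NULL))
    sol <- pam_kmedoids(P, K = 2, seed = rep_i, n_restarts = 3)
    D <- as.matrix(dist(P))
    pairs <- combn(8, 2)
    costs <- apply(pairs, 2, function(m) sum(pmin(D[, m[1]], D[, m[2]])))
    expect_equal(sol$cost, min(costs))
  }
})

test_that("PAM handles edge cases and well-separated clouds", {
  P <- matrix(rnorm(20), 10, 2, dimnames = list(letters[1:10], NULL))
  solN <- pam_kmedoids(P, K = 10)
  expect_equal(solN$cost, 0)
  expect_setequal(solN$medoid_ids, letters[1:10])
  expect_error(pam_kmedoids(P, K = 11), "exceeds")

  set.seed(2)
  Q <- rbind(matrix(rnorm(20, 0, 0.1), 10),
             matrix(rnorm(20, 5, 0.1), 10))
  rownames(Q) <- sprintf("q%02d", 1:20)
  sol2 <- pam_kmedoids(Q, K = 2)
  expect_equal(unname(sol2$assignment[1:10]), rep(sol2$assignment[[1]], 10))
  expect_equal(unname(sol2$assignment[11:20]), rep(sol2$assignment[[11]], 10))
  expect_false(sol2$assignment[[1]] == sol2$assignment[[11]])
})

test_that("PAM is invariant to input row order and agrees with an independent implementation", {
  skip_if_not_installed("cluster")
  set.seed(31)
  P <- matrix(rnorm(60 * 4), 60, dimnames = list(sprintf("g%02d", 1:60), NULL))
  sol <- pam_kmedoids(P, K = 4, seed = 1, n_restarts = 5)
  perm <- sample(60)
  sol_p <- pam_kmedoids(P[perm, ], K = 4, seed = 1, n_restarts = 5)
  expect_identical(sol$medoid_ids, sol_p$medoid_ids)
  expect_identical(sol$assignment[sort(names(sol$assignment))],
                   sol_p$assignment[sort(names(sol_p$assignment))])
  # independent route: cluster::pam on the same data should not beat us
  ref <- cluster::pam(dist(P), k = 4)
  D <- as.matrix(dist(P))
  ref_cost <- sum(D[cbind(seq_len(60), ref$id.med[ref$clustering])])
  expect_lte(sol$cost, ref_cost + 1e-8)
})

test_that("the Krzanowski-Lai table matches a hand evaluation on a 1-d dataset", {
  # three tight groups on a line; W_K computable by hand
  pts <- c(0, 1, 10, 11, 30, 31)
  P <- matrix(pts, 6, 1, dimnames = list(sprintf("x%d", 1:6), NULL))
  kl <- krzanowski_lai(P, K_range = 2:4, seed = 1, n_restarts = 2)
  # exhaustive W for each K: best medoid set by total |distance|
  D <- as.matrix(dist(P))
  bestW <- function(K) {
    sets <- combn(6, K)
    costs <- apply(sets, 2, function(m)
      sum(apply(D[, m, drop = FALSE], 1, min)))
    m <- sets[, which.min(costs)]
    sum(apply(D[, m, drop = FALSE], 1, min)^2)
  }
  W <- vapply(1:4, bestW, 0)
  expect_equal(kl$table$W, W[2:4])
  DIFF <- c(NA, sapply(2:4, function(K)
    (K - 1)^(2 / 1) * W[K - 1] - K^(2 / 1) * W[K]))
  expect_equal(kl$table$DIFF, DIFF[2:4])
  expect_equal(kl$table$KL[kl$table$K == 2], abs(DIFF[2]) / abs(DIFF[3]))
  expect_equal(kl$table$KL[kl$table$K == 3], abs(DIFF[3]) / abs(DIFF[4]))
  expect_equal(kl$chosen_K, 3L)  # three planted groups
})

test_that("W is non-increasing in K and tight planted structure is chosen", {
  set.seed(5)
  P <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2),
             matrix(rnorm(30, 4, 0.2), 15, 2),
             cbind(rnorm(15, 0, 0.2), rnorm(15, 8, 0.2)))
  rownames(P) <- sprintf("f%02d", 1:45)
  kl <- krzanowski_lai(P, K_range = 2:6, seed = 2, n_restarts = 5)
  expect_equal(kl$chosen_K, 3L)
  expect_true(all(diff(kl$table$W) <= 1e-9))
})
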
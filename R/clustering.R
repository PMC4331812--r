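#' Standardized temporal profiles
#'
#' Replicates are averaged within each time point, then each feature's
#' profile is standardized to mean 0 and sd 1 across time points, so that
#' clustering groups features by the *shape* of their trajectory, not its
#' level or amplitude. Constant profiles cannot be standardized; they are
#' excluded and reported.
#'
#' @param x an [omics_matrix()] (normally `ln_centered`).
#' @param features optional subset of feature ids (e.g. the differential set).
#' @return A list: `profiles` (features x time-points matrix of standardized
#'   means, row names = feature ids, column names = time values), `constant`
#'   (ids of excluded constant profiles), `times`.
#' @export
make_profiles <- function(x, features = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  features <- features %||% rownames(x$values)
  missing <- setdiff(features, rownames(x$values))
  if (length(missing))
    stop_("feature(s) not in matrix: %s", paste(missing, collapse = ", "))
  tp <- sort(unique(x$design$time))
  grp <- factor(x$design$time, levels = tp)
  v <- x$values[features, , drop = FALSE]
  means <- sapply(levels(grp), function(g)
    rowMeans(v[, grp == g, drop = FALSE], na.rm = TRUE))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(features, levels(grp)))
  sds <- apply(means, 1L, stats::sd)
  const <- !is.finite(sds) | sds < .Machine$double.eps^0.5
  prof <- (means - rowMeans(means)) / sds
  list(profiles = prof[!const, , drop = FALSE],
       constant = features[const],
       times = tp)
}

# ---- PAM (K-medoids) ------------------------------------------------------

# BUILD phase on a distance matrix: greedy selection of K initial medoids.
pam_build <- function(D, K) {
  n <- nrow(D)
  med <- which.min(colSums(D))
  dnear <- D[, med]
  while (length(med) < K) {
    # gain of adding candidate j: total reduction in nearest-medoid distance
    gain <- colSums(pmax(dnear - D, 0))
    gain[med] <- -Inf
    j <- which.max(gain)
    med <- c(med, j)
    dnear <- pmin(dnear, D[, j])
  }
  sort(med)
}

# Row-wise minimum over a set of columns of D, vectorized.
rowmin_cols <- function(D, cols) {
  if (length(cols) == 1L) return(D[, cols])
  do.call(pmin, lapply(cols, function(j) D[, j]))
}

# SWAP phase: steepest-descent swaps of a medoid for a non-medoid until no
# swap reduces the total cost. Candidates are scanned in fixed row order, so
# the result is deterministic for a given start.
pam_swap <- function(D, med) {
  n <- nrow(D)
  repeat {
    cost <- sum(rowmin_cols(D, med))
    best <- list(cost = cost)
    cand <- setdiff(seq_len(n), med)
    for (mi in seq_along(med)) {
      others <- med[-mi]
      drest <- if (length(others)) rowmin_cols(D, others) else rep(Inf, n)
      cand_cost <- colSums(pmin(D[, cand, drop = FALSE], drest))
      j <- which.min(cand_cost)
      if (cand_cost[j] < best$cost - 1e-12) {
        best <- list(cost = cand_cost[j], mi = mi, h = cand[j])
      }
    }
    if (is.null(best$mi)) break
    med[best$mi] <- best$h
    med <- sort(med)
  }
  med
}

#' K-medoids (PAM) clustering of temporal profiles
#'
#' Partitioning around medoids with Euclidean distance: a deterministic
#' BUILD initialisation refined by steepest-descent SWAP, plus
#' `n_restarts - 1` random restarts; the solution with the lowest total
#' distance-to-medoid cost wins. Feature order does not matter: rows are
#' processed in lexicographic feature-id order and ties break toward the
#' lexicographically smaller id.
#'
#' @param profiles numeric matrix (features x dimensions) with feature ids
#'   as row names, e.g. `make_profiles(x)$profiles`.
#' @param K number of clusters, `2 <= K <= nrow(profiles)`.
#' @param seed integer seed driving the random restarts.
#' @param n_restarts number of starts (first is the deterministic BUILD).
#' @return An object of class `cluster_solution`: list with `K`,
#'   `medoid_ids`, `assignment` (named integer vector, clusters numbered by
#'   medoid id order), `cost` (total Euclidean distance to medoids), and
#'   `W` (total *squared* distance to medoids, the within-cluster
#'   dispersion used by [krzanowski_lai()]).
#' @export
pam_kmedoids <- function(profiles, K, seed = 1L, n_restarts = 10L) {
  if (is.null(rownames(profiles))) stop_("profiles must have row names")
  n <- nrow(profiles)
  if (K > n) stop_("K = %d exceeds number of profiles (%d)", K, n)
  if (K < 1L) stop_("K must be >= 1")
  ord <- order(rownames(profiles))
  profiles <- profiles[ord, , drop = FALSE]
  D <- as.matrix(stats::dist(profiles))
  if (K == n) {
    med <- seq_len(n)
  } else {
    starts <- list(pam_build(D, K))
    if (n_restarts > 1L && K < n) {
      rand <- with_seed(seed, lapply(seq_len(n_restarts - 1L),
                                     function(i) sort(sample.int(n, K))))
      starts <- c(starts, rand)
    }
    sols <- lapply(starts, function(s) if (K > 1L) pam_swap(D, s) else {
      # K = 1: the medoid minimizing total distance
      which.min(colSums(D))
    })
    costs <- vapply(sols, function(m)
      sum(apply(D[, m, drop = FALSE], 1L, min)), 0)
    med <- sols[[which.min(costs)]]
  }
  Dm <- D[, med, drop = FALSE]
  assign_idx <- max.col(-Dm, ties.method = "first")
  cost <- sum(Dm[cbind(seq_len(n), assign_idx)])
  W <- sum(Dm[cbind(seq_len(n), assign_idx)]^2)
  assignment <- stats::setNames(assign_idx, rownames(profiles))
  structure(list(K = K, medoid_ids = rownames(profiles)[med],
                 assignment = assignment, cost = cost, W = W),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: K = %d, cost = %.4f, W = %.4f\n",
              x$K, x$cost, x$W))
  cat("sizes:", paste(tabulate(x$assignment, x$K), collapse = ", "), "\n")
  cat("medoids:", paste(x$medoid_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Krzanowski-Lai selection of the cluster number
#'
#' For each K in `K_range`, profiles are clustered with [pam_kmedoids()] and
#' the within-cluster dispersion `W_K` (total squared Euclidean distance of
#' members to their medoid) is recorded. With `d` the profile dimension,
#' `DIFF(K) = (K-1)^(2/d) W_(K-1) - K^(2/d) W_K` and
#' `KL(K) = |DIFF(K)| / |DIFF(K+1)|`; the chosen K maximizes KL over the K
#' for which both terms exist, with ties broken toward smaller K. `W_1`
#' (needed for `DIFF` at the lower end) is always computed.
#'
#' @inheritParams pam_kmedoids
#' @param K_range integer vector of candidate K (within `[2, n - 1]`).
#' @return An object of class `kl_selection`: list with `table`
#'   (`data.frame` of K, W, DIFF, KL), `chosen_K`, and `solutions` (the
#'   `cluster_solution` per K, named by K).
#' @export
krzanowski_lai <- function(profiles, K_range = 2:8, seed = 1L, n_restarts = 10L) {
  n <- nrow(profiles)
  K_range <- sort(unique(as.integer(K_range)))
  if (min(K_range) < 2L || max(K_range) > n - 1L)
    stop_("K_range must lie within [2, n-1]")
  if (length(K_range) < 2L)
    stop_("K_range too small to evaluate the criterion")
  d <- ncol(profiles)
  Ks <- c(min(K_range) - 1L, K_range)   # include K-1 for the first DIFF
  sols <- lapply(Ks, function(K)
    pam_kmedoids(profiles, K, seed = substream_seed(seed, paste0("K", K)),
                 n_restarts = n_restarts))
  names(sols) <- Ks
  W <- vapply(sols, `[[`, 0, "W")
  DIFF <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)[-1]) {
    DIFF[i] <- (Ks[i] - 1L)^(2 / d) * W[i - 1L] - Ks[i]^(2 / d) * W[i]
  }
  KL <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)) {
    if (!is.na(DIFF[i]) && i < length(Ks) && !is.na(DIFF[i + 1L]))
      KL[i] <- abs(DIFF[i]) / abs(DIFF[i + 1L])
  }
  tab <- data.frame(K = Ks, W = unname(W), DIFF = DIFF, KL = KL)
  evaluable <- which(!is.na(KL))
  if (!length(evaluable)) stop_("K_range too small to evaluate any KL value")
  chosen <- Ks[evaluable[which.max(KL[evaluable])]]  # which.max: first max, smaller K
  structure(list(table = tab[tab$K %in% K_range, ], chosen_K = chosen,
                 solutions = sols[as.character(K_range)]),
            class = "kl_selection")
}

#' @export
print.kl_selection <- function(x, ...) {
  cat("Krzanowski-Lai cluster-number selection\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("chosen K:", x$chosen_K, "\n")
  invisible(x)
}
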
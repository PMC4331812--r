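#' Multiresponse permutation procedure (MRPP) for a feature category
#'
#' Tests whether the joint abundance distribution of a category's member
#' features (a metabolic pathway or GO term) changed over the time course.
#' Each sample is the vector of the category's member values; groups are the
#' time points. The observed statistic is the group-size-weighted mean of
#' within-group pairwise Euclidean distances,
#' `delta = sum_g (n_g / N) * mean(D within group g)`; the null distribution
#' is obtained by permuting the sample-to-group labels while preserving
#' group sizes, and `p = (1 + #\{delta_perm <= delta_obs\}) / (B + 1)`, so p
#' has resolution `1/(B+1)` and never equals 0. The chance-corrected
#' within-group agreement `A = 1 - delta / E(delta)` (with `E(delta)` the
#' mean over all pairwise distances) is reported informationally.
#'
#' Distances are computed on the normalized (ln, median-centred) values
#' without per-feature standardization, since the test targets change in
#' accumulation, which standardization would erase.
#'
#' @param x an `ln_centered` [omics_matrix()].
#' @param members character vector of member feature ids (>= 2 measured).
#' @param B number of permutations.
#' @param seed integer seed for the permutations.
#' @return A list: `delta`, `A`, `p`, `m` (measured member count), `B`.
#' @export
mrpp_test <- function(x, members, B = 10000L, seed = 1L) {
  stopifnot(inherits(x, "omics_matrix"))
  members <- intersect(members, rownames(x$values))
  if (length(members) < 2L)
    stop_("category not testable: fewer than 2 measured members")
  grp <- factor(x$design$time)
  if (nlevels(grp) < 2L) stop_("need >= 2 time points (groups)")
  D <- as.matrix(stats::dist(t(x$values[members, , drop = FALSE])))
  N <- ncol(D)
  sizes <- tabulate(grp)
  w <- sizes / N
  delta_of <- function(labels) {
    s <- 0
    for (g in seq_len(nlevels(grp))) {
      idx <- which(labels == g)
      if (length(idx) > 1L)
        s <- s + w[g] * mean(D[idx, idx][lower.tri(diag(length(idx)))])
    }
    s
  }
  obs <- delta_of(as.integer(grp))
  perm <- with_seed(seed, vapply(seq_len(B), function(b)
    delta_of(sample(as.integer(grp))), 0))
  p <- (1 + sum(perm <= obs + 1e-12)) / (B + 1)
  e_delta <- mean(D[lower.tri(D)])
  A <- if (e_delta > 0) 1 - obs / e_delta else 0
  list(delta = obs, A = A, p = p, m = length(members), B = B)
}

#' MRPP over a category catalog, with FDR
#'
#' Runs [mrpp_test()] for every testable category and converts the p-values
#' to Storey q-values.
#'
#' @param x an `ln_centered` [omics_matrix()].
#' @param catalog a `category_catalog` (see [read_catalog()]).
#' @param B permutations per category.
#' @param seed master seed; each category gets its own substream.
#' @param pi0_method passed to [storey_q()].
#' @return A `data.frame`: `category_id`, `m`, `delta`, `A`, `p`, `q`, `B`.
#' @export
mrpp_catalog <- function(x, catalog, B = 10000L, seed = 1L,
                         pi0_method = "lambda_0.5") {
  cats <- catalog[catalog$testable, , drop = FALSE]
  if (nrow(cats) == 0L) stop_("no testable categories")
  res <- lapply(seq_len(nrow(cats)), function(i)
    mrpp_test(x, cats$members[[i]], B = B,
              seed = substream_seed(seed, cats$category_id[i])))
  out <- data.frame(category_id = cats$category_id,
                    m = vapply(res, `[[`, 0L, "m"),
                    delta = vapply(res, `[[`, 0, "delta"),
                    A = vapply(res, `[[`, 0, "A"),
                    p = vapply(res, `[[`, 0, "p"),
                    B = B, stringsAsFactors = FALSE)
  category_fdr(out, pi0_method = pi0_method)
}

#' Attach Storey q-values to category test results
#'
#' @param results `data.frame` with a `p` column.
#' @param pi0_method passed to [storey_q()].
#' @return `results` with a `q` column.
#' @export
category_fdr <- function(results, pi0_method = "lambda_0.5") {
  results$q <- as.numeric(storey_q(results$p, pi0_method = pi0_method))
  results
}

#' Fisher exact over-representation of one category
#'
#' One-sided hypergeometric upper-tail test for whether a selected feature
#' list contains more members of a category than expected when drawing from
#' the background. The odds ratio uses a 0.5 continuity substitution on zero
#' cells, for reporting only.
#'
#' @param selected character vector, a subset of `background`.
#' @param members the category's member feature ids.
#' @param background the measured feature universe.
#' @return A one-row `data.frame`: counts `a` (selected, in category),
#'   `b` (selected, out), `c` (unselected, in), `d` (unselected, out),
#'   `odds_ratio`, `p`.
#' @export
fisher_overrep <- function(selected, members, background) {
  selected <- unique(selected); background <- unique(background)
  if (length(setdiff(selected, background)))
    stop_("selected features must be a subset of the background")
  cat_bg <- intersect(members, background)
  a <- length(intersect(selected, cat_bg))
  b <- length(selected) - a
  c_ <- length(cat_bg) - a
  d <- length(background) - a - b - c_
  p <- stats::phyper(a - 1L, length(cat_bg),
                     length(background) - length(cat_bg),
                     length(selected), lower.tail = FALSE)
  cc <- c(a, b, c_, d)
  if (any(cc == 0)) cc <- cc + 0.5
  data.frame(a = a, b = b, c = c_, d = d,
             odds_ratio = (cc[1] * cc[4]) / (cc[2] * cc[3]),
             p = p)
}

#' Fisher over-representation over a catalog
#'
#' @param selected selected feature ids (subset of `background`).
#' @param catalog a `category_catalog`.
#' @param background measured feature universe.
#' @param min_measured minimum measured members for a category to be tested.
#' @return `data.frame` with one row per tested category, ordered by p.
#' @export
fisher_overrep_catalog <- function(selected, catalog, background,
                                   min_measured = 2L) {
  keep <- vapply(catalog$members, function(m)
    length(intersect(m, background)) >= min_measured, TRUE)
  cats <- catalog[keep, , drop = FALSE]
  if (nrow(cats) == 0L) stop_("no testable categories against this background")
  rows <- lapply(cats$members, fisher_overrep, selected = selected,
                 background = background)
  out <- cbind(data.frame(category_id = cats$category_id,
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  out[order(out$p, out$category_id), ]
}

#' Chemical-class by cluster distribution tests
#'
#' Given a cluster assignment and a chemical-class annotation for the same
#' features, builds the class-by-cluster contingency table and runs three
#' test families:
#' \describe{
#'   \item{per class}{is the class evenly distributed over the clusters? A
#'     Pearson chi-square goodness-of-fit of the class's counts across
#'     clusters against a uniform null (`per_class_null = "uniform"`,
#'     asymptotic, df = J - 1); `"cluster_size"` tests proportionality to
#'     cluster sizes instead, and `"fisher"` runs the exact conditional test
#'     on the 2 x J class-versus-rest table.}
#'   \item{per cluster}{does the cluster's class composition differ from the
#'     remaining features? Pearson chi-square on the 2 x I cluster-versus-
#'     rest table with a Monte-Carlo p-value
#'     (`p = (1 + #more-extreme) / (B + 1)`); `"fisher"` uses the exact
#'     conditional test instead.}
#'   \item{overall}{a uniform goodness-of-fit on the cluster totals, plus a
#'     Monte-Carlo chi-square test of class-cluster independence on the full
#'     I x J table.}
#' }
#'
#' @param assignment named vector, feature -> cluster.
#' @param classes named vector, feature -> chemical class; names must match
#'   `assignment`.
#' @param B Monte-Carlo replicates.
#' @param seed integer seed for the Monte-Carlo tests.
#' @param per_class_null `"uniform"`, `"cluster_size"`, or `"fisher"`.
#' @param per_cluster_method `"chisq_mc"` or `"fisher"`.
#' @return An object of class `class_cluster_tests`: list with `table`
#'   (I x J counts), `per_class`, `per_cluster` (`data.frame`s), `overall`.
#' @export
class_by_cluster_tests <- function(assignment, classes, B = 100000L, seed = 1L,
                                   per_class_null = c("uniform", "cluster_size",
                                                      "fisher"),
                                   per_cluster_method = c("chisq_mc", "fisher")) {
  per_class_null <- match.arg(per_class_null)
  per_cluster_method <- match.arg(per_cluster_method)
  feats <- intersect(names(assignment), names(classes))
  if (!length(feats)) stop_("assignment and classes share no features")
  tab <- table(class = factor(classes[feats]),
               cluster = factor(assignment[feats]))
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop_("need at least 2 classes and 2 clusters")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_("class or cluster with zero total")
  cl_tot <- colSums(tab)
  J <- ncol(tab)

  per_class <- do.call(rbind, lapply(rownames(tab), function(cls) {
    xrow <- as.integer(tab[cls, ])
    if (per_class_null == "fisher") {
      p <- stats::fisher.test(rbind(xrow, cl_tot - xrow),
                              workspace = 2e7)$p.value
      data.frame(class = cls, n = sum(xrow), statistic = NA_real_,
                 df = NA_integer_, p = p, method = "fisher_exact",
                 stringsAsFactors = FALSE)
    } else {
      p0 <- if (per_class_null == "uniform") rep(1 / J, J) else cl_tot / sum(cl_tot)
      ct <- suppressWarnings(stats::chisq.test(xrow, p = p0))
      data.frame(class = cls, n = sum(xrow),
                 statistic = unname(ct$statistic), df = J - 1L,
                 p = ct$p.value, method = paste0("chisq_gof_", per_class_null),
                 stringsAsFactors = FALSE)
    }
  }))

  per_cluster <- do.call(rbind, lapply(colnames(tab), function(cl) {
    xcol <- as.integer(tab[, cl])
    rest <- as.integer(rowSums(tab)) - xcol
    t2 <- rbind(xcol, rest)
    if (per_cluster_method == "fisher") {
      p <- stats::fisher.test(t2, workspace = 2e7)$p.value
      data.frame(cluster = cl, n = sum(xcol), statistic = NA_real_,
                 p = p, method = "fisher_exact", B = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      ct <- with_seed(substream_seed(seed, paste0("cluster_", cl)),
        suppressWarnings(stats::chisq.test(t2, simulate.p.value = TRUE, B = B)))
      data.frame(cluster = cl, n = sum(xcol),
                 statistic = unname(ct$statistic),
                 p = ct$p.value, method = "chisq_monte_carlo", B = B,
                 stringsAsFactors = FALSE)
    }
  }))

  ov_gof <- suppressWarnings(stats::chisq.test(as.integer(cl_tot),
                                               p = rep(1 / J, J)))
  ov_ind <- with_seed(substream_seed(seed, "overall"),
    suppressWarnings(stats::chisq.test(tab, simulate.p.value = TRUE, B = B)))
  structure(list(table = tab,
                 per_class = per_class,
                 per_cluster = per_cluster,
                 overall = list(
                   uniform_gof = list(statistic = unname(ov_gof$statistic),
                                      df = J - 1L, p = ov_gof$p.value),
                   independence_mc = list(statistic = unname(ov_ind$statistic),
                                          p = ov_ind$p.value, B = B))),
            class = "class_cluster_tests")
}

#' @export
print.class_cluster_tests <- function(x, ...) {
  cat("class-by-cluster distribution tests\n\ncounts:\n")
  print(x$table)
  cat("\nper class (evenness over clusters):\n")
  print(x$per_class, row.names = FALSE, digits = 3)
  cat("\nper cluster (composition vs rest):\n")
  print(x$per_cluster, row.names = FALSE, digits = 3)
  cat(sprintf("\noverall: uniform GOF p = %.3g; independence (MC) p = %.3g\n",
              x$overall$uniform_gof$p, x$overall$independence_mc$p))
  invisible(x)
}
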
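#' Volcano comparison of two time points
#'
#' For every feature, a two-sample t-test (Welch by default) between the
#' replicate values at two time points, with the fold change reported as the
#' difference of group means on the ln scale (`group2 - group1`). Features
#' with zero variance in both groups and equal means get `p = 1` (degenerate
#' convention). q-values come from [storey_q()].
#'
#' @param x an `ln_centered` [omics_matrix()].
#' @param group1,group2 time-point values present in the design (>= 2
#'   replicates each).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param pi0_method passed to [storey_q()].
#' @return A `data.frame`: `feature_id`, `log_fc`, `t`, `df`, `p`, `q`.
#' @export
volcano <- function(x, group1, group2, var_equal = FALSE,
                    pi0_method = "lambda_0.5") {
  stopifnot(inherits(x, "omics_matrix"))
  i1 <- which(x$design$time == group1)
  i2 <- which(x$design$time == group2)
  if (length(i1) < 2L || length(i2) < 2L)
    stop_("both time points need >= 2 replicates")
  res <- t(apply(x$values, 1L, function(v) {
    a <- v[i1][!is.na(v[i1])]; b <- v[i2][!is.na(v[i2])]
    if (length(a) < 2L || length(b) < 2L) return(c(NA, NA, NA, NA))
    lfc <- mean(b) - mean(a)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (lfc == 0) return(c(0, 0, length(a) + length(b) - 2, 1))
      return(c(lfc, Inf, length(a) + length(b) - 2, 0))
    }
    tt <- stats::t.test(b, a, var.equal = var_equal)
    c(lfc, unname(tt$statistic), unname(tt$parameter), tt$p.value)
  }))
  out <- data.frame(feature_id = rownames(x$values),
                    log_fc = res[, 1], t = res[, 2], df = res[, 3],
                    p = res[, 4], stringsAsFactors = FALSE)
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- as.numeric(storey_q(out$p[ok], pi0_method = pi0_method))
  out
}

#' Correlate a query profile against all features of a matrix
#'
#' Pearson correlation between a query feature's time-point mean profile and
#' every target feature's, over the shared time points, with the two-sided
#' p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' With `level = "replicate"` the correlation is computed over matched
#' replicate samples instead of time-point means (both platforms must then
#' share the sample layout).
#'
#' @param query either a feature id present in `query_matrix`, or a named
#'   numeric vector of per-time-point means (names = time values).
#' @param targets the target [omics_matrix()] (typically transcripts).
#' @param query_matrix the matrix holding the query feature (defaults to
#'   `targets`, for within-platform co-analysis).
#' @param level `"time_means"` (default) or `"replicate"`.
#' @return A `data.frame` (`target_id`, `r`, `n`, `p`, `flagged`) sorted by
#'   decreasing `|r|`; zero-variance targets have `NA` correlation and are
#'   flagged.
#' @export
correlate_query <- function(query, targets, query_matrix = targets,
                            level = c("time_means", "replicate")) {
  stopifnot(inherits(targets, "omics_matrix"))
  level <- match.arg(level)
  tp <- sort(unique(targets$design$time))
  if (is.character(query)) {
    if (!query %in% rownames(query_matrix$values))
      stop_("query feature %s not found", query)
    qv <- query_matrix$values[query, ]
    qprof <- tapply(qv, factor(query_matrix$design$time), mean, na.rm = TRUE)
  } else {
    qprof <- query
  }
  shared <- intersect(names(qprof), as.character(tp))
  if (length(shared) < 3L) stop_("need >= 3 shared time points")
  if (level == "time_means") {
    grp <- factor(targets$design$time)
    tm <- sapply(levels(grp), function(g)
      rowMeans(targets$values[, grp == g, drop = FALSE], na.rm = TRUE))
    if (is.null(dim(tm)))
      tm <- matrix(tm, nrow = 1, dimnames = list(rownames(targets$values),
                                                 levels(grp)))
    M <- tm[, shared, drop = FALSE]
    qq <- as.numeric(qprof[shared])
  } else {
    if (!is.character(query)) stop_("replicate-level needs a query feature id")
    key_t <- paste(targets$design$time, targets$design$replicate)
    key_q <- paste(query_matrix$design$time, query_matrix$design$replicate)
    shared_s <- intersect(key_q, key_t)
    if (length(shared_s) < 3L) stop_("need >= 3 matched samples")
    M <- targets$values[, match(shared_s, key_t), drop = FALSE]
    qq <- as.numeric(query_matrix$values[query, match(shared_s, key_q)])
  }
  n <- length(qq)
  r <- suppressWarnings(as.numeric(stats::cor(qq, t(M),
                                              use = "pairwise.complete.obs")))
  flagged <- !is.finite(r)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!flagged & abs(r) >= 1] <- 0
  out <- data.frame(target_id = rownames(M), r = r, n = n, p = p,
                    flagged = flagged, stringsAsFactors = FALSE)
  out[order(-abs(out$r), out$target_id), ]
}

#' Over-representation among correlated features
#'
#' Selects the targets whose correlation with the query falls in `r_band`
#' with `p < p_max`, then tests every catalog category for over-representation
#' of the selection against the full target background with
#' [fisher_overrep_catalog()].
#'
#' @param records output of [correlate_query()].
#' @param r_band length-2 numeric, inclusive correlation band (e.g.
#'   `c(0.9, 1)`).
#' @param p_max correlation p-value cutoff.
#' @param catalog a `category_catalog`.
#' @return A `data.frame` as from [fisher_overrep_catalog()], with the
#'   selection size as attribute `n_selected`; zero selected features yields
#'   an empty result with a warning.
#' @export
correlated_set_overrep <- function(records, r_band, p_max, catalog) {
  stopifnot(length(r_band) == 2L)
  sel <- records$target_id[!records$flagged &
                             records$r >= r_band[1] & records$r <= r_band[2] &
                             records$p < p_max]
  background <- records$target_id
  if (!length(sel)) {
    warning("no features in the requested correlation band", call. = FALSE)
    out <- data.frame(category_id = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      odds_ratio = numeric(0), p = numeric(0))
    attr(out, "n_selected") <- 0L
    return(out)
  }
  out <- fisher_overrep_catalog(sel, catalog, background)
  attr(out, "n_selected") <- length(sel)
  out
}
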
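#' Detection filter
#'
#' Keeps a feature only if there is at least one time point at which all of
#' its replicates are present (above the detection limit, i.e. non-missing
#' and positive). Cells below detection are `NA`.
#'
#' @param x a raw [omics_matrix()].
#' @return A list: `matrix` (the filtered `omics_matrix`) and `dropped`
#'   (character vector of removed feature ids).
#' @export
detection_filter <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$scale != "raw") stop_("detection_filter expects a raw-scale matrix")
  grp <- factor(x$design$time)
  present <- !is.na(x$values) & x$values > 0
  # per feature, per time point: all replicates present?
  all_present <- vapply(levels(grp), function(g) {
    cols <- which(grp == g)
    rowSums(present[, cols, drop = FALSE]) == length(cols)
  }, logical(nrow(x$values)))
  keep <- rowSums(all_present) >= 1L
  dropped <- rownames(x$values)[!keep]
  list(matrix = omics_matrix(x$values[keep, , drop = FALSE], x$design, "raw"),
       dropped = dropped)
}

#' Natural-log transform and per-sample median centring
#'
#' Each value is replaced by its natural log minus the median over features
#' of the logged values in the same sample ("chip"), so the per-sample median
#' of the transformed values is 0. Below-detection cells stay missing and are
#' excluded from the medians.
#'
#' @param x a raw [omics_matrix()] with strictly positive present values.
#' @return An [omics_matrix()] on the `"ln_centered"` scale.
#' @export
ln_median_center <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$scale != "raw") stop_("matrix is already transformed")
  if (any(x$values <= 0, na.rm = TRUE)) stop_("non-positive value in raw matrix")
  ln <- log(x$values)
  med <- apply(ln, 2L, stats::median, na.rm = TRUE)
  out <- sweep(ln, 2L, med, "-")
  structure(list(values = out, design = x$design, scale = "ln_centered"),
            class = "omics_matrix")
}

#' Per-feature time-course F-test
#'
#' For each feature, fits the linear model `value ~ replicate + time` with
#' both terms categorical (replicate as a block effect) and performs the
#' overall F-test for dropping the time term, i.e. for any change in mean
#' abundance across time points. Features with zero residual degrees of
#' freedom or constant values get `p = 1` and are flagged degenerate, so
#' downstream set operations stay total.
#'
#' @param x an `ln_centered` [omics_matrix()] (any scale is accepted; the
#'   test is scale-invariant up to the model assumptions).
#' @return A `data.frame`: `feature_id`, `F`, `df_num`, `df_den`, `p`,
#'   `degenerate`.
#' @export
timecourse_ftest <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  d <- x$design
  if (length(unique(d$time)) < 2L) stop_("need >= 2 time points")
  time_f <- factor(d$time)
  rep_f <- factor(d$replicate)
  use_rep <- nlevels(rep_f) > 1L
  X_full <- if (use_rep) stats::model.matrix(~ rep_f + time_f)
            else stats::model.matrix(~ time_f)
  X_red <- if (use_rep) stats::model.matrix(~ rep_f)
           else stats::model.matrix(~ 1)
  df_num <- nlevels(time_f) - 1L
  df_den <- nrow(X_full) - qr(X_full)$rank
  Y <- t(x$values)
  n_feat <- ncol(Y)
  F_stat <- rep(NA_real_, n_feat)
  p <- rep(NA_real_, n_feat)
  degen <- logical(n_feat)
  complete <- !apply(Y, 2L, anyNA)
  if (any(complete) && df_den > 0L) {
    qf <- qr(X_full); qr_ <- qr(X_red)
    rss_full <- colSums(qr.resid(qf, Y[, complete, drop = FALSE])^2)
    rss_red <- colSums(qr.resid(qr_, Y[, complete, drop = FALSE])^2)
    Fs <- ((rss_red - rss_full) / df_num) / (rss_full / df_den)
    F_stat[complete] <- Fs
    p[complete] <- stats::pf(Fs, df_num, df_den, lower.tail = FALSE)
  }
  # features with missing cells: per-feature fit on available samples
  for (j in which(!complete)) {
    ok <- !is.na(Y[, j])
    if (sum(ok) < 2L || length(unique(d$time[ok])) < 2L) next
    tf <- factor(d$time[ok]); rf <- factor(d$replicate[ok])
    full <- if (nlevels(rf) > 1L) stats::lm(Y[ok, j] ~ rf + tf)
            else stats::lm(Y[ok, j] ~ tf)
    red <- if (nlevels(rf) > 1L) stats::lm(Y[ok, j] ~ rf)
           else stats::lm(Y[ok, j] ~ 1)
    av <- stats::anova(red, full)
    if (av$Res.Df[2] > 0 && is.finite(av$F[2])) {
      F_stat[j] <- av$F[2]
      p[j] <- av$`Pr(>F)`[2]
    }
  }
  # degenerate: constant response or no residual df
  const <- apply(Y, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || max(v) - min(v) < .Machine$double.eps^0.5 * (1 + abs(max(v)))
  })
  degen <- const | !is.finite(p)
  p[degen] <- 1
  F_stat[degen | !is.finite(F_stat)] <- 0
  data.frame(feature_id = rownames(x$values), F = F_stat,
             df_num = df_num, df_den = df_den, p = p,
             degenerate = degen, stringsAsFactors = FALSE)
}

#' Storey q-values
#'
#' Converts p-values to q-values controlling the false discovery rate. With
#' order statistics `p(1) <= ... <= p(m)`,
#' `q(i) = min over j >= i of pi0 * m * p(j) / j`, clipped to 1. The null
#' proportion `pi0` is 1 for `pi0_method = "fixed_1"` (then the q-values are
#' exactly Benjamini-Hochberg adjusted p-values),
#' `#\{p > 0.5\} / (0.5 m)` clipped to `(0, 1]` for `"lambda_0.5"`, or a
#' natural-spline smoother over a lambda grid extrapolated to 1 for
#' `"smoother"`.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param pi0_method one of `"lambda_0.5"`, `"fixed_1"`, `"smoother"`.
#' @return Numeric q-values in the input order, with attribute `pi0`.
#' @examples
#' storey_q(c(0.01, 0.02, 0.03, 0.04), pi0_method = "fixed_1")
#' @export
storey_q <- function(p, pi0_method = c("lambda_0.5", "fixed_1", "smoother")) {
  pi0_method <- match.arg(pi0_method)
  if (length(p) == 0L) stop_("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop_("p-values must be in [0, 1]")
  m <- length(p)
  pi0 <- switch(pi0_method,
    fixed_1 = 1,
    lambda_0.5 = sum(p > 0.5) / (0.5 * m),
    smoother = {
      lam <- seq(0.05, 0.9, by = 0.05)
      est <- vapply(lam, function(l) sum(p > l) / ((1 - l) * m), 0)
      fit <- stats::smooth.spline(lam, est, df = 3)
      stats::predict(fit, x = 1)$y
    })
  pi0 <- min(1, max(pi0, 1 / m))
  ord <- order(p)
  q_sorted <- pi0 * m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

#' Differential time-course analysis
#'
#' Convenience wrapper: detection filter (raw input only), ln/median-centre,
#' per-feature F-test, Storey q-values.
#'
#' @param x an [omics_matrix()] on either scale.
#' @param pi0_method passed to [storey_q()].
#' @return A `data.frame` as from [timecourse_ftest()] plus columns `q` and
#'   `passed_detection`.
#' @export
differential_analysis <- function(x, pi0_method = "lambda_0.5") {
  stopifnot(inherits(x, "omics_matrix"))
  dropped <- character(0)
  if (x$scale == "raw") {
    flt <- detection_filter(x)
    dropped <- flt$dropped
    x <- ln_median_center(flt$matrix)
  }
  res <- timecourse_ftest(x)
  res$q <- as.numeric(storey_q(res$p, pi0_method = pi0_method))
  res$passed_detection <- TRUE
  if (length(dropped)) {
    extra <- data.frame(feature_id = dropped, F = 0,
                        df_num = res$df_num[1] %||% NA_integer_,
                        df_den = res$df_den[1] %||% NA_integer_,
                        p = NA_real_, degenerate = NA, q = NA_real_,
                        passed_detection = FALSE, stringsAsFactors = FALSE)
    res <- rbind(res, extra)
  }
  res
}
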
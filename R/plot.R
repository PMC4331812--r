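#' Plot standardized cluster profiles
#'
#' One panel per cluster: member profiles in grey, the medoid highlighted in
#' red -- the standard way to display temporal co-accumulation clusters.
#'
#' @param profiles matrix as from [make_profiles()]`$profiles`.
#' @param solution a `cluster_solution` from [pam_kmedoids()].
#' @param times numeric time values for the x axis (default: column names).
#' @return Invisibly, `NULL`.
#' @export
plot_cluster_profiles <- function(profiles, solution, times = NULL) {
  times <- times %||% as.numeric(colnames(profiles))
  K <- solution$K
  old <- graphics::par(mfrow = grDevices::n2mfrow(K), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (k in seq_len(K)) {
    ids <- names(solution$assignment)[solution$assignment == k]
    graphics::matplot(times, t(profiles[ids, , drop = FALSE]), type = "l",
                      lty = 1, col = grDevices::grey(0.75),
                      xlab = "", ylab = "", main = sprintf("cluster %d (n=%d)",
                                                           k, length(ids)))
    med <- solution$medoid_ids[k]
    graphics::lines(times, profiles[med, ], col = "red", lwd = 2)
  }
  invisible(NULL)
}

#' Volcano plot
#'
#' Significance against ln fold change for a two-time-point comparison.
#'
#' @param records `data.frame` from [volcano()].
#' @param q_cutoff points with `q` below this are highlighted.
#' @return Invisibly, `NULL`.
#' @export
plot_volcano <- function(records, q_cutoff = 0.05) {
  sig <- !is.na(records$q) & records$q < q_cutoff
  graphics::plot(records$log_fc, -log10(pmax(records$p, 1e-300)),
                 pch = 20, col = ifelse(sig, "red", "grey50"),
                 xlab = "ln fold change", ylab = "-log10 p")
  graphics::abline(v = 0, lty = 2)
  invisible(NULL)
}
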
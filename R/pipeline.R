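#' Pipeline configuration
#'
#' Bundles every threshold and input the end-to-end analysis needs. By
#' default the pipeline runs on synthetic data from [simulate_timecourse()];
#' supply `inputs` (a list of file paths: `metab`, `metab_design`, `trans`,
#' `trans_design`, optionally `catalog`, `classes`, `promoters`, `motifs`,
#' `clusters`) to run on real tables instead.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; every stage draws from a named substream of it.
#' @param sim a [sim_spec()] used when no `inputs` are given.
#' @param q_metab,q_trans q-value cutoffs defining the differential sets
#'   (defaults 0.05 for metabolites, 0.01 for transcripts).
#' @param K_range_metab,K_range_trans candidate cluster numbers.
#' @param n_restarts PAM restarts.
#' @param kl_max_features cap on profiles used for the Krzanowski-Lai scan
#'   (a seeded subsample; the final clustering at the chosen K uses all
#'   features).
#' @param mrpp_B,class_B permutation / Monte-Carlo replicates.
#' @param n_categories,enriched_fraction synthetic catalog settings.
#' @param volcano_pair two time points to compare.
#' @param r_band,p_max correlation band and p cutoff for co-analysis.
#' @param planted_rate,background_rate synthetic promoter settings.
#' @param inputs optional list of input file paths (see above).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, sim = sim_spec(seed = seed),
                       q_metab = 0.05, q_trans = 0.01,
                       K_range_metab = 2:8, K_range_trans = 2:10,
                       n_restarts = 10L, kl_max_features = 800L,
                       mrpp_B = 1000L, class_B = 100000L,
                       n_categories = 20L, enriched_fraction = 0.5,
                       volcano_pair = c(25, 50),
                       r_band = c(0.9, 1), p_max = 0.05,
                       planted_rate = 0.5, background_rate = 0.05,
                       inputs = NULL) {
  stopifnot(q_metab >= 0, q_metab <= 1, q_trans >= 0, q_trans <= 1,
            all(r_band >= -1), all(r_band <= 1), length(volcano_pair) == 2L)
  structure(as.list(environment()), class = "run_config")
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  message(sprintf("[seedfill] %-12s %6.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- data (simulate or load),
#' detection filter + normalisation, per-feature time-course differential
#' tests, profile clustering with automatic K selection, category statistics
#' (MRPP, Fisher over-representation, class-by-cluster tests), volcano and
#' correlation co-analysis, and promoter motif enrichment -- writing each
#' stage's tables as TSV plus a machine-readable JSON run summary. The run
#' is idempotent: the same config and seed give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return The run summary (also written to `summary.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  summary <- list(seed = config$seed)

  # ---- data ---------------------------------------------------------------
  truth <- NULL
  if (is.null(config$inputs)) {
    sim <- stage("simulate", simulate_timecourse(config$sim))
    metab_raw <- sim$metab; trans_raw <- sim$trans; truth <- sim$truth
    classes <- truth$metab$class
    catalog <- simulate_catalogs(truth, config$n_categories,
                                 config$enriched_fraction, platform = "trans")
    motifs <- read_motifs(system.file("extdata", "motifs.tsv",
                                      package = "seedfill"))
    promoters <- simulate_promoters(truth, motifs,
                                    planted_rate = config$planted_rate,
                                    background_rate = config$background_rate)
    write_matrix(metab_raw, out("metab_raw.tsv"), out("metab_design.tsv"))
    write_matrix(trans_raw, out("trans_raw.tsv"), out("trans_design.tsv"))
  } else {
    inp <- config$inputs
    metab_raw <- stage("load", read_matrix(inp$metab, inp$metab_design))
    trans_raw <- read_matrix(inp$trans, inp$trans_design)
    classes <- if (!is.null(inp$classes)) {
      cd <- read_tsv_file(inp$classes)
      stats::setNames(cd$chemical_class, cd$feature_id)
    } else NULL
    catalog <- if (!is.null(inp$catalog))
      read_catalog(inp$catalog, feature_ids(trans_raw)) else NULL
    motifs <- if (!is.null(inp$motifs)) read_motifs(inp$motifs) else NULL
    promoters <- if (!is.null(inp$promoters)) read_promoters(inp$promoters)
                 else NULL
  }

  # ---- differential -------------------------------------------------------
  diff2 <- stage("differential", {
    lapply(list(metab = metab_raw, trans = trans_raw), differential_analysis)
  })
  for (pl in names(diff2)) write_tsv_file(diff2[[pl]], out(paste0("diff_", pl, ".tsv")))
  flt_m <- detection_filter(metab_raw)
  metab <- ln_median_center(flt_m$matrix)
  trans <- ln_median_center(detection_filter(trans_raw)$matrix)
  sig_metab <- diff2$metab$feature_id[!is.na(diff2$metab$q) &
                                        diff2$metab$q < config$q_metab]
  sig_trans <- diff2$trans$feature_id[!is.na(diff2$trans$q) &
                                        diff2$trans$q < config$q_trans]
  summary$differential <- list(
    metab_detected = nrow(metab$values), metab_dropped = length(flt_m$dropped),
    metab_sig = length(sig_metab), q_metab = config$q_metab,
    trans_sig = length(sig_trans), q_trans = config$q_trans)

  # ---- clustering ---------------------------------------------------------
  clus <- stage("clustering", {
    res <- list()
    specs <- list(metab = list(x = metab, feats = feature_ids(metab),
                               Ks = config$K_range_metab),
                  trans = list(x = trans, feats = sig_trans,
                               Ks = config$K_range_trans))
    for (pl in names(specs)) {
      s <- specs[[pl]]
      if (length(s$feats) < max(s$Ks) + 2L) { res[[pl]] <- NULL; next }
      prof <- make_profiles(s$x, s$feats)
      kl_prof <- prof$profiles
      if (nrow(kl_prof) > config$kl_max_features) {
        idx <- with_seed(substream_seed(config$seed, paste0("klsub_", pl)),
                         sort(sample.int(nrow(kl_prof), config$kl_max_features)))
        kl_prof <- kl_prof[idx, , drop = FALSE]
      }
      kl <- krzanowski_lai(kl_prof, s$Ks,
                           seed = substream_seed(config$seed, paste0("kl_", pl)),
                           n_restarts = config$n_restarts)
      sol <- pam_kmedoids(prof$profiles, kl$chosen_K,
                          seed = substream_seed(config$seed, paste0("pam_", pl)),
                          n_restarts = config$n_restarts)
      write_tsv_file(kl$table, out(paste0("kl_", pl, ".tsv")))
      write_tsv_file(data.frame(feature_id = names(sol$assignment),
                                cluster = unname(sol$assignment),
                                medoid = names(sol$assignment) %in% sol$medoid_ids),
                     out(paste0("clusters_", pl, ".tsv")))
      res[[pl]] <- list(profiles = prof, kl = kl, solution = sol)
    }
    res
  })
  summary$clustering <- lapply(clus, function(cl) list(
    chosen_K = cl$kl$chosen_K, n_clustered = length(cl$solution$assignment),
    medoids = cl$solution$medoid_ids))

  # ---- category statistics ------------------------------------------------
  if (!is.null(catalog)) {
    cat_res <- stage("categories", {
      mr <- mrpp_catalog(trans, catalog, B = config$mrpp_B,
                         seed = substream_seed(config$seed, "mrpp"))
      fr <- fisher_overrep_catalog(sig_trans, catalog, feature_ids(trans))
      list(mrpp = mr, fisher = fr)
    })
    write_tsv_file(cat_res$mrpp, out("mrpp.tsv"))
    write_tsv_file(cat_res$fisher, out("fisher_overrep.tsv"))
    summary$categories <- list(
      mrpp_sig_q05 = sum(cat_res$mrpp$q < 0.05),
      fisher_sig_p05 = sum(cat_res$fisher$p < 0.05))
  }
  if (!is.null(classes) && !is.null(clus$metab)) {
    cc <- stage("class_dist",
                class_by_cluster_tests(clus$metab$solution$assignment, classes,
                                       B = config$class_B,
                                       seed = substream_seed(config$seed, "classdist")))
    write_tsv_file(cc$per_class, out("class_by_cluster_per_class.tsv"))
    write_tsv_file(cc$per_cluster, out("class_by_cluster_per_cluster.tsv"))
    summary$class_dist <- list(
      per_class_sig = sum(cc$per_class$p < 0.05),
      overall_uniform_p = cc$overall$uniform_gof$p,
      overall_independence_p = cc$overall$independence_mc$p)
  }

  # ---- co-analysis --------------------------------------------------------
  coa <- stage("coanalysis", {
    vol <- volcano(metab, config$volcano_pair[1], config$volcano_pair[2])
    qid <- feature_ids(metab)[1]
    rec <- correlate_query(qid, targets = trans, query_matrix = metab)
    ov <- if (!is.null(catalog))
      tryCatch(correlated_set_overrep(rec, config$r_band, config$p_max, catalog),
               warning = function(w) NULL) else NULL
    list(volcano = vol, correlations = rec, overrep = ov, query = qid)
  })
  write_tsv_file(coa$volcano, out("volcano.tsv"))
  write_tsv_file(coa$correlations, out("correlations.tsv"))
  summary$coanalysis <- list(
    volcano_sig_q05 = sum(coa$volcano$q < 0.05, na.rm = TRUE),
    query = coa$query,
    n_correlated = sum(!coa$correlations$flagged &
                         coa$correlations$r >= config$r_band[1] &
                         coa$correlations$r <= config$r_band[2] &
                         coa$correlations$p < config$p_max))

  # ---- motifs -------------------------------------------------------------
  if (!is.null(promoters) && !is.null(motifs)) {
    clmap <- if (!is.null(clus$trans)) clus$trans$solution$assignment
             else if (!is.null(config$inputs$clusters)) {
               cd <- read_tsv_file(config$inputs$clusters)
               stats::setNames(cd$cluster, cd$feature_id)
             } else NULL
    if (!is.null(clmap)) {
      mo <- stage("motifs", {
        hits <- scan_motifs(promoters, motifs)
        clmap <- clmap[names(clmap) %in% names(promoters)]
        motif_cluster_enrichment(hits, clmap, background = names(promoters))
      })
      write_tsv_file(mo, out("motif_enrichment.tsv"))
      summary$motifs <- list(n_tests = nrow(mo), sig_p05 = sum(mo$significant))
    }
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}
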
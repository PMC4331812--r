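#' Simulation settings for a synthetic seed-fill study
#'
#' Defaults emulate the shape of a developmental seed-fill profiling study:
#' five harvests at 25, 30, 35, 45 and 50 days after flowering; 273 metabolite
#' analytes in 6 replicates falling into 8 chemical classes
#' (31 AA, 7 AR, 12 eFA, 12 fFA, 15 OA, 41 SGD, 30 ST, 125 UK);
#' 2,869 differentially expressed transcripts in 2 replicates, with optional
#' additional flat (null) transcripts up to chip scale; 5 planted metabolite
#' clusters and 8 planted transcript clusters.
#'
#' Abundances are log-normal: on the natural-log scale a feature is its
#' baseline plus a standardized temporal template scaled by `effect_scale`,
#' plus a per-replicate offset (Normal with sd `noise_sd / 2`) and i.i.d.
#' Normal noise with sd `noise_sd`. Null features have a flat template.
#'
#' @param seed integer master seed; all draws derive from it.
#' @param times numeric time-point values (DAF).
#' @param n_rep_metab,n_rep_trans replicates per time point per platform.
#' @param n_metab,n_trans number of metabolite analytes / clustered transcripts.
#' @param n_trans_null additional flat transcripts, up to chip scale
#'   (37,593 probes in total); the default simulates the differential
#'   transcripts only. With a two-replicate design the per-feature F-test
#'   has little power at stringent q cutoffs once tens of thousands of null
#'   probes dominate the FDR estimate, so chip-scale universes are mainly
#'   useful for null-calibration studies.
#' @param class_counts named integer vector of metabolite chemical-class
#'   sizes; must sum to `n_metab`.
#' @param k_metab,k_trans planted cluster counts (>= 2).
#' @param noise_sd residual sd on the ln scale (> 0).
#' @param effect_scale amplitude of the standardized temporal templates.
#' @param frac_null fraction of the `n_metab` and `n_trans` features replaced
#'   by flat profiles (used for null calibration).
#' @param baseline_mean,baseline_sd ln-scale baseline abundance distribution.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L,
                     times = c(25, 30, 35, 45, 50),
                     n_rep_metab = 6L, n_rep_trans = 2L,
                     n_metab = 273L, n_trans = 2869L, n_trans_null = 0L,
                     class_counts = c(AA = 31L, AR = 7L, eFA = 12L, fFA = 12L,
                                      OA = 15L, SGD = 41L, ST = 30L, UK = 125L),
                     k_metab = 5L, k_trans = 8L,
                     noise_sd = 0.25, effect_scale = 1,
                     frac_null = 0,
                     baseline_mean = 6, baseline_sd = 1) {
  if (!is_count(seed, min = 0L)) stop_("seed must be a non-negative integer")
  if (length(times) < 2L || anyDuplicated(times)) stop_("need >= 2 distinct time points")
  if (sum(class_counts) != n_metab)
    stop_("class_counts sums to %d, not n_metab = %d", sum(class_counts), n_metab)
  if (k_metab < 2L || k_trans < 2L) stop_("planted cluster counts must be >= 2")
  if (noise_sd <= 0) stop_("noise_sd must be > 0")
  if (frac_null < 0 || frac_null > 1) stop_("frac_null must be in [0, 1]")
  structure(list(seed = as.integer(seed), times = sort(as.numeric(times)),
                 n_rep_metab = as.integer(n_rep_metab),
                 n_rep_trans = as.integer(n_rep_trans),
                 n_metab = as.integer(n_metab), n_trans = as.integer(n_trans),
                 n_trans_null = as.integer(n_trans_null),
                 class_counts = class_counts,
                 k_metab = as.integer(k_metab), k_trans = as.integer(k_trans),
                 noise_sd = noise_sd, effect_scale = effect_scale,
                 frac_null = frac_null,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "sim_spec")
}

# Deterministic bank of temporal shape families, evaluated at the design's
# day values and standardized to mean 0 / sd 1 across time points. The
# families mirror the profile classes seen in seed-fill data: steady rise,
# steady fall, late rise, mid-development peak, early decline to a basal
# level, early rise to a plateau, a mid-development trough, and a late fall.
template_bank <- function(times, k) {
  u <- (times - min(times)) / diff(range(times))
  shapes <- list(
    up         = function(u) u,
    down       = function(u) 1 - u,
    late_rise  = function(u) plogis((u - 0.75) * 12),
    mid_peak   = function(u) exp(-((u - 0.55) / 0.22)^2),
    early_fall = function(u) exp(-u / 0.25),
    early_rise = function(u) pmin(1, u / 0.35),
    trough     = function(u) abs(u - 0.45),
    late_fall  = function(u) plogis((0.7 - u) * 12)
  )
  if (k > length(shapes))
    stop_("at most %d planted clusters supported", length(shapes))
  t(vapply(shapes[seq_len(k)], function(f) {
    v <- f(u)
    (v - mean(v)) / stats::sd(v)
  }, numeric(length(u))))
}

simulate_platform <- function(prefix, n, n_null_extra, n_rep, k, spec) {
  times <- spec$times
  tmpl <- template_bank(times, k)
  n_tot <- n + n_null_extra
  ids <- sprintf("%s%0*d", prefix, nchar(as.character(n_tot)) + 1L, seq_len(n_tot))
  # planted assignment: clusters filled round-robin so sizes are near-equal,
  # then frac_null of the first n features (plus all extras) made flat
  cluster <- c(rep_len(seq_len(k), n), rep(NA_integer_, n_null_extra))
  is_null <- c(seq_len(n) <= round(spec$frac_null * n), rep(TRUE, n_null_extra))
  cluster[is_null] <- NA_integer_
  names(cluster) <- names(is_null) <- ids

  n_t <- length(times)
  sample_id <- as.vector(t(outer(times, seq_len(n_rep),
                                 function(t, r) sprintf("%s_%g_r%d", prefix, t, r))))
  design <- sample_design(sample_id,
                          time = rep(times, each = n_rep),
                          replicate = rep(seq_len(n_rep), times = n_t))
  baseline <- stats::rnorm(n_tot, spec$baseline_mean, spec$baseline_sd)
  rep_off <- stats::rnorm(n_rep, 0, spec$noise_sd / 2)
  prof <- matrix(0, n_tot, n_t)
  keep <- !is.na(cluster)
  prof[keep, ] <- tmpl[cluster[keep], , drop = FALSE] * spec$effect_scale
  # ln-scale values: baseline + template + replicate offset + noise
  ln <- prof[, rep(seq_len(n_t), each = n_rep), drop = FALSE] + baseline
  ln <- sweep(ln, 2L, rep(rep_off, times = n_t), "+")
  ln <- ln + matrix(stats::rnorm(n_tot * n_t * n_rep, 0, spec$noise_sd), n_tot)
  vals <- exp(ln)
  dimnames(vals) <- list(ids, design$sample_id)
  list(matrix = omics_matrix(vals, design, scale = "raw"),
       cluster = cluster, is_null = is_null, templates = tmpl)
}

#' Simulate a two-platform seed-fill time course with known ground truth
#'
#' Generates a metabolite matrix and a transcript matrix over the same time
#' course (replicate structure per platform), with features drawn from
#' planted temporal clusters; see [sim_spec()] for the generative model.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @return A list with elements `metab` and `trans` (raw [omics_matrix()]
#'   objects) and `truth`, a list holding per-platform planted cluster
#'   assignments (`NA` for null features), null flags, the standardized
#'   templates, and the metabolite chemical-class annotation.
#' @export
simulate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  metab <- with_seed(substream_seed(spec$seed, "metab"),
                     simulate_platform("M", spec$n_metab, 0L,
                                       spec$n_rep_metab, spec$k_metab, spec))
  trans <- with_seed(substream_seed(spec$seed, "trans"),
                     simulate_platform("T", spec$n_trans, spec$n_trans_null,
                                       spec$n_rep_trans, spec$k_trans, spec))
  classes <- rep(names(spec$class_counts), spec$class_counts)
  names(classes) <- feature_ids(metab$matrix)
  truth <- list(times = spec$times,
                k_metab = spec$k_metab, k_trans = spec$k_trans,
                metab = list(cluster = metab$cluster, is_null = metab$is_null,
                             templates = metab$templates, class = classes),
                trans = list(cluster = trans$cluster, is_null = trans$is_null,
                             templates = trans$templates),
                spec = spec)
  list(metab = metab$matrix, trans = trans$matrix, truth = truth)
}

#' Simulate category catalogs with planted enrichment
#'
#' Enriched categories draw at least 80% (by construction 90%) of their
#' members from one planted cluster; background categories sample features
#' uniformly. All categories have at least 2 members.
#'
#' @param truth ground truth from [simulate_timecourse()].
#' @param n_categories number of categories.
#' @param enriched_fraction fraction of categories planted as enriched.
#' @param platform `"trans"` or `"metab"`: which feature universe.
#' @param size_range inclusive range of category sizes.
#' @param seed integer seed (default: derived from the simulation seed).
#' @return A `category_catalog` (see [read_catalog()]) with extra truth
#'   columns `enriched` and `target_cluster`.
#' @export
simulate_catalogs <- function(truth, n_categories = 20L, enriched_fraction = 0.5,
                              platform = c("trans", "metab"),
                              size_range = c(6L, 15L), seed = NULL) {
  platform <- match.arg(platform)
  pt <- truth[[platform]]
  feats <- names(pt$cluster)
  k <- if (platform == "trans") truth$k_trans else truth$k_metab
  seed <- seed %||% substream_seed(truth$spec$seed, paste0("catalogs_", platform))
  n_enr <- round(n_categories * enriched_fraction)
  with_seed(seed, {
    members <- vector("list", n_categories)
    target <- rep(NA_integer_, n_categories)
    for (i in seq_len(n_categories)) {
      size <- max(2L, sample(size_range[1]:size_range[2], 1L))
      if (i <= n_enr) {
        tc <- ((i - 1L) %% k) + 1L
        target[i] <- tc
        in_cl <- feats[!is.na(pt$cluster) & pt$cluster == tc]
        n_in <- min(length(in_cl), max(2L, ceiling(0.9 * size)))
        members[[i]] <- c(sample(in_cl, n_in),
                          sample(setdiff(feats, in_cl), size - n_in))
      } else {
        members[[i]] <- sample(feats, size)
      }
    }
    names(members) <- sprintf("CAT%03d", seq_len(n_categories))
    cat <- build_catalog(members,
                         kind = stats::setNames(rep("pathway", n_categories),
                                                names(members)),
                         measured_ids = feats)
    cat$enriched <- cat$category_id %in% names(members)[seq_len(n_enr)]
    cat$target_cluster <- target[match(cat$category_id, names(members))]
    cat
  })
}

# Draw one concrete realization of an IUPAC motif.
realize_iupac <- function(iupac) {
  paste(vapply(strsplit(iupac, "")[[1]], function(code) {
    letters <- strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
    if (length(letters) == 1L) letters else sample(letters, 1L)
  }, ""), collapse = "")
}

#' Simulate promoters with planted cis-element motifs
#'
#' Each gene receives a promoter of i.i.d. uniform A/C/G/T of length `len`.
#' Genes in a motif's target cluster additionally receive one planted exact
#' instance of the motif with probability `planted_rate`; all other genes
#' with probability `background_rate`. Chance background matches of course
#' still occur and must be found by scanning, not assumed absent.
#'
#' @param truth ground truth from [simulate_timecourse()].
#' @param motifs `data.frame` with `motif_name`, `iupac` (see [read_motifs()]).
#' @param motif_targets integer vector (recycled) of target transcript
#'   clusters, one per motif; default cycles over clusters.
#' @param planted_rate,background_rate planting probabilities, with
#'   `planted_rate > background_rate`.
#' @param genes genes to build promoters for; default all clustered transcripts.
#' @param len promoter length (nt).
#' @param seed integer seed (default derived from the simulation seed).
#' @return A named [Biostrings::DNAStringSet] with attribute `truth`: a
#'   `data.frame` (`gene_id`, `motif_name`, `planted`).
#' @export
simulate_promoters <- function(truth, motifs, motif_targets = NULL,
                               planted_rate = 0.5, background_rate = 0.05,
                               genes = NULL, len = 1000L, seed = NULL) {
  if (planted_rate <= background_rate)
    stop_("planted_rate must exceed background_rate")
  if (any(nchar(motifs$iupac) > len)) stop_("motif longer than promoter")
  genes <- genes %||% names(truth$trans$cluster)[!is.na(truth$trans$cluster)]
  motif_targets <- rep_len(motif_targets %||% seq_len(truth$k_trans),
                           nrow(motifs))
  seed <- seed %||% substream_seed(truth$spec$seed, "promoters")
  with_seed(seed, {
    seqm <- matrix(sample(c("A", "C", "G", "T"), length(genes) * len,
                          replace = TRUE), nrow = length(genes))
    plant_log <- list()
    for (j in seq_len(nrow(motifs))) {
      w <- nchar(motifs$iupac[j])
      in_target <- truth$trans$cluster[genes] == motif_targets[j] &
        !is.na(truth$trans$cluster[genes])
      rate <- ifelse(in_target, planted_rate, background_rate)
      planted <- stats::runif(length(genes)) < rate
      for (i in which(planted)) {
        pos <- sample.int(len - w + 1L, 1L)
        seqm[i, pos:(pos + w - 1L)] <- strsplit(realize_iupac(motifs$iupac[j]), "")[[1]]
      }
      plant_log[[j]] <- data.frame(gene_id = genes,
                                   motif_name = motifs$motif_name[j],
                                   planted = planted,
                                   stringsAsFactors = FALSE)
    }
    seqs <- Biostrings::DNAStringSet(apply(seqm, 1L, paste, collapse = ""))
    names(seqs) <- genes
    attr(seqs, "truth") <- do.call(rbind, plant_log)
    seqs
  })
}

#' Plant exact metabolite-transcript correlations
#'
#' For each requested pair, the transcript's ln-scale time-point mean profile
#' is rebuilt as a blend of the metabolite's mean profile and an orthogonal
#' residual so that the realized Pearson correlation over time-point means
#' equals `target_r` exactly; within-time-point replicate deviations are
#' preserved (recentred), so replicate structure and variance are kept.
#'
#' @param metab,trans raw [omics_matrix()] objects from [simulate_timecourse()].
#' @param pairs `data.frame` with columns `metab_id`, `trans_id`, `target_r`.
#' @param seed integer seed for the residual direction.
#' @return `trans` with the listed transcripts rewritten.
#' @export
plant_correlation <- function(metab, trans, pairs, seed = 1L) {
  stopifnot(inherits(metab, "omics_matrix"), inherits(trans, "omics_matrix"))
  tp <- sort(unique(trans$design$time))
  if (!identical(tp, sort(unique(metab$design$time))))
    stop_("platforms must share time points")
  vals <- trans$values
  with_seed(seed, {
    for (i in seq_len(nrow(pairs))) {
      r <- pairs$target_r[i]
      if (abs(r) > 1) stop_("target_r must be in [-1, 1]")
      m_ln <- log(metab$values[pairs$metab_id[i], ])
      q <- tapply(m_ln, metab$design$time, mean)[as.character(tp)]
      t_ln <- log(vals[pairs$trans_id[i], ])
      grp <- factor(trans$design$time, levels = tp)
      old_means <- tapply(t_ln, grp, mean)
      qs <- (q - mean(q)) / stats::sd(q)
      z <- stats::rnorm(length(tp))
      z <- stats::residuals(stats::lm(z ~ qs))
      z <- z / stats::sd(z)
      new_means <- mean(old_means) +
        stats::sd(old_means) * (r * qs + sqrt(max(0, 1 - r^2)) * z)
      shift <- (new_means - old_means)[as.integer(grp)]
      vals[pairs$trans_id[i], ] <- exp(t_ln + shift)
    }
  })
  omics_matrix(vals, trans$design, scale = "raw")
}
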
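# IUPAC codes resolved to base sets once (from Biostrings).
iupac_regex <- function(iupac) {
  codes <- strsplit(iupac, "")[[1]]
  paste(vapply(codes, function(cd) {
    b <- Biostrings::IUPAC_CODE_MAP[[cd]]
    if (is.null(b)) stop_("invalid IUPAC code: %s", cd)
    if (nchar(b) == 1L) b else paste0("[", b, "]")
  }, ""), collapse = "")
}

# Count matches of an IUPAC pattern in one strand of every sequence, with
# the contract that an N in the *sequence* matches nothing. Biostrings
# treats a pattern N as compatible with a subject N, so matches whose window
# overlaps an N are discarded.
count_strand <- function(seqs, pattern, n_counts) {
  w <- nchar(pattern)
  counts <- rep(0L, length(seqs))
  ok <- Biostrings::width(seqs) >= w
  if (!any(ok)) return(counts)
  hits <- Biostrings::vmatchPattern(pattern, seqs[ok], fixed = "subject")
  cnt <- lengths(hits)
  # drop matches overlapping an N (only sequences that contain one)
  fix <- which(cnt > 0L & n_counts[ok] > 0L)
  for (i in fix) {
    s <- seqs[ok][[i]]
    npos <- as.integer(
      Biostrings::matchPattern("N", s, fixed = TRUE)@ranges@start)
    st <- as.integer(hits[[i]]@start)
    cnt[i] <- sum(vapply(st, function(p)
      !any(npos >= p & npos <= p + w - 1L), TRUE))
  }
  counts[ok] <- cnt
  counts
}

#' Scan promoters for an IUPAC motif
#'
#' Counts occurrences of a degenerate (IUPAC) motif in each promoter on the
#' forward strand and on the reverse complement, i.e. elements on either
#' strand are found. Overlapping matches count; an `N` in the promoter
#' matches nothing; a motif longer than the promoter yields count 0.
#'
#' @param promoters a named [Biostrings::DNAStringSet]
#'   (see [read_promoters()]).
#' @param iupac motif string over the IUPAC alphabet.
#' @return A `data.frame`: `gene_id`, `count`, `present`.
#' @export
scan_motif <- function(promoters, iupac) {
  iupac <- toupper(iupac)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", iupac)) stop_("invalid IUPAC motif")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(iupac)))
  n_counts <- Biostrings::alphabetFrequency(promoters)[, "N"]
  counts <- count_strand(promoters, iupac, n_counts) +
    count_strand(promoters, rc, n_counts)
  data.frame(gene_id = names(promoters), count = counts,
             present = counts >= 1L, stringsAsFactors = FALSE)
}

#' Scan promoters for a motif library
#'
#' @param promoters a named [Biostrings::DNAStringSet].
#' @param motifs `data.frame` with `motif_name`, `iupac`
#'   (see [read_motifs()]).
#' @return A `data.frame`: `gene_id`, `motif_name`, `count`, `present`.
#' @export
scan_motifs <- function(promoters, motifs) {
  do.call(rbind, lapply(seq_len(nrow(motifs)), function(j) {
    h <- scan_motif(promoters, motifs$iupac[j])
    h$motif_name <- motifs$motif_name[j]
    h[, c("gene_id", "motif_name", "count", "present")]
  }))
}

#' Per-cluster motif enrichment
#'
#' For each (motif, cluster) pair, a one-sided Fisher exact test of whether
#' promoters of the cluster's genes contain the motif (presence, not count)
#' more often than promoters in the background gene universe. Pairs with
#' `p < alpha` are flagged significant. No multiplicity correction is applied
#' by default; set `add_q = TRUE` for a Storey q column.
#'
#' @param hits `data.frame` from [scan_motifs()] (needs `gene_id`,
#'   `motif_name`, `present`).
#' @param clusters named vector, gene -> cluster; must be a subset of the
#'   background.
#' @param background character vector of all genes with scanned promoters;
#'   default: all genes in `hits`.
#' @param alpha significance flag threshold.
#' @param add_q add Storey q-values across all (motif, cluster) tests.
#' @return A `data.frame`: `motif_name`, `cluster`, `k_in`, `n_in`, `k_bg`,
#'   `n_bg`, `odds_ratio`, `p`, `significant`, ordered by p.
#' @export
motif_cluster_enrichment <- function(hits, clusters, background = NULL,
                                     alpha = 0.05, add_q = FALSE) {
  background <- unique(background %||% hits$gene_id)
  if (length(setdiff(names(clusters), background)))
    stop_("cluster genes must be a subset of the background")
  out <- do.call(rbind, lapply(unique(hits$motif_name), function(mo) {
    h <- hits[hits$motif_name == mo & hits$gene_id %in% background, ]
    with_motif <- h$gene_id[h$present]
    do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
      genes_cl <- names(clusters)[clusters == cl]
      fr <- fisher_overrep(genes_cl, with_motif, background)
      data.frame(motif_name = mo, cluster = cl,
                 k_in = fr$a, n_in = length(genes_cl),
                 k_bg = length(with_motif), n_bg = length(background),
                 odds_ratio = fr$odds_ratio, p = fr$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  out$significant <- out$p < alpha
  if (add_q) out$q <- as.numeric(storey_q(out$p))
  out[order(out$p, out$motif_name, out$cluster), ]
}
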
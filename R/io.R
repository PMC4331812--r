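#' Construct a sample design
#'
#' A sample design binds each sample (a chip or a metabolomics run) to its
#' developmental time point, in days after flowering (DAF), and its biological
#' replicate number. Every abundance matrix in the package carries one.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param time numeric vector of time-point values (DAF).
#' @param replicate positive integer vector of replicate numbers.
#' @return A `data.frame` of class `sample_design` with columns
#'   `sample_id`, `time`, `replicate`.
#' @examples
#' sample_design(c("s1", "s2"), c(25, 25), c(1, 2))
#' @export
sample_design <- function(sample_id, time, replicate) {
  sample_id <- as.character(sample_id)
  time <- as.numeric(time)
  replicate <- as.integer(replicate)
  if (anyDuplicated(sample_id))
    stop_("duplicated sample ids: %s",
          paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (length(sample_id) != length(time) || length(sample_id) != length(replicate))
    stop_("sample_id, time and replicate must have equal length")
  if (anyNA(time)) stop_("time points must be numeric and non-missing")
  if (anyNA(replicate) || any(replicate < 1L))
    stop_("replicates must be positive integers")
  out <- data.frame(sample_id = sample_id, time = time, replicate = replicate,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_design", "data.frame")
  out
}

#' Read a sample design from TSV
#'
#' @param path TSV file with columns `sample_id`, `time`, `replicate`.
#' @return A [sample_design()] object.
#' @export
read_design <- function(path) {
  df <- read_tsv_file(path)
  need <- c("sample_id", "time", "replicate")
  if (!all(need %in% names(df)))
    stop_("design file %s must have columns %s", path, paste(need, collapse = ", "))
  sample_design(df$sample_id, df$time, df$replicate)
}

#' Construct a feature-by-sample abundance matrix
#'
#' The central container of the package: a numeric matrix of feature
#' abundances (metabolite analyte intensities or transcript signal values)
#' with features as rows and samples as columns, bound to a [sample_design()].
#' Missing cells (`NA`) mark values below the detection limit of the platform.
#'
#' @param values numeric matrix, features x samples, with feature ids as row
#'   names and sample ids as column names.
#' @param design a [sample_design()] covering exactly the matrix columns;
#'   columns of `values` are reordered to the design's sample order.
#' @param scale `"raw"` (positive abundances) or `"ln_centered"`
#'   (natural-log transformed and per-sample median centred,
#'   see [ln_median_center()]).
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `design`, `scale`.
#' @export
omics_matrix <- function(values, design, scale = c("raw", "ln_centered")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_("values must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop_("duplicated feature ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (!inherits(design, "sample_design")) stop_("design must be a sample_design")
  missing_in_design <- setdiff(colnames(values), design$sample_id)
  if (length(missing_in_design))
    stop_("sample(s) not in design: %s", paste(missing_in_design, collapse = ", "))
  missing_in_values <- setdiff(design$sample_id, colnames(values))
  if (length(missing_in_values))
    stop_("design sample(s) missing from matrix: %s",
          paste(missing_in_values, collapse = ", "))
  values <- values[, design$sample_id, drop = FALSE]
  if (scale == "raw" && any(values <= 0, na.rm = TRUE)) {
    warning("non-positive raw values flagged as below detection (set to NA)",
            call. = FALSE)
    values[values <= 0] <- NA_real_
  }
  structure(list(values = values, design = design, scale = scale),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  tp <- sort(unique(x$design$time))
  cat(sprintf("time points (DAF): %s; replicates per time: %s\n",
              paste(tp, collapse = ", "),
              paste(tabulate(factor(x$design$time, levels = tp)), collapse = ", ")))
  if (anyNA(x$values))
    cat(sprintf("%d below-detection cells\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Feature ids of an omics matrix
#' @param x an `omics_matrix`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' Read an abundance matrix plus its design from TSV
#'
#' The value file has a header row of sample ids and feature ids in the first
#' column; empty cells encode below-detection values. The sample order of the
#' returned matrix is the order of the design file, regardless of the column
#' order in the value file.
#'
#' @param path TSV abundance file.
#' @param design_path TSV design file (see [read_design()]).
#' @return An [omics_matrix()] on the `"raw"` scale.
#' @export
read_matrix <- function(path, design_path) {
  design <- read_design(design_path)
  df <- read_tsv_file(path, colClasses = NA, na.strings = c("", "NA"))
  if (ncol(df) < 2L) stop_("matrix file %s has no sample columns", path)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stop_("non-numeric cells in sample column(s): %s",
          paste(names(vals)[bad], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  omics_matrix(m, design, scale = "raw")
}

#' Write an abundance matrix (and optionally its design) to TSV
#'
#' @param x an [omics_matrix()].
#' @param path output TSV for the values.
#' @param design_path optional output TSV for the design.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, design_path = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  # full double precision so write/read round trips are lossless
  chr <- apply(x$values, 2L, function(v)
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v)))
  if (is.null(dim(chr))) chr <- matrix(chr, nrow = nrow(x$values))
  df <- data.frame(feature_id = rownames(x$values), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("feature_id", colnames(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(design_path))
    write_tsv_file(as.data.frame(x$design), design_path)
  invisible(path)
}

#' Assemble category catalogs from a feature-to-category map
#'
#' Categories (metabolic pathways or GO terms) are read from a two- or
#' three-column TSV (`feature_id`, `category_id`, optional `category_kind`).
#' Membership is a set: duplicate rows collapse. A category is *testable*
#' only when at least two of its members are among the measured features.
#' Non-testable categories are retained but flagged.
#'
#' @param path TSV file path.
#' @param measured_ids character vector of measured feature ids.
#' @return A `data.frame` of class `category_catalog` with columns
#'   `category_id`, `category_kind`, `members` (list column),
#'   `n_members`, `n_measured`, `testable`, ordered by `category_id`.
#' @export
read_catalog <- function(path, measured_ids) {
  if (!file.exists(path) || length(readLines(path, n = 1L)) == 0L)
    stop_("empty catalog file: %s", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_("empty catalog file: %s", path)
  if (ncol(df) < 2L) stop_("catalog file %s needs >= 2 columns", path)
  # tolerate a header row
  if (identical(tolower(df[1, 1]), "feature_id")) df <- df[-1L, , drop = FALSE]
  if (any(!nzchar(df[[1]])) || any(!nzchar(df[[2]])))
    stop_("malformed catalog row with empty field in %s", path)
  kind <- if (ncol(df) >= 3L) as.character(df[[3]]) else rep("pathway", nrow(df))
  build_catalog(split(as.character(df[[1]]), as.character(df[[2]])),
                kind = vapply(split(kind, as.character(df[[2]])), `[`, "", 1L),
                measured_ids = measured_ids)
}

# Shared catalog assembler for file input and the simulator.
build_catalog <- function(member_list, kind, measured_ids) {
  ord <- order(names(member_list))
  member_list <- lapply(member_list[ord], function(m) sort(unique(m)))
  out <- data.frame(category_id = names(member_list),
                    category_kind = unname(kind[ord]),
                    stringsAsFactors = FALSE)
  out$members <- unname(member_list)
  out$n_members <- lengths(member_list)
  out$n_measured <- vapply(member_list,
                           function(m) sum(m %in% measured_ids), 0L)
  out$testable <- out$n_measured >= 2L
  rownames(out) <- NULL
  class(out) <- c("category_catalog", "data.frame")
  out
}

#' Read promoter sequences from FASTA
#'
#' Promoters are the regions upstream of the ATG translational start codon.
#' Sequences are upper-cased; records longer than `max_len` are truncated to
#' the 3'-most `max_len` nucleotides, i.e. the end adjacent to the ATG.
#'
#' @param path FASTA file; record names are gene ids.
#' @param max_len maximum promoter length kept (default 1000 nt).
#' @return A [Biostrings::DNAStringSet] named by gene id.
#' @export
read_promoters <- function(path, max_len = 1000L) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop_("duplicate gene id(s) in %s: %s", path,
          paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  af <- Biostrings::alphabetFrequency(seqs)
  extra <- rowSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(extra > 0))
    stop_("invalid characters in promoter(s): %s",
          paste(names(seqs)[extra > 0], collapse = ", "))
  w <- Biostrings::width(seqs)
  long <- w > max_len
  if (any(long))
    seqs[long] <- Biostrings::subseq(seqs[long], start = w[long] - max_len + 1L)
  seqs
}

#' Read a cis-element motif library from TSV
#'
#' @param path TSV with columns `motif_name` and `iupac` (degenerate DNA
#'   string over the IUPAC alphabet).
#' @return A `data.frame` with columns `motif_name`, `iupac`.
#' @export
read_motifs <- function(path) {
  df <- read_tsv_file(path)
  if (!all(c("motif_name", "iupac") %in% names(df)))
    stop_("motif file %s must have columns motif_name, iupac", path)
  df$iupac <- toupper(df$iupac)
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", df$iupac)
  if (!all(ok))
    stop_("invalid IUPAC motif(s): %s", paste(df$motif_name[!ok], collapse = ", "))
  df[, c("motif_name", "iupac")]
}
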
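# Builders for small in-code fixtures.

# Balanced omics matrix from a features x (times*reps) value matrix; columns
# ordered time-major (all replicates of time 1, then time 2, ...).
make_om <- function(values, times = c(25, 30, 35, 45, 50), reps = 2L,
                    scale = "raw", ids = NULL) {
  n_t <- length(times)
  values <- as.matrix(values)
  stopifnot(ncol(values) == n_t * reps)
  ids <- ids %||% sprintf("f%02d", seq_len(nrow(values)))
  sid <- sprintf("s_%g_r%d", rep(times, each = reps), rep(seq_len(reps), n_t))
  dimnames(values) <- list(ids, sid)
  d <- sample_design(sid, rep(times, each = reps), rep(seq_len(reps), n_t))
  omics_matrix(values, d, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent naive IUPAC sliding-window scanner (both strands, N in the
# sequence matches nothing).
naive_scan <- function(seq, iupac) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
           W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
           V = "ACG", N = "ACGT")
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  count1 <- function(s, pat) {
    sc <- strsplit(s, "")[[1]]
    pc <- strsplit(pat, "")[[1]]
    w <- length(pc); n <- length(sc)
    if (w > n) return(0L)
    hits <- 0L
    for (i in seq_len(n - w + 1L)) {
      win <- sc[i:(i + w - 1L)]
      ok <- all(vapply(seq_len(w), function(j)
        win[j] != "N" && grepl(win[j], map[pc[j]], fixed = TRUE), TRUE))
      if (ok) hits <- hits + 1L
    }
    hits
  }
  rc <- paste(rev(comp[strsplit(iupac, "")[[1]]]), collapse = "")
  count1(seq, iupac) + count1(seq, rc)
}

# Exhaustive MRPP p-value: all label assignments with fixed group sizes.
exhaustive_mrpp_p <- function(vals, grp) {
  D <- as.matrix(dist(t(vals)))
  N <- ncol(D)
  sizes <- table(grp)
  delta_of <- function(labels) {
    s <- 0
    for (g in unique(labels)) {
      idx <- which(labels == g)
      s <- s + (length(idx) / N) *
        mean(D[idx, idx][lower.tri(diag(length(idx)))])
    }
    s
  }
  obs <- delta_of(grp)
  stopifnot(length(sizes) == 2L)  # oracle for two groups only
  g1 <- utils::combn(N, sizes[1])
  deltas <- apply(g1, 2L, function(idx) {
    lab <- rep(2L, N); lab[idx] <- 1L
    delta_of(lab)
  })
  list(obs = obs, p = mean(deltas <= obs + 1e-12))
}
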
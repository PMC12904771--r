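# Shared test fixtures and independent oracles.

random_records <- function(n, min_len = 5, max_len = 40, prefix = "p",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- min_len + sample.int(max_len - min_len + 1L, n, replace = TRUE) - 1L
  seqs <- vapply(lens, function(L)
    paste(sample(AA_ALPHABET_LG, L, replace = TRUE), collapse = ""),
    character(1))
  protein_records(paste0(prefix, seq_len(n)), seqs)
}

random_hits <- function(n, qids = paste0("q", 1:5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qstart <- sample(1:50, n, replace = TRUE)
  sstart <- sample(1:80, n, replace = TRUE)
  len <- sample(10:60, n, replace = TRUE)
  data.frame(
    qseqid = sample(qids, n, replace = TRUE),
    sseqid = paste0("s", sample(1:40, n, replace = TRUE)),
    pident = round(runif(n, 10, 100), 2),
    length = len,
    mismatch = sample(0:20, n, replace = TRUE),
    gapopen = sample(0:4, n, replace = TRUE),
    qstart = qstart, qend = qstart + len - 1L,
    sstart = sstart, send = sstart + len - 1L,
    evalue = 10^runif(n, -8, 0),
    bitscore = round(runif(n, 15, 80), 2),
    stringsAsFactors = FALSE)
}

# Independent Smith-Waterman oracle: three-state affine recursion written in
# plain R (no column sweep, no shared code with the C++ kernel). Scores only.
sw_oracle_score <- function(query, subject, gap_open = 11, gap_extend = 1) {
  smat <- divorph:::scoring_matrix()
  q <- strsplit(query, "")[[1]]; s <- strsplit(subject, "")[[1]]
  nq <- length(q); ns <- length(s)
  M <- matrix(-Inf, nq + 1, ns + 1)
  Ix <- matrix(-Inf, nq + 1, ns + 1)
  Iy <- matrix(-Inf, nq + 1, ns + 1)
  best <- 0
  for (i in seq_len(nq)) {
    for (j in seq_len(ns)) {
      sub <- smat[q[i], s[j]]
      M[i + 1, j + 1] <- sub + max(0, M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# tiny labeled feature-like table with a planted linear signal
toy_labeled_table <- function(n_per_class = 60, p = 5, shift = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), ncol = p)
  X[seq_len(n_per_class), 1] <- X[seq_len(n_per_class), 1] + shift
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(p))
  df$CLASS <- rep(c(1L, 0L), each = n_per_class)
  df
}
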
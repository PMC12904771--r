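# Desk-scale similarity search: all-vs-database affine-gap Smith-Waterman
# with Karlin-Altschul E-values, emitting the standard 12-column tabular
# schema. External DIAMOND/BLAST outfmt-6 files are interchangeable with
# this engine's output downstream.

#' Search parameter set
#'
#' `lambda` and `K` default to the published gapped BLOSUM62 (open 11 /
#' extend 1) Karlin-Altschul values; they are configuration, not constants,
#' because an external aligner's internal calibration cannot be reproduced
#' exactly -- the pipeline's contract is the hit schema, not hit-identical
#' output.
#'
#' @param matrix Scoring matrix name; only "BLOSUM62" is shipped.
#' @param gap_open Gap opening penalty (> 0); a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param gap_extend Gap extension penalty (> 0).
#' @param lambda Karlin-Altschul scale (> 0).
#' @param K Karlin-Altschul constant (> 0).
#' @param e_max E-value report ceiling (default 1.0).
#' @param db_size Total residues assumed in the database; `NULL` means use
#'   the searched database's actual residue count.
#' @return A list of class `search_params`.
#' @export
search_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041, e_max = 1.0,
                          db_size = NULL) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0, e_max > 0)
  if (!identical(matrix, "BLOSUM62"))
    stop("only BLOSUM62 is available")
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, e_max = e_max, db_size = db_size),
            class = "search_params")
}

# 21-letter scoring matrix in LG residue order + X; X scores 0 vs anything.
.search_cache <- new.env(parent = emptyenv())

scoring_matrix <- function(name = "BLOSUM62") {
  key <- paste0("mat_", name)
  if (is.null(.search_cache[[key]])) {
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    full <- data_env$BLOSUM62
    ab <- c(AA_ALPHABET_LG, "X")
    m <- full[ab, ab]
    m["X", ] <- 0L
    m[, "X"] <- 0L
    storage.mode(m) <- "integer"
    .search_cache[[key]] <- m
  }
  .search_cache[[key]]
}

# 0-based integer codes into the scoring matrix rows
search_codes <- function(sequence) {
  codes <- match(strsplit(sequence, "", fixed = TRUE)[[1L]],
                 c(AA_ALPHABET_LG, "X")) - 1L
  if (anyNA(codes)) stop("sequence contains non-amino-acid characters")
  codes
}

#' Optimal local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman. Ties on the optimal score are broken
#' deterministically (smallest query end, then subject end, diagonal-first
#' traceback).
#'
#' @param query,subject Amino-acid sequence strings (non-empty).
#' @param params A [search_params] object.
#' @return A list with `score`, 1-based inclusive coordinates `qstart`,
#'   `qend`, `sstart`, `send`, `align_len` (columns including gaps),
#'   `identities`, `mismatches`, `gap_opens` and `pident`; or
#'   `list(score = 0)` when no positive-scoring local alignment exists.
#' @export
smith_waterman <- function(query, subject, params = search_params()) {
  if (!nzchar(query) || !nzchar(subject)) stop("sequences must be non-empty")
  res <- .cpp_sw_align(search_codes(query), search_codes(subject),
                       scoring_matrix(params$matrix),
                       as.integer(params$gap_open),
                       as.integer(params$gap_extend))
  if (res$score > 0) res$pident <- 100 * res$identities / res$align_len
  res
}

#' Karlin-Altschul E-value and bit score
#'
#' `bitscore = (lambda * S - ln K) / ln 2` and
#' `evalue = query_len * db_size * 2^(-bitscore)`.
#'
#' @param raw_score Raw alignment score(s), >= 0 (vectorized).
#' @param query_len Query length in residues.
#' @param db_size Database size in residues.
#' @param params A [search_params] object supplying lambda and K.
#' @return A list with numeric vectors `evalue` and `bitscore`.
#' @export
evalue_and_bitscore <- function(raw_score, query_len, db_size,
                                params = search_params()) {
  stopifnot(all(raw_score >= 0), query_len >= 1, db_size >= 1)
  bitscore <- (params$lambda * raw_score - log(params$K)) / log(2)
  evalue <- query_len * db_size * 2^(-bitscore)
  list(evalue = evalue, bitscore = bitscore)
}

#' Search all queries against a sequence database
#'
#' For every query, every subject whose optimal local alignment reaches
#' `evalue <= e_max` is reported as one outfmt-6 row (single best alignment
#' per query-subject pair, no HSP chaining), sorted per query by ascending
#' E-value then subject id.
#'
#' @param queries,database [protein_records] frames.
#' @param params A [search_params] object.
#' @param exclude_self Drop hits where `qseqid == sseqid` (for real-orphan
#'   searches where queries are part of the database).
#' @return A hit table with the 12 standard columns (see
#'   [read_tabular_hits]).
#' @export
search_all <- function(queries, database, params = search_params(),
                       exclude_self = FALSE) {
  if (nrow(database) == 0L) stop("empty database")
  if (nrow(queries) == 0L) return(empty_hits())
  smat <- scoring_matrix(params$matrix)
  db_codes <- lapply(database$sequence, search_codes)
  db_size <- if (is.null(params$db_size)) sum(nchar(database$sequence))
             else params$db_size
  gapo <- as.integer(params$gap_open); gape <- as.integer(params$gap_extend)

  rows <- vector("list", nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    qcodes <- search_codes(queries$sequence[qi])
    qlen <- length(qcodes)
    scores <- .cpp_sw_score_batch(qcodes, db_codes, smat, gapo, gape)
    eb <- evalue_and_bitscore(pmax(scores, 0), qlen, db_size, params)
    cand <- which(scores > 0 & eb$evalue <= params$e_max)
    if (exclude_self)
      cand <- cand[database$id[cand] != queries$id[qi]]
    if (!length(cand)) next
    sub_rows <- lapply(cand, function(si) {
      al <- .cpp_sw_align(qcodes, db_codes[[si]], smat, gapo, gape)
      data.frame(qseqid = queries$id[qi], sseqid = database$id[si],
                 pident = 100 * al$identities / al$align_len,
                 length = al$align_len, mismatch = al$mismatches,
                 gapopen = al$gap_opens, qstart = al$qstart, qend = al$qend,
                 sstart = al$sstart, send = al$send,
                 evalue = eb$evalue[si], bitscore = eb$bitscore[si],
                 stringsAsFactors = FALSE)
    })
    qhits <- do.call(rbind, sub_rows)
    qhits <- qhits[order(qhits$evalue, qhits$sseqid), , drop = FALSE]
    rows[[qi]] <- qhits
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(empty_hits())
  rownames(out) <- NULL
  out
}
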
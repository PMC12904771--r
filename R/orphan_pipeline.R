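# From search output to labeled datasets: eligibility calling on the
# non-significant hit band, reversed-sequence negative controls, truncation
# calibration for length matching, and balanced dataset assembly.

#' Call orphan eligibility from a hit table
#'
#' A query is an *eligible orphan* when it has no hit with
#' `evalue <= sig_threshold` but at least one hit inside the band
#' `[sig_threshold, band_max]`. Queries whose best hit is significant are
#' `has_significant_hit`; queries with no band hit at all (including queries
#' absent from the hit table) are `no_band_hits`. The band is closed on both
#' ends by default; `strict_upper = TRUE` uses `< band_max` instead.
#'
#' @param hits A 12-column hit table ([search_all] or [read_tabular_hits]).
#' @param queries A [protein_records] frame of every searched query (needed
#'   so hit-less queries are reported).
#' @param sig_threshold Significance cutoff (default 1e-3).
#' @param band_max Upper E-value bound of the retained band (default 1).
#' @param strict_upper Use a strict upper bound for the band.
#' @return A list of class `orphan_calls`: `calls` (query_id, query_length,
#'   status, n_band_hits) and `band_hits` (band rows of eligible queries).
#' @export
call_eligibility <- function(hits, queries, sig_threshold = 1e-3,
                             band_max = 1.0, strict_upper = FALSE) {
  stopifnot(sig_threshold > 0, sig_threshold < band_max)
  in_band <- hits$evalue >= sig_threshold &
    (if (strict_upper) hits$evalue < band_max else hits$evalue <= band_max)
  min_e <- tapply(hits$evalue, hits$qseqid, min)
  band_n <- tapply(in_band, hits$qseqid, sum)

  qid <- queries$id
  qlen <- nchar(queries$sequence)
  me <- unname(min_e[qid])
  bn <- unname(band_n[qid]); bn[is.na(bn)] <- 0L
  status <- ifelse(!is.na(me) & me <= sig_threshold, "has_significant_hit",
                   ifelse(bn > 0, "eligible_orphan", "no_band_hits"))
  calls <- data.frame(query_id = qid, query_length = qlen, status = status,
                      n_band_hits = as.integer(bn), stringsAsFactors = FALSE)
  eligible <- calls$query_id[calls$status == "eligible_orphan"]
  band_hits <- hits[in_band & hits$qseqid %in% eligible, , drop = FALSE]
  rownames(band_hits) <- NULL
  structure(list(calls = calls, band_hits = band_hits,
                 sig_threshold = sig_threshold, band_max = band_max),
            class = "orphan_calls")
}

#' Reverse protein sequences (homology-free negative control)
#'
#' Reading each sequence end-to-start preserves length and amino-acid
#' composition but destroys true homology. Ids get a `_rev` suffix and
#' provenance becomes `reversed`.
#'
#' @param records A [protein_records] frame.
#' @return A [protein_records] frame of reversed sequences.
#' @export
reverse_sequence <- function(records) {
  rev_one <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                               collapse = "")
  protein_records(paste0(records$id, "_rev"),
                  vapply(records$sequence, rev_one, character(1)),
                  provenance = "reversed",
                  taxon_label = records$taxon_label)
}

#' Truncate sequences by a trailing fraction
#'
#' Removes the trailing fraction `fraction` of each sequence (on an already
#' reversed sequence this discards what was the original N-terminus; set
#' `end = "leading"` for the other convention). At least `min_len` residues
#' are kept.
#'
#' @param records A [protein_records] frame.
#' @param fraction Fraction removed, in `[0, 0.9]`.
#' @param end Which end to remove: "trailing" (default) or "leading".
#' @param min_len Minimum retained length.
#' @return A [protein_records] frame with truncated sequences.
#' @export
truncate_records <- function(records, fraction, end = c("trailing", "leading"),
                             min_len = 1L) {
  stopifnot(fraction >= 0, fraction <= 0.9)
  end <- match.arg(end)
  L <- nchar(records$sequence)
  keep <- pmax(min_len, round(L * (1 - fraction)))
  keep <- pmin(keep, L)
  seqs <- if (end == "trailing") substr(records$sequence, 1L, keep)
          else substr(records$sequence, L - keep + 1L, L)
  out <- records
  out$sequence <- unname(seqs)
  out
}

#' Calibrate the negative-control truncation fraction
#'
#' Reversed controls tend to stay longer than eligible simulated orphans
#' (short sequences fade into the twilight zone faster), which would leak
#' length into the classifier. For each candidate fraction the reversed
#' candidates are truncated, re-searched, re-called, and the mean length of
#' *eligible* negatives compared with the mean eligible positive length; the
#' fraction minimizing the absolute difference wins (ties: smaller
#' fraction).
#'
#' @param positive_lengths Lengths of the eligible simulated orphans.
#' @param reversed_candidates [protein_records] of reversed query candidates.
#' @param search_fn Function `records -> hit table` (the search backend).
#' @param grid Candidate fractions in `[0, 0.9]`.
#' @param sig_threshold,band_max Eligibility thresholds.
#' @return List: `fraction` (f*), and `table` of per-fraction mean eligible
#'   negative lengths.
#' @export
calibrate_truncation <- function(positive_lengths, reversed_candidates,
                                 search_fn, grid = seq(0, 0.4, by = 0.1),
                                 sig_threshold = 1e-3, band_max = 1.0) {
  if (!length(grid)) stop("empty truncation grid")
  stopifnot(all(grid >= 0 & grid <= 0.9), length(positive_lengths) > 0)
  mean_pos <- mean(positive_lengths)
  res <- lapply(grid, function(f) {
    trunc <- truncate_records(reversed_candidates, f)
    hits <- search_fn(trunc)
    calls <- call_eligibility(hits, trunc, sig_threshold, band_max)$calls
    el <- calls$query_length[calls$status == "eligible_orphan"]
    data.frame(fraction = f, n_eligible = length(el),
               mean_neg_length = if (length(el)) mean(el) else NA_real_)
  })
  tab <- do.call(rbind, res)
  ok <- !is.na(tab$mean_neg_length)
  if (!any(ok)) stop("no eligible negatives at any truncation fraction")
  gap <- abs(tab$mean_neg_length - mean_pos)
  gap[!ok] <- Inf
  best <- which(gap == min(gap))
  f_star <- min(tab$fraction[best])  # ties -> smaller fraction
  list(fraction = f_star, mean_positive_length = mean_pos, table = tab)
}

#' Assemble a balanced labeled dataset
#'
#' Samples an equal number of rows from the positive (simulated, CLASS = 1)
#' and negative (reversed, CLASS = 0) feature tables.
#'
#' @param positives,negatives Feature tables without a CLASS column.
#' @param n_per_class Rows per class; default `min(nrow(positives),
#'   nrow(negatives))`.
#' @param seed Optional seed for reproducible sampling.
#' @return A single feature table with a binary `CLASS` column.
#' @export
assemble_dataset <- function(positives, negatives, n_per_class = NULL,
                             seed = NULL) {
  if (!nrow(positives) || !nrow(negatives))
    stop("both classes must be non-empty")
  avail <- min(nrow(positives), nrow(negatives))
  if (is.null(n_per_class)) n_per_class <- avail
  if (n_per_class > avail)
    stop("requested ", n_per_class, " rows per class but only ", avail,
         " available")
  if (!is.null(seed)) set.seed(seed)
  pos <- positives[sample.int(nrow(positives), n_per_class), , drop = FALSE]
  neg <- negatives[sample.int(nrow(negatives), n_per_class), , drop = FALSE]
  pos$CLASS <- 1L
  neg$CLASS <- 0L
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}

#' Assemble a mixed dataset across parameter subsets
#'
#' Takes one `(positives, negatives)` pair per parameter set and samples the
#' same number of rows per class from every subset -- the minimum class
#' yield across all subsets -- so each parameter combination contributes
#' equally.
#'
#' @param subsets A list; each element is `list(positives = <table>,
#'   negatives = <table>)`.
#' @param seed Optional seed.
#' @return A combined feature table with `CLASS`, plus attribute
#'   `n_per_class`.
#' @export
assemble_mixed_dataset <- function(subsets, seed = NULL) {
  if (!length(subsets)) stop("no subsets supplied")
  n <- min(vapply(subsets, function(s)
    min(nrow(s$positives), nrow(s$negatives)), integer(1)))
  if (n < 1L) stop("a subset has an empty class; cannot balance")
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(subsets, function(s)
    assemble_dataset(s$positives, s$negatives, n_per_class = n))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "n_per_class") <- n
  out
}
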
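# The eleven hit-band statistics computed per eligible orphan, and the
# z-score scaler applied before model training.

#' Names of the eleven hit-band features, in canonical column order
#' @export
FEATURE_NAMES <- c("alignment_count", "avg_pident", "avg_evalue",
                   "avg_bitscore", "avg_coverage", "min_evalue",
                   "max_pident", "avg_align_len", "max_bitscore",
                   "max_align_len", "total_query_coverage")

#' Extract the eleven hit-band features for one query
#'
#' All statistics are computed over the query's band hits
#' (`sig_threshold <= E <= band_max`). Length-dependent quantities are
#' normalized by query length: alignment count (hits per residue), average
#' and highest bit score (bits per residue), highest alignment length
#' (fraction), and the coverages. Average alignment length stays in
#' residues. `total_query_coverage` is the fraction of query residues
#' covered by the union of hit intervals. Because alignment length counts
#' gap columns, `avg_coverage` may exceed 1 for heavily gapped hits.
#'
#' @param query_length Query length in residues (>= 1).
#' @param band_hits Hit-table rows for this query (>= 1 row).
#' @return Named numeric vector of length 11.
#' @export
extract_features <- function(query_length, band_hits) {
  if (nrow(band_hits) == 0L)
    stop("zero band hits: eligibility must be enforced before feature extraction")
  stopifnot(query_length >= 1)
  union_cov <- function(qs, qe) {
    qs <- pmax(1L, qs); qe <- pmin(as.integer(query_length), qe)
    o <- order(qs, qe)
    qs <- qs[o]; qe <- qe[o]
    total <- 0L; hi <- 0L
    for (k in seq_along(qs)) {
      if (qs[k] > hi) { total <- total + qe[k] - qs[k] + 1L; hi <- qe[k] }
      else if (qe[k] > hi) { total <- total + qe[k] - hi; hi <- qe[k] }
    }
    total
  }
  c(alignment_count = nrow(band_hits) / query_length,
    avg_pident = mean(band_hits$pident),
    avg_evalue = mean(band_hits$evalue),
    avg_bitscore = mean(band_hits$bitscore) / query_length,
    avg_coverage = mean(band_hits$length / query_length),
    min_evalue = min(band_hits$evalue),
    max_pident = max(band_hits$pident),
    avg_align_len = mean(band_hits$length),
    max_bitscore = max(band_hits$bitscore) / query_length,
    max_align_len = max(band_hits$length) / query_length,
    total_query_coverage = union_cov(band_hits$qstart, band_hits$qend) /
      query_length)
}

#' Build a feature table from orphan calls
#'
#' One row per eligible orphan, columns in the fixed order of
#' `FEATURE_NAMES`, with the query id as row identifier column and an
#' optional binary `CLASS` label (1 = simulated/divergent, 0 = reversed).
#'
#' @param calls An `orphan_calls` object from [call_eligibility].
#' @param class_label Optional single 0/1 label for every row.
#' @return A `data.frame` with `query_id`, the 11 features, and `CLASS` when
#'   labeled.
#' @export
feature_table <- function(calls, class_label = NULL) {
  el <- calls$calls[calls$calls$status == "eligible_orphan", , drop = FALSE]
  split_hits <- split(calls$band_hits, calls$band_hits$qseqid)
  rows <- lapply(seq_len(nrow(el)), function(k)
    extract_features(el$query_length[k], split_hits[[el$query_id[k]]]))
  out <- as.data.frame(do.call(rbind, rows))
  if (!nrow(el)) out <- as.data.frame(matrix(numeric(), 0, length(FEATURE_NAMES),
                                             dimnames = list(NULL, FEATURE_NAMES)))
  out <- cbind(data.frame(query_id = el$query_id, stringsAsFactors = FALSE), out)
  if (!is.null(class_label)) out$CLASS <- as.integer(class_label)
  out
}

#' Fit a z-score scaler
#'
#' Per-feature mean and sample (n-1) standard deviation on a reference
#' table. Constant columns are dropped with a warning. `query_id` and
#' `CLASS` are never scaled.
#'
#' @param table A feature table (>= 2 rows).
#' @return A list of class `feature_scaler` with `center`, `scale` and the
#'   retained feature names.
#' @export
fit_scaler <- function(table) {
  feats <- setdiff(names(table), c("query_id", "CLASS"))
  if (nrow(table) < 2L) stop("need >= 2 rows to fit a scaler")
  center <- vapply(table[feats], mean, numeric(1))
  scale <- vapply(table[feats], stats::sd, numeric(1))
  constant <- scale <= 0 | !is.finite(scale)
  if (any(constant)) {
    warning("dropping constant feature(s): ",
            paste(feats[constant], collapse = ", "))
    feats <- feats[!constant]
    center <- center[!constant]
    scale <- scale[!constant]
  }
  structure(list(features = feats, center = center, scale = scale),
            class = "feature_scaler")
}

#' Apply (or invert) a fitted z-score scaler
#'
#' @param table A feature table.
#' @param scaler A [fit_scaler] result.
#' @param inverse Undo the scaling instead.
#' @return The table with scaled feature columns; columns dropped at fitting
#'   time are dropped here too. `CLASS`/`query_id` pass through untouched.
#' @export
apply_scaler <- function(table, scaler, inverse = FALSE) {
  keep <- intersect(names(table), c("query_id", scaler$features, "CLASS"))
  out <- table[keep]
  for (f in scaler$features) {
    out[[f]] <- if (inverse) table[[f]] * scaler$scale[[f]] + scaler$center[[f]]
                else (table[[f]] - scaler$center[[f]]) / scaler$scale[[f]]
  }
  out
}
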
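# Standard formats touched by the pipeline: FASTA protein sequences,
# 12-column tabular similarity hits (BLAST/DIAMOND -outfmt 6), newick trees.

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")
.outfmt6_numeric <- c("pident", "length", "mismatch", "gapopen", "qstart",
                      "qend", "sstart", "send", "evalue", "bitscore")

PROVENANCE_LEVELS <- c("root", "simulated", "reversed", "real")

#' Construct a protein record collection
#'
#' A plain `data.frame` with one row per protein: `id`, `sequence`,
#' `provenance` (one of root / simulated / reversed / real) and an optional
#' `taxon_label` naming the terminal branch that produced a simulated record.
#' Sequences are uppercased; the non-canonical letters B, J, Z, U, O, `*` and
#' existing X are all mapped to X (X is scored 0 against everything by the
#' search engine rather than rejected, since real catalogues contain them).
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param provenance Provenance tag, recycled; see above.
#' @param taxon_label Optional terminal-branch label, recycled.
#' @return A `data.frame` with class `protein_records`.
#' @export
protein_records <- function(id, sequence, provenance = "real",
                            taxon_label = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("'id' and 'sequence' must have the same length")
  if (anyDuplicated(id))
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for id(s): ", paste(id[!nzchar(sequence)], collapse = ", "))
  sequence <- chartr("BJZUO*", "XXXXXX", sequence)
  bad <- grepl(sprintf("[^%sX]", paste(AA_ALPHABET_LG, collapse = "")), sequence)
  if (any(bad))
    stop("non-amino-acid characters in sequence(s): ",
         paste(utils::head(id[bad], 5), collapse = ", "))
  provenance <- rep_len(as.character(provenance), length(id))
  if (!all(provenance %in% PROVENANCE_LEVELS))
    stop("provenance must be one of: ", paste(PROVENANCE_LEVELS, collapse = ", "))
  out <- data.frame(id = id, sequence = sequence, provenance = provenance,
                    taxon_label = rep_len(as.character(taxon_label), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' The header token before the first whitespace becomes the record id;
#' sequences are uppercased and non-canonical residues mapped to X.
#'
#' @param path Path to a FASTA file.
#' @param provenance Provenance tag assigned to all records (default "real").
#' @return A [protein_records] data frame.
#' @export
read_fasta <- function(path, provenance = "real") {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && !startsWith(first, ">"))
    stop("malformed FASTA at line 1 (expected '>'): ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L)
    return(protein_records(character(), character(), provenance))
  ids <- sub("\\s.*$", "", names(set))
  protein_records(ids, as.character(set), provenance)
}

#' Write protein records as FASTA
#'
#' @param records A [protein_records] data frame (or anything with `id` and
#'   `sequence` columns).
#' @param path Output path.
#' @param line_width Sequence line width (default 60, must be >= 1).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  stopifnot(line_width >= 1L)
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width))
  invisible(path)
}

#' Read 12-column tabular similarity hits (outfmt 6)
#'
#' Parses the standard BLAST/DIAMOND tab-separated format with the canonical
#' column order qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore. Rows violating the schema are
#' rejected with the offending row number, never silently dropped.
#'
#' @param path Path to a tab-separated hit table without header.
#' @return A `data.frame` with the 12 standard columns, in file order.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("expected 12 tab-separated columns, got ", nf[which(nf != 12L)[1L]],
         " at row ", which(nf != 12L)[1L])
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  hits <- data.frame(qseqid = m[, 1L], sseqid = m[, 2L], stringsAsFactors = FALSE)
  for (k in 3:12) {
    v <- suppressWarnings(as.numeric(m[, k]))
    if (anyNA(v))
      stop("non-numeric value '", m[which(is.na(v))[1L], k], "' in column ",
           OUTFMT6_COLS[k], " at row ", which(is.na(v))[1L])
    hits[[OUTFMT6_COLS[k]]] <- v
  }
  int_cols <- c("length", "mismatch", "gapopen", "qstart", "qend", "sstart", "send")
  for (k in int_cols) hits[[k]] <- as.integer(round(hits[[k]]))
  validate_hits(hits)
  hits
}

empty_hits <- function() {
  hits <- data.frame(qseqid = character(), sseqid = character(),
                     pident = numeric(), length = integer(),
                     mismatch = integer(), gapopen = integer(),
                     qstart = integer(), qend = integer(),
                     sstart = integer(), send = integer(),
                     evalue = numeric(), bitscore = numeric(),
                     stringsAsFactors = FALSE)
  hits
}

validate_hits <- function(hits) {
  with(hits, {
    if (any(evalue < 0)) stop("negative E-value in hit table")
    if (any(pident < 0 | pident > 100)) stop("pident outside [0, 100]")
    if (any(length < 1L)) stop("alignment length < 1")
    if (any(qstart > qend) || any(sstart > send))
      stop("coordinates must satisfy start <= end (1-based inclusive)")
    if (any(qstart < 1L) || any(sstart < 1L)) stop("coordinates are 1-based")
  })
  invisible(hits)
}

#' Write similarity hits in tabular outfmt 6
#'
#' Numeric fields are serialized with 10 significant digits so that a
#' parse/serialize round trip preserves values to relative error < 1e-9.
#'
#' @param hits Hit table as returned by [read_tabular_hits] or [search_all].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tabular_hits <- function(hits, path) {
  num <- function(x) sprintf("%.10g", x)
  lines <- paste(hits$qseqid, hits$sseqid, num(hits$pident), hits$length,
                 hits$mismatch, hits$gapopen, hits$qstart, hits$qend,
                 hits$sstart, hits$send, num(hits$evalue), num(hits$bitscore),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Parse a newick tree with branch lengths
#'
#' @param text A newick string (or, with `file=`, a path).
#' @param file Optional path to a newick file; overrides `text`.
#' @return An `ape::phylo` tree. Errors if branch lengths are missing or
#'   negative or tip labels are duplicated.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) ape::read.tree(file = file)
          else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse newick input")
  if (is.null(tree$edge.length))
    stop("newick tree must carry branch lengths on all edges")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("newick tree has missing or negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate terminal labels in tree")
  tree
}

#' The default 4-taxon simulation tree
#'
#' Terminal branches of lengths 1, 3, 5 and 10 with short (0.1) internal
#' edges, so branch length directly controls how far each descendant has
#' diverged from the root sequence.
#'
#' @return An `ape::phylo` tree with tips Taxon1..Taxon4.
#' @export
default_tree <- function() {
  parse_newick("(((Taxon1:1, Taxon2:3):0.1, Taxon3:5):0.1, Taxon4:10);")
}
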
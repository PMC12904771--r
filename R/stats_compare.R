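# Downstream statistics on divergence calls: 2x2 enrichment (Pearson
# chi-squared with Yates continuity correction), two-sample Wilcoxon
# rank-sum comparisons of protein properties, Cohen's d effect sizes, and
# the length-controlled enrichment re-test. All pure functions of their
# numeric inputs.

#' Pearson chi-squared statistic for a 2x2 table
#'
#' Continuity correction is ON by default: the convention under which the
#' reconstructed reference enrichment table reproduces its reported
#' statistic (the uncorrected value is larger on every table).
#'
#' @param table A 2x2 matrix of non-negative counts
#'   (rows: group subset/rest; columns: call divergent/non-divergent).
#' @param continuity_correction Apply the Yates correction (default TRUE).
#' @return List with `statistic`, `p_value` and `df = 1`.
#' @export
chi_squared <- function(table, continuity_correction = TRUE) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in contingency table")
  expected <- outer(rs, cs) / n
  dev <- abs(table - expected)
  if (continuity_correction) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       df = 1L)
}

#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Exact enumeration when both samples have fewer than 50 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. Degenerate all-tied input yields p = 1.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact distribution;
#'   `NULL` (default) selects automatically as above.
#' @return List with `statistic` (Mann-Whitney U of `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Cohen's d standardized mean difference
#'
#' `(mean(x) - mean(y)) / s_pooled`, pooling variances with n-1 weights.
#'
#' @param x,y Numeric samples of size >= 2.
#' @return Scalar effect size.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Build the subset-vs-rest divergence contingency table
#'
#' @param annotated A `data.frame` with columns `id`, `divergent` (logical
#'   or 0/1).
#' @param subset_ids Ids forming the focal subset (e.g. de novo candidates).
#' @return 2x2 matrix: rows subset/rest, columns divergent/non_divergent.
#' @export
enrichment_table <- function(annotated, subset_ids) {
  in_sub <- annotated$id %in% subset_ids
  div <- as.logical(annotated$divergent)
  m <- rbind(subset = c(sum(in_sub & div), sum(in_sub & !div)),
             rest = c(sum(!in_sub & div), sum(!in_sub & !div)))
  colnames(m) <- c("divergent", "non_divergent")
  m
}

#' Length-controlled enrichment re-test
#'
#' Restricts both groups to proteins no longer than the mean length of the
#' subset, then recomputes the chi-squared enrichment, removing the length
#' confound between the subset and the remaining orphans.
#'
#' @param annotated A `data.frame` with `id`, `divergent` and `length`.
#' @param subset_ids Ids of the focal subset.
#' @param continuity_correction Passed to [chi_squared].
#' @return List with the filtered `table`, `statistic`, `p_value` and the
#'   length `threshold` used.
#' @export
length_controlled_enrichment <- function(annotated, subset_ids,
                                         continuity_correction = TRUE) {
  stopifnot(all(c("id", "divergent", "length") %in% names(annotated)),
            !anyNA(annotated$length))
  threshold <- mean(annotated$length[annotated$id %in% subset_ids])
  kept <- annotated[annotated$length <= threshold, , drop = FALSE]
  if (!any(kept$id %in% subset_ids) || !any(!(kept$id %in% subset_ids)))
    stop("a group is empty after length filtering")
  tab <- enrichment_table(kept, subset_ids)
  res <- chi_squared(tab, continuity_correction)
  list(table = tab, statistic = res$statistic, p_value = res$p_value,
       threshold = threshold)
}
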
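# Compact print methods for the user-facing result objects.

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report>", x$name, "\n")
  if (length(x$best_params))
    cat("  best params:",
        paste(names(x$best_params), unlist(x$best_params), sep = "=",
              collapse = ", "), "\n")
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f  MCC %.3f\n",
              x$metrics["accuracy"], x$metrics["precision"],
              x$metrics["recall"], x$metrics["mcc"]))
  invisible(x)
}

#' @export
print.classification_run <- function(x, ...) {
  cat("<classification_run>", length(x$models), "models,",
      nrow(x$split$train), "train /", nrow(x$split$test), "test rows\n")
  for (r in x$reports) print(r)
  if (!is.na(x$ensemble_accuracy))
    cat(sprintf("  ensemble (2-of-3) accuracy: %.3f\n", x$ensemble_accuracy))
  invisible(x)
}

#' @export
print.scenario_bundle <- function(x, ...) {
  m <- x$manifest
  cat("<scenario_bundle>", m$scenario, "| seed", m$seed, "|",
      length(m$sets), "parameter set(s) x", m$n_roots, "roots\n")
  if (!is.null(x$yield))
    cat("  eligible orphans:", sum(x$yield$eligible), "of",
        nrow(x$yield), "simulated queries\n")
  if (is.null(x$dataset)) cat("  dataset: empty (a class had no rows)\n")
  else cat("  dataset:", nrow(x$dataset), "rows,",
           sum(x$dataset$CLASS == 1), "per class\n")
  invisible(x)
}

#' @export
print.orphan_calls <- function(x, ...) {
  cat("<orphan_calls>", nrow(x$calls), "queries | band [",
      format(x$sig_threshold), ",", format(x$band_max), "]\n")
  print(table(x$calls$status))
  invisible(x)
}

#' @export
print.protein_records <- function(x, ...) {
  cat("<protein_records>", nrow(x), "sequences")
  if (nrow(x)) cat(", lengths", min(nchar(x$sequence)), "-",
                   max(nchar(x$sequence)),
                   "| provenance:", paste(unique(x$provenance), collapse = ","))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(x, 5))
  invisible(x)
}
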
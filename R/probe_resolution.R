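# Probe-to-gene resolution: symbol mapping, specificity/coding exclusions,
# and duplicate-probe collapse with a best-probe map (jetset-style input) or
# an IQR fallback.

#' Resolve surviving probes to unique gene symbols
#'
#' Applies four exclusion steps in the exclusion-flow order:
#' \enumerate{
#'   \item probes with no gene symbol ("No Gene Symbol for Probe ID"),
#'   \item non-specific probes ("Non-specific Probe IDs"),
#'   \item probes for non-coding genes ("Non-coding Genes"),
#'   \item duplicate probes per gene ("Duplicated Genes"): when
#'     `best_probe_map` names a surviving probe for the gene it is kept;
#'     otherwise the fallback keeps the probe with the largest interquartile
#'     range of expression across samples, ties broken lexicographically by
#'     probe ID.
#' }
#' After resolution gene symbols are unique and each maps to exactly one
#' probe.
#'
#' @param records Correlation records (post significance/threshold filters).
#' @param annotation Probe annotation data frame (see [read_annotation()]).
#' @param mat Expression matrix still containing the record probes, used by
#'   the IQR fallback.
#' @param best_probe_map Optional named character vector (gene -> probe ID).
#'   A map entry naming a probe that is not among the surviving duplicates
#'   triggers a warning and the fallback heuristic.
#' @param ledger Exclusion ledger to append the four steps to.
#' @return List with resolved `records` (now carrying `gene_symbol`) and the
#'   extended `ledger`.
#' @export
resolve_probes <- function(records, annotation, mat, best_probe_map = NULL,
                           ledger = new_ledger()) {
  unknown <- setdiff(records$probe_id, annotation$probe_id)
  if (length(unknown) > 0)
    stop(sprintf("probe(s) missing from annotation: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  ann <- annotation[match(records$probe_id, annotation$probe_id), ]
  records$gene_symbol <- ann$gene_symbol

  keep <- !is.na(ann$gene_symbol)
  ledger <- ledger_append(ledger, "No Gene Symbol for Probe ID",
                          nrow(records), sum(!keep))
  records <- records[keep, , drop = FALSE]; ann <- ann[keep, , drop = FALSE]

  keep <- ann$is_specific
  ledger <- ledger_append(ledger, "Non-specific Probe IDs",
                          nrow(records), sum(!keep))
  records <- records[keep, , drop = FALSE]; ann <- ann[keep, , drop = FALSE]

  keep <- ann$is_coding
  ledger <- ledger_append(ledger, "Non-coding Genes",
                          nrow(records), sum(!keep))
  records <- records[keep, , drop = FALSE]; ann <- ann[keep, , drop = FALSE]

  dup_genes <- unique(records$gene_symbol[duplicated(records$gene_symbol)])
  n_before <- nrow(records)
  drop <- character(0)
  for (g in dup_genes) {
    probes <- records$probe_id[records$gene_symbol == g]
    chosen <- NA_character_
    if (!is.null(best_probe_map) && g %in% names(best_probe_map)) {
      mapped <- unname(best_probe_map[[g]])
      if (mapped %in% probes) {
        chosen <- mapped
      } else {
        warning(sprintf(
          "best-probe map names '%s' for gene %s but it is not among the surviving probes; using IQR fallback",
          mapped, g))
      }
    }
    if (is.na(chosen)) {
      iqr <- vapply(probes, function(p) stats::IQR(mat[p, ]), numeric(1))
      ord <- order(-iqr, probes)
      chosen <- probes[ord[1]]
    }
    drop <- c(drop, setdiff(probes, chosen))
  }
  keep <- !records$probe_id %in% drop
  ledger <- ledger_append(ledger, "Duplicated Genes", n_before, sum(!keep))
  records <- records[keep, , drop = FALSE]
  stopifnot(!anyDuplicated(records$gene_symbol))
  list(records = records, ledger = ledger)
}
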
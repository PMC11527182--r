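# Causal-gene augmentation and the ontology co-membership novel-gene caller.

#' Augment a gene list with a disorder's causal genes
#'
#' Union of the list's gene symbols and the causal gene set; causal genes
#' already in the list do not increase the size.
#'
#' @param list A `threshold_list` (the disorder's optimal list) or a
#'   character vector of gene symbols.
#' @param causal_genes Character vector of causal gene symbols.
#' @return Character vector: the augmented gene set.
#' @export
augment_list <- function(list, causal_genes) {
  genes <- if (inherits(list, "threshold_list")) names(list$genes) else list
  union(toupper(genes), toupper(causal_genes))
}

#' Call novel candidate genes for one disorder
#'
#' Enriches the disorder's causal-gene-augmented optimal list against each
#' ontology library. Every term with `q < q_threshold` whose overlap with the
#' augmented list contains at least one causal gene and at least one
#' candidate — a list gene that is neither causal nor in the disorder's
#' disease-term overlap — yields a novel-gene call. Optionally the
#' co-membership requirement can be relaxed from causal genes to causal or
#' disease-overlap genes.
#'
#' @param call A disorder call from [discover_disorders()] (must carry
#'   non-empty `causal_genes` and an `optimal` entry).
#' @param ladder Output of [build_ladder()] (to fetch the optimal list's
#'   genes).
#' @param ontology_libraries List of [gene_set_library()] objects.
#' @param background Background policy (see [enrich()]).
#' @param q_threshold Adjusted significance gate (default 0.05).
#' @param require_causal If `FALSE`, a disease-overlap gene in the term also
#'   licenses candidates (default `TRUE`: a causal gene must co-occur).
#' @return List of novel-gene calls: `disorder`, `term`, `library`,
#'   `q_value`, `causal_in_term`, `candidates`, `provenance` (augmented list
#'   label).
#' @export
call_novel <- function(call, ladder, ontology_libraries,
                       background = "library-union", q_threshold = 0.05,
                       require_causal = TRUE) {
  if (length(call$causal_genes) == 0)
    stop(sprintf("disorder '%s' has no causal genes; cannot augment",
                 call$disorder))
  opt <- call$optimal
  lst <- NULL
  for (l in ladder[[opt$sign]]) if (identical(l$label, opt$list_label)) lst <- l
  if (is.null(lst)) stop(sprintf("optimal list '%s' not found in ladder",
                                 opt$list_label))
  causal <- toupper(call$causal_genes)
  augmented <- augment_list(lst, causal)
  disease_overlap <- toupper(opt$overlap_genes)
  anchors <- if (require_causal) causal else union(causal, disease_overlap)

  out <- list()
  for (lib in ontology_libraries) {
    res <- tryCatch(enrich(augmented, lib, background), error = function(e) NULL)
    if (is.null(res)) next
    for (i in seq_len(nrow(res))) {
      row <- res[i, , drop = FALSE]
      if (row$q_value >= q_threshold) next
      overlap <- row$overlap_genes[[1]]
      causal_in_term <- intersect(overlap, causal)
      if (length(intersect(overlap, anchors)) == 0) next
      candidates <- setdiff(overlap, union(causal, disease_overlap))
      if (length(causal_in_term) == 0 || length(candidates) == 0) next
      out[[length(out) + 1]] <- list(
        disorder = call$disorder, term = row$term, library = lib$name,
        q_value = row$q_value, causal_in_term = causal_in_term,
        candidates = sort(candidates),
        provenance = sprintf("%s + causal", opt$list_label))
    }
  }
  out
}

#' Call novel genes for every disorder call
#'
#' @param calls Disorder calls from [discover_disorders()]. Calls without
#'   causal genes are skipped with a warning (they cannot be augmented).
#' @inheritParams call_novel
#' @return Flat list of novel-gene calls across disorders.
#' @export
call_novel_all <- function(calls, ladder, ontology_libraries,
                           background = "library-union", q_threshold = 0.05,
                           require_causal = TRUE) {
  out <- list()
  for (call in calls) {
    if (length(call$causal_genes) == 0) {
      warning(sprintf("skipping disorder '%s': no causal genes", call$disorder))
      next
    }
    out <- c(out, call_novel(call, ladder, ontology_libraries, background,
                             q_threshold, require_causal))
  }
  out
}

#' Summarize novel-gene calls per disorder
#'
#' Deduplicates candidates across ontology terms within each disorder, and
#' reports the headline tallies: `total` sums the per-disorder unique
#' candidate counts (a gene backing several disorders counts once per
#' disorder), while `unique` counts distinct genes overall.
#'
#' @param novel_calls Output of [call_novel_all()].
#' @return List with `per_disorder` (named list disorder -> sorted candidate
#'   genes), `total`, `unique_genes`, `n_unique`.
#' @export
summarize_novel <- function(novel_calls) {
  per <- list()
  for (nc in novel_calls)
    per[[nc$disorder]] <- sort(union(per[[nc$disorder]], nc$candidates))
  uniq <- sort(unique(unlist(per, use.names = FALSE)))
  list(per_disorder = per,
       total = sum(lengths(per)),
       unique_genes = uniq,
       n_unique = length(uniq))
}
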
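# Disorder selection: inclusion criteria on signed-list enrichments,
# smallest viable list per disorder, unique discrimination by overlap +
# causal genes, and optimal parent-list attachment.

#' Does an enrichment result meet the disorder inclusion criteria?
#'
#' A disorder term qualifies on a signed list iff its BH-adjusted q is below
#' `q_threshold` and its overlap is large enough: on a positively correlated
#' list the seed gene plus at least `min_overlap - 1` other list genes must
#' be in the overlap; on a negatively correlated list (which cannot contain
#' the seed) at least `min_overlap` list genes must overlap. Unsigned (full)
#' lists are rejected: signed lists carry the same overlaps at greater
#' significance, so full lists are dropped from disorder discovery.
#'
#' @param result One row of an [enrich()] result (data frame row).
#' @param list_sign `"positive"` or `"negative"`.
#' @param seed_gene Seed gene symbol.
#' @param q_threshold Adjusted significance gate (default 0.05).
#' @param min_overlap Minimum overlap size (default 3).
#' @return Logical.
#' @export
meets_inclusion <- function(result, list_sign, seed_gene, q_threshold = 0.05,
                            min_overlap = 3) {
  if (list_sign == "full")
    stop("unsigned lists are not considered for disorder inclusion")
  list_sign <- match.arg(list_sign, c("positive", "negative"))
  overlap <- result$overlap_genes[[1]]
  if (result$q_value >= q_threshold) return(FALSE)
  if (length(overlap) < min_overlap) return(FALSE)
  if (list_sign == "positive" && !(toupper(seed_gene) %in% overlap))
    return(FALSE)
  TRUE
}

# One qualifying (disorder, list) record carried through discovery.
qualifying_entry <- function(row, lst) {
  list(term = row$term, list_label = lst$label, tau = lst$tau,
       sign = lst$sign, list_size = length(lst$genes),
       overlap_genes = row$overlap_genes[[1]],
       p_value = row$p_value, q_value = row$q_value)
}

#' Enrich every signed list of a ladder against a library
#'
#' @param ladder Output of [build_ladder()].
#' @param library A [gene_set_library()].
#' @param background Background policy (see [enrich()]).
#' @return Nested list `results[[sign]][[list_label]]` of enrichment data
#'   frames; empty signed lists are skipped.
#' @export
enrich_ladder <- function(ladder, library, background = "library-union") {
  out <- list(positive = list(), negative = list())
  for (sign in c("positive", "negative")) {
    for (lst in ladder[[sign]]) {
      if (length(lst$genes) == 0) next
      res <- tryCatch(enrich(names(lst$genes), library, background),
                      error = function(e) NULL)
      if (!is.null(res)) out[[sign]][[lst$label]] <- res
    }
  }
  out
}

#' Smallest viable list per disorder
#'
#' Scans the signed lists in ascending gene-count order (list 1, 2, ...)
#' separately within each sign and records, for every disorder, the first
#' list on which it meets the inclusion criteria. Disorders never meeting
#' inclusion are absent from the result. A disorder qualifying on both signed
#' ladders is attached to the sign where its first qualifying q is smaller.
#'
#' @param ladder Output of [build_ladder()].
#' @param library Disease gene-set library.
#' @param config A [pipeline_config()].
#' @param enrichments Optional precomputed [enrich_ladder()] results.
#' @return Named list: disorder -> qualifying entry (term, list label, tau,
#'   sign, list size, overlap genes, p, q).
#' @export
smallest_viable <- function(ladder, library, config, enrichments = NULL) {
  if (is.null(enrichments))
    enrichments <- enrich_ladder(ladder, library, config$background)
  found <- list()
  for (sign in c("positive", "negative")) {
    lists <- ladder[[sign]]
    counts <- vapply(lists, function(l) length(l$genes), integer(1))
    taus <- vapply(lists, function(l) l$tau, numeric(1))
    # equal-count rungs hold identical gene sets; prefer the tighter label
    for (lst in lists[order(counts, -taus)]) {
      res <- enrichments[[sign]][[lst$label]]
      if (is.null(res)) next
      for (i in seq_len(nrow(res))) {
        row <- res[i, , drop = FALSE]
        if (!meets_inclusion(row, sign, config$seed_gene,
                             config$q_threshold, config$min_overlap)) next
        d <- row$term
        entry <- qualifying_entry(row, lst)
        prev <- found[[d]]
        if (is.null(prev)) {
          found[[d]] <- entry
        } else if (prev$sign != sign && entry$q_value < prev$q_value) {
          found[[d]] <- entry          # cross-sign tie broken by smaller q
        }
      }
    }
  }
  found
}

#' Exclude disorders that cannot be uniquely discriminated
#'
#' Two disorders are indistinguishable iff they have identical overlap gene
#' sets on their smallest viable lists and identical causal gene sets. Every
#' member of an indistinguishable group of size >= 2 is excluded, unless a
#' merge table declares the group synonyms, in which case the group collapses
#' to a single call under the canonical name (the treatment given to
#' disorders sharing one external disease identifier).
#'
#' @param calls Named list of disorder calls (each with `causal_genes` and a
#'   `smallest_viable` entry).
#' @param merge_table Optional named character vector mapping disorder name
#'   to canonical name.
#' @return The surviving (possibly merged) calls.
#' @export
discriminate <- function(calls, merge_table = NULL) {
  if (length(calls) == 0) return(calls)
  canonical <- function(d) {
    if (!is.null(merge_table) && d %in% names(merge_table))
      unname(merge_table[[d]]) else d
  }
  # merge declared synonyms first: groups sharing a canonical name collapse
  canon <- vapply(names(calls), canonical, character(1))
  merged <- list()
  for (cn in unique(canon)) {
    group <- calls[canon == cn]
    pick <- group[[order(vapply(group, function(g) g$smallest_viable$q_value,
                                numeric(1)))[1]]]
    pick$disorder <- cn
    pick$merged_from <- names(group)
    merged[[cn]] <- pick
  }
  # then exclude residual indistinguishable groups
  key <- vapply(merged, function(g) {
    paste(paste(sort(g$smallest_viable$overlap_genes), collapse = ","),
          paste(sort(g$causal_genes), collapse = ","), sep = "|")
  }, character(1))
  keep <- key %in% names(which(table(key) == 1))
  merged[keep]
}

#' Attach the optimal parent list to a disorder call
#'
#' Among all same-sign lists on which the disorder meets inclusion, attaches
#' the one with the largest overlap, breaking ties by smaller q, then by
#' smaller list size.
#'
#' @param call A disorder call with a `smallest_viable` entry.
#' @param ladder Output of [build_ladder()].
#' @param enrichments Precomputed [enrich_ladder()] results for the disease
#'   library.
#' @param config A [pipeline_config()].
#' @return The call with an `optimal` entry attached.
#' @export
select_optimal <- function(call, ladder, enrichments, config) {
  sign <- call$smallest_viable$sign
  term <- call$smallest_viable$term
  candidates <- list()
  for (lst in ladder[[sign]]) {
    res <- enrichments[[sign]][[lst$label]]
    if (is.null(res)) next
    row <- res[res$term == term, , drop = FALSE]
    if (nrow(row) != 1) next
    if (!meets_inclusion(row, sign, config$seed_gene,
                         config$q_threshold, config$min_overlap)) next
    candidates[[lst$label]] <- qualifying_entry(row, lst)
  }
  stopifnot(length(candidates) >= 1)
  ov <- vapply(candidates, function(e) length(e$overlap_genes), integer(1))
  qv <- vapply(candidates, function(e) e$q_value, numeric(1))
  sz <- vapply(candidates, function(e) e$list_size, integer(1))
  tv <- vapply(candidates, function(e) e$tau, numeric(1))
  best <- order(-ov, qv, sz, -tv)[1]
  call$optimal <- candidates[[best]]
  call
}

#' Run the full disorder-discovery stage
#'
#' Enriches every signed list against the disease library, finds each
#' disorder's smallest viable list, attaches causal genes, excludes
#' non-discriminable disorders (merging declared synonyms), and attaches the
#' optimal parent list to each survivor.
#'
#' @param ladder Output of [build_ladder()].
#' @param disease_library Disease [gene_set_library()].
#' @param causal_map Named list disorder -> causal gene symbols; disorders
#'   absent from the map get an empty causal set.
#' @param config A [pipeline_config()].
#' @param merge_table Optional synonym map (see [discriminate()]).
#' @return Named list of disorder calls, each with `disorder`,
#'   `causal_genes`, `smallest_viable`, `optimal`, `discriminated = TRUE`.
#' @export
discover_disorders <- function(ladder, disease_library, causal_map, config,
                               merge_table = NULL) {
  enrichments <- enrich_ladder(ladder, disease_library, config$background)
  sv <- smallest_viable(ladder, disease_library, config, enrichments)
  calls <- lapply(names(sv), function(d) {
    causal <- if (d %in% names(causal_map)) toupper(causal_map[[d]]) else character(0)
    list(disorder = d, causal_genes = causal, smallest_viable = sv[[d]])
  })
  names(calls) <- names(sv)
  calls <- discriminate(calls, merge_table)
  calls <- lapply(calls, select_optimal, ladder = ladder,
                  enrichments = enrichments, config = config)
  for (d in names(calls)) calls[[d]]$discriminated <- TRUE
  calls
}
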
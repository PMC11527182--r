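# Over-representation analysis of a gene list against a GMT library:
# one-sided hypergeometric p per term, BH-adjusted q across the library's
# tested terms.

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} where X counts library-term genes drawn into a query of
#' size `n_list` from a background of `N_bg` genes of which `K_term` carry
#' the term. Evaluated in log space via the hypergeometric distribution
#' function, so it is numerically stable for large backgrounds.
#'
#' @param k Observed overlap count(s); vectorized.
#' @param n_list Query size (genes of the list present in the background).
#' @param K_term Term size within the background.
#' @param N_bg Background universe size.
#' @return The upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, n_list, K_term, N_bg) {
  if (any(k < 0) || any(n_list < 0) || any(K_term < 0) || any(N_bg < 1))
    stop("counts must be non-negative with N_bg >= 1")
  if (any(n_list > N_bg) || any(K_term > N_bg))
    stop("query and term must fit inside the background")
  if (any(k > pmin(n_list, K_term)))
    stop("overlap k cannot exceed min(n_list, K_term)")
  stats::phyper(k - 1, K_term, N_bg - K_term, n_list, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment: on the sorted scale
#' \eqn{q_{(i)} = \min_{j \ge i} (p_{(j)} m / j)} capped at 1, mapped back to
#' the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Resolve a background policy into a gene universe
#'
#' @param background `"library-union"` (default: the union of all genes in
#'   the library under test), a single integer (a fixed universe size, e.g.
#'   20003 to mimic a fixed enrichment-server background), or a character
#'   vector of gene symbols.
#' @param library The gene-set library under test.
#' @return A list with `genes` (character vector or NULL when only a size is
#'   known) and `size`.
#' @keywords internal
resolve_background <- function(background, library) {
  if (is.character(background) && length(background) == 1 &&
      background == "library-union") {
    genes <- unique(toupper(unlist(library$terms, use.names = FALSE)))
    return(list(genes = genes, size = length(genes)))
  }
  if (is.numeric(background) && length(background) == 1) {
    size <- as.integer(background)
    if (size < 1) stop("background size must be positive")
    return(list(genes = NULL, size = size))
  }
  if (is.character(background)) {
    genes <- unique(toupper(background))
    return(list(genes = genes, size = length(genes)))
  }
  stop("background must be 'library-union', an integer size, or a gene vector")
}

#' Enrich a query gene set against a GMT library
#'
#' One result per library term overlapping the query (k >= 1): the overlap
#' genes, the one-sided hypergeometric p, and the BH-adjusted q computed
#' across all tested (k >= 1) terms of this library for this query. Results
#' are sorted by q, then p, then term name.
#'
#' When the background is an explicit gene set, the query and each term are
#' intersected with it before counting; when it is a bare size, genes are
#' counted as-is against that universe size.
#'
#' @param query Character vector of gene symbols (uppercased internally).
#' @param library A [gene_set_library()].
#' @param background Background policy, see [resolve_background()].
#' @return Data frame with columns `term`, `library`, `overlap_genes`
#'   (list-column), `k`, `n_list`, `K_term`, `N_bg`, `p_value`, `q_value`,
#'   `odds_ratio`.
#' @export
enrich <- function(query, library, background = "library-union") {
  query <- unique(toupper(query))
  if (length(query) == 0) stop("query gene set is empty")
  bg <- resolve_background(background, library)
  if (is.null(bg$genes)) {
    q_in_bg <- query
  } else {
    q_in_bg <- intersect(query, bg$genes)
  }
  n_list <- length(q_in_bg)
  if (n_list == 0)
    stop("query is disjoint from the enrichment background")
  if (n_list > bg$size) stop("query larger than the background universe")

  rows <- lapply(names(library$terms), function(tn) {
    term <- library$terms[[tn]]
    if (!is.null(bg$genes)) term <- intersect(term, bg$genes)
    K <- length(term)
    ov <- intersect(q_in_bg, term)
    k <- length(ov)
    if (k == 0 || K == 0) return(NULL)
    p <- hypergeom_upper_tail(k, n_list, K, bg$size)
    # odds ratio of the 2x2 table (0.5 continuity only when a cell is empty)
    a <- k; b <- n_list - k; cc <- K - k; d <- bg$size - n_list - K + k
    if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    data.frame(term = tn, library = library$name,
               overlap_genes = I(list(sort(ov))), k = k, n_list = n_list,
               K_term = K, N_bg = bg$size, p_value = p,
               odds_ratio = (a * d) / (b * cc),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(term = character(0), library = character(0),
                      k = integer(0), n_list = integer(0), K_term = integer(0),
                      N_bg = integer(0), p_value = numeric(0),
                      odds_ratio = numeric(0))
    out$overlap_genes <- list()
    out$q_value <- numeric(0)
    return(out)
  }
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res <- res[order(res$q_value, res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
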
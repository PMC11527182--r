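# ---- Pipeline configuration -------------------------------------------------

#' Pipeline configuration
#'
#' Collects every tunable the screening pipeline uses. Defaults are the
#' study conditions the package emulates: alpha = 0.05 Bonferroni-corrected
#' by the sample count (giving alpha_cor = 2.3e-5 at n = 2158), a correlation
#' threshold ladder from |rho| = 0.34 to 0.41 in 0.01 steps, an adjusted
#' significance gate of q < 0.05 with a minimum overlap of 3 genes, and 1000
#' bootstrap resamples for cluster support.
#'
#' @param seed_probe_id Probe ID of the seed gene's reference probe.
#' @param seed_gene Gene symbol of the seed gene.
#' @param alpha Nominal significance level before multiple-testing correction.
#' @param bonferroni_divisor Divisor for the Bonferroni correction of the
#'   correlation t-test; `NULL` (default) uses the sample count of the matrix
#'   being analysed. The printed alpha_cor = 2.3e-5 corresponds to dividing
#'   by the 2158 samples rather than the 54,675 probes; the divisor is
#'   exposed so either convention can be requested explicitly.
#' @param alpha_norm Significance level of the Jarque-Bera screen.
#' @param tau_min,tau_max,tau_step Absolute-correlation threshold ladder.
#' @param q_threshold Adjusted-p (BH) significance gate for enrichment calls.
#' @param min_overlap Minimum overlap genes for disorder inclusion.
#' @param nboot Bootstrap resamples for cluster support.
#' @param background Background policy for enrichment: `"library-union"`, an
#'   integer background size, or an explicit character vector of gene symbols.
#' @param sample_corrected Use bias-corrected moments in the Jarque-Bera
#'   screen.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed_probe_id, seed_gene,
                            alpha = 0.05, bonferroni_divisor = NULL,
                            alpha_norm = 0.05,
                            tau_min = 0.34, tau_max = 0.41, tau_step = 0.01,
                            q_threshold = 0.05, min_overlap = 3,
                            nboot = 1000, background = "library-union",
                            sample_corrected = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (tau_min > tau_max) stop("tau_min must not exceed tau_max")
  if (tau_step <= 0) stop("tau_step must be positive")
  seed_gene <- toupper(seed_gene)
  structure(list(seed_probe_id = seed_probe_id, seed_gene = seed_gene,
                 alpha = alpha, bonferroni_divisor = bonferroni_divisor,
                 alpha_norm = alpha_norm,
                 tau_min = tau_min, tau_max = tau_max, tau_step = tau_step,
                 q_threshold = q_threshold, min_overlap = min_overlap,
                 nboot = nboot, background = background,
                 sample_corrected = sample_corrected),
            class = "pipeline_config")
}

#' Threshold rungs of the correlation ladder
#' @param config A [pipeline_config()].
#' @return Numeric vector of |rho| thresholds, ascending.
#' @export
ladder_taus <- function(config) {
  taus <- seq(config$tau_min, config$tau_max, by = config$tau_step)
  round(taus, 10)
}

# ---- Correlation against the seed -------------------------------------------

#' Pearson correlation of every probe against the seed probe
#'
#' Standard product-moment correlation over all samples, one record per
#' non-seed probe, with the two-tail t-test p-value attached
#' (see [correlation_pvalue()]).
#'
#' @param mat An expression matrix that still contains the seed probe.
#' @param seed_probe Probe ID of the seed.
#' @return Data frame with columns `probe_id`, `rho`, `t_statistic`,
#'   `p_value`, `n`.
#' @export
pearson_vs_seed <- function(mat, seed_probe) {
  if (!seed_probe %in% rownames(mat))
    stop(sprintf("seed probe '%s' is absent from the matrix (excluded upstream?)",
                 seed_probe))
  seed <- mat[seed_probe, ]
  others <- rownames(mat)[rownames(mat) != seed_probe]
  rho <- as.numeric(stats::cor(seed, t(mat[others, , drop = FALSE])))
  # clamp tiny float excursions outside [-1, 1]
  rho <- pmin(1, pmax(-1, rho))
  n <- ncol(mat)
  tp <- correlation_pvalue(rho, n)
  data.frame(probe_id = others, rho = rho, t_statistic = tp$t_statistic,
             p_value = tp$p_value, n = n, stringsAsFactors = FALSE)
}

#' Two-tail t-test p-value for a Pearson correlation
#'
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} referred to a t distribution with
#' n - 2 degrees of freedom, two-tailed. Perfect correlations (|rho| = 1)
#' return p = 0.
#'
#' @param rho Correlation(s) in `[-1, 1]`.
#' @param n Sample count (>= 3).
#' @return List with `t_statistic` and `p_value` vectors.
#' @export
correlation_pvalue <- function(rho, n) {
  if (n < 3) stop("correlation t-test needs at least 3 samples")
  if (any(abs(rho) > 1)) stop("rho must lie in [-1, 1]")
  t_stat <- ifelse(abs(rho) == 1, sign(rho) * Inf,
                   rho * sqrt((n - 2) / (1 - rho^2)))
  p <- ifelse(abs(rho) == 1, 0, 2 * stats::pt(-abs(t_stat), df = n - 2))
  list(t_statistic = t_stat, p_value = p)
}

#' Bonferroni-adjusted significance threshold
#' @param alpha Nominal level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (length(m) != 1 || m < 1) stop("m must be a positive count")
  alpha / m
}

#' Drop correlation records failing the adjusted significance level
#'
#' Exclusion is strict: records with `p > alpha_cor` are removed, a record at
#' exactly `alpha_cor` is retained.
#'
#' @param records Correlation records from [pearson_vs_seed()].
#' @param alpha_cor Bonferroni-adjusted level.
#' @param ledger Exclusion ledger to append to.
#' @return List with surviving `records` and the extended `ledger`.
#' @export
filter_significant <- function(records, alpha_cor, ledger = new_ledger()) {
  keep <- records$p_value <= alpha_cor
  label <- sprintf("Failed Pearson correlation two-tail t-test (alpha_cor = %.3g)",
                   alpha_cor)
  ledger <- ledger_append(ledger, label, nrow(records), sum(!keep))
  list(records = records[keep, , drop = FALSE], ledger = ledger)
}

#' Drop correlation records below the ladder's loosest threshold
#'
#' Probe-level analogue of the exclusion-flow step `rho < tau_min`: records
#' with `|rho| < tau_min` (rho rounded to 10 decimals) are removed before
#' probe-to-gene resolution.
#'
#' @param records Correlation records.
#' @param tau_min Loosest absolute-correlation threshold.
#' @param ledger Exclusion ledger to append to.
#' @return List with surviving `records` and the extended `ledger`.
#' @export
filter_rho_threshold <- function(records, tau_min, ledger = new_ledger()) {
  keep <- abs(round(records$rho, 10)) >= round(tau_min, 10)
  ledger <- ledger_append(ledger,
                          sprintf("Failed Pearson rho threshold (rho < %.2f)", tau_min),
                          nrow(records), sum(!keep))
  list(records = records[keep, , drop = FALSE], ledger = ledger)
}

# ---- Threshold ladder -------------------------------------------------------

#' Construct a threshold gene list
#' @param label List label, e.g. `"list 2"`, `"list 2+"`.
#' @param tau Absolute-correlation threshold of the list.
#' @param sign One of `"full"`, `"positive"`, `"negative"`.
#' @param genes Named numeric vector of rho values (names = gene symbols).
#' @return A `threshold_list` object; members ordered by descending |rho|.
#' @keywords internal
threshold_list <- function(label, tau, sign, genes) {
  sign <- match.arg(sign, c("full", "positive", "negative"))
  genes <- genes[order(-abs(genes), names(genes))]
  structure(list(label = label, tau = tau, sign = sign, genes = genes),
            class = "threshold_list")
}

#' @export
print.threshold_list <- function(x, ...) {
  cat(sprintf("<threshold_list '%s'> tau=%.2f sign=%s genes=%d\n",
              x$label, x$tau, x$sign, length(x$genes)))
  invisible(x)
}

#' Build the nested signed threshold ladder
#'
#' From resolved correlation records (one gene symbol per record), builds the
#' full gene list at every |rho| threshold of the ladder, numbers the full
#' lists in ascending order by gene count (the tightest threshold is list 1),
#' and splits each into its positive and negative signed sub-lists. The seed
#' gene itself (rho = 1 with itself by definition) is a member of every full
#' and positive list. Threshold comparisons use rho rounded to 10 decimals so
#' float representation cannot flip a boundary case; membership is
#' `|rho| >= tau`.
#'
#' @param records Resolved correlation records with `gene_symbol` and `rho`.
#' @param config A [pipeline_config()].
#' @param ledger Optional exclusion ledger: when supplied, the sub-threshold
#'   exclusion (`rho < tau_min`) and the per-rung narrowing steps are
#'   appended, mirroring the exclusion-flow table layout.
#' @return List with `full`, `positive`, `negative` (each a list of
#'   `threshold_list` in ladder order, i.e. largest list first), and `ledger`.
#' @export
build_ladder <- function(records, config, ledger = NULL) {
  if (is.null(records$gene_symbol))
    stop("records must carry resolved gene symbols (run resolve_probes first)")
  genes <- setNames(records$rho, records$gene_symbol)
  genes[config$seed_gene] <- 1.0
  rho_r <- round(genes, 10)
  taus <- ladder_taus(config)
  n_rungs <- length(taus)

  member_sets <- lapply(taus, function(tau) genes[abs(rho_r) >= tau])
  counts <- lengths(member_sets)
  if (counts[1] == 0)
    warning(sprintf("no genes at the loosest threshold |rho| >= %.2f", taus[1]))

  if (!is.null(ledger) && n_rungs > 1) {
    # rung-narrowing steps: from the list at tau_i, drop |rho| < tau_{i+1}
    for (i in seq_len(n_rungs - 1)) {
      ledger <- ledger_append(ledger, sprintf("rho < %.2f", taus[i + 1]),
                              counts[i], counts[i] - counts[i + 1])
    }
  }

  # list number = rank by ascending gene count: tightest threshold is list 1
  full <- vector("list", n_rungs)
  positive <- vector("list", n_rungs)
  negative <- vector("list", n_rungs)
  for (i in seq_len(n_rungs)) {
    number <- n_rungs - i + 1L           # tau ascending -> list number descending
    members <- member_sets[[i]]
    fl <- threshold_list(sprintf("list %d", number), taus[i], "full", members)
    parts <- split_signed(fl)
    full[[i]] <- fl
    positive[[i]] <- parts$positive
    negative[[i]] <- parts$negative
  }
  list(full = full, positive = positive, negative = negative, ledger = ledger)
}

#' Split a full threshold list into signed sub-lists
#'
#' Partitions members by the sign of rho into the `X+` and `X-` lists; the
#' union of the parts is the full list and the parts are disjoint. A zero
#' correlation cannot survive the significance filter, so it is rejected
#' defensively.
#'
#' @param list A full (unsigned) `threshold_list`.
#' @return List with `positive` and `negative` `threshold_list` objects.
#' @export
split_signed <- function(list) {
  if (!identical(list$sign, "full"))
    stop("split_signed expects a full (unsigned) list")
  if (any(list$genes == 0))
    stop("zero correlation in a threshold list: cannot assign a sign")
  pos <- list$genes[list$genes > 0]
  neg <- list$genes[list$genes < 0]
  number <- sub("^list ", "", list$label)
  list(positive = threshold_list(sprintf("list %s+", number), list$tau,
                                 "positive", pos),
       negative = threshold_list(sprintf("list %s-", number), list$tau,
                                 "negative", neg))
}
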
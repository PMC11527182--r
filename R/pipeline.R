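# End-to-end orchestration: QC -> seed correlation -> significance filter ->
# probe resolution -> threshold ladder -> disease enrichment -> disorder
# discovery -> causal augmentation / novel genes -> bootstrap robustness.

#' Run the full screening pipeline on in-memory objects
#'
#' Stages execute in the workflow order with every exclusion appended to one
#' ledger: Jarque-Bera normality screen, Pearson correlation of all probes
#' against the seed probe (the seed's own record, rho = 1, is carried so the
#' seed gene reaches every positive list), Bonferroni-adjusted two-tail t
#' filter, |rho| threshold, probe-to-gene resolution, ladder construction,
#' disease-library enrichment with disorder selection, causal-gene
#' augmentation with ontology novel-gene calling, and (optionally) bootstrap
#' robustness of the loosest full list.
#'
#' @param mat An [expression_matrix()] containing the seed probe.
#' @param annotation Probe annotation data frame.
#' @param disease_library Disease [gene_set_library()].
#' @param ontology_libraries A [gene_set_library()] or list of them.
#' @param causal_map Named list disorder -> causal genes.
#' @param config A [pipeline_config()].
#' @param best_probe_map Optional named vector gene -> preferred probe.
#' @param merge_table Optional synonym map for [discriminate()].
#' @param run_robustness Run the bootstrap clustering stage (default TRUE).
#' @param rng_seed Integer seed for the bootstrap stage.
#' @return A list with `ledger`, `records` (resolved correlation records),
#'   `ladder`, `disorder_calls`, `novel_calls`, `novel_summary`,
#'   `robustness` (`NULL` when skipped), `alpha_cor`, and `config`.
#' @export
run_pipeline <- function(mat, annotation, disease_library, ontology_libraries,
                         causal_map, config, best_probe_map = NULL,
                         merge_table = NULL, run_robustness = TRUE,
                         rng_seed = 1L) {
  if (inherits(ontology_libraries, "gene_set_library"))
    ontology_libraries <- list(ontology_libraries)

  qc <- filter_normality(mat, config$alpha_norm, new_ledger(),
                         config$sample_corrected,
                         exempt = config$seed_probe_id)
  ledger <- qc$ledger
  if (!config$seed_probe_id %in% rownames(qc$matrix))
    stop(sprintf("seed probe '%s' was excluded by the normality screen",
                 config$seed_probe_id))

  records <- pearson_vs_seed(qc$matrix, config$seed_probe_id)
  seed_row <- data.frame(probe_id = config$seed_probe_id, rho = 1,
                         t_statistic = Inf, p_value = 0, n = ncol(qc$matrix),
                         stringsAsFactors = FALSE)
  records <- rbind(seed_row, records)

  divisor <- config$bonferroni_divisor
  if (is.null(divisor)) divisor <- ncol(mat)
  alpha_cor <- bonferroni_threshold(config$alpha, divisor)

  sig <- filter_significant(records, alpha_cor, ledger)
  thr <- filter_rho_threshold(sig$records, config$tau_min, sig$ledger)
  res <- resolve_probes(thr$records, annotation, qc$matrix, best_probe_map,
                        thr$ledger)
  ladder <- build_ladder(res$records, config, res$ledger)
  ledger <- ladder$ledger

  disorder_calls <- discover_disorders(ladder, disease_library, causal_map,
                                       config, merge_table)
  callable <- Filter(function(c) length(c$causal_genes) > 0, disorder_calls)
  novel_calls <- call_novel_all(callable, ladder, ontology_libraries,
                                config$background, config$q_threshold)
  novel_summary <- summarize_novel(novel_calls)

  robustness <- NULL
  if (run_robustness) {
    full <- ladder$full[[1]]          # loosest threshold: the largest list
    genes <- names(full$genes)
    if (length(genes) >= 3) {
      gm <- gene_matrix(qc$matrix, res$records, config)
      genes <- intersect(genes, rownames(gm))
      support <- bootstrap_support(gm, genes, nboot = config$nboot,
                                   rng_seed = rng_seed)
      robustness <- list(support = support,
                         separation = sign_separation(support, full$genes))
    }
  }

  list(ledger = ledger, records = res$records, ladder = ladder,
       disorder_calls = disorder_calls, novel_calls = novel_calls,
       novel_summary = novel_summary, robustness = robustness,
       alpha_cor = alpha_cor, config = config)
}

# Expression submatrix keyed by resolved gene symbols (seed gene included).
gene_matrix <- function(mat, resolved_records, config) {
  probes <- resolved_records$probe_id
  symbols <- resolved_records$gene_symbol
  if (!config$seed_gene %in% symbols) {
    probes <- c(probes, config$seed_probe_id)
    symbols <- c(symbols, config$seed_gene)
  }
  gm <- mat[probes, , drop = FALSE]
  rownames(gm) <- symbols
  gm
}

#' Run the pipeline from a fixture/input directory
#'
#' Reads the six artifacts written by [simulate_study()] (or assembled by
#' hand in the same formats), runs [run_pipeline()], and writes the reports
#' plus a run manifest into `out_dir`.
#'
#' @param input_dir Directory with `expression.tsv`, `annotation.tsv`,
#'   `disease.gmt`, `ontology.gmt`, `causal_map.tsv`.
#' @param config A [pipeline_config()].
#' @param out_dir Report directory.
#' @param ... Passed to [run_pipeline()].
#' @return The [run_pipeline()] result, with `manifest` attached.
#' @export
run_pipeline_dir <- function(input_dir, config, out_dir, ...) {
  t0 <- Sys.time()
  paths <- file.path(input_dir, c("expression.tsv", "annotation.tsv",
                                  "disease.gmt", "ontology.gmt",
                                  "causal_map.tsv"))
  names(paths) <- c("expression", "annotation", "disease", "ontology",
                    "causal_map")
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  mat <- read_expression(paths["expression"])
  annotation <- read_annotation(paths["annotation"])
  disease <- read_gmt(paths["disease"], name = "disease")
  ontology <- read_gmt(paths["ontology"], name = "ontology")
  causal_map <- read_causal_map(paths["causal_map"])

  result <- run_pipeline(mat, annotation, disease, ontology, causal_map,
                         config, ...)
  files <- write_reports(result, out_dir)
  if (!is.null(result$robustness)) {
    nw <- file.path(out_dir, "robustness.nwk")
    write_support_newick(result$robustness$support, nw)
    files <- c(files, nw)
  }
  result$manifest <- list(
    config = unclass(config),
    inputs = vapply(paths, function(p) unname(tools::md5sum(p)), character(1)),
    outputs = files,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  result
}
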
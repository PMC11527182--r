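# ---- Expression matrices ----------------------------------------------------

#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix of normalized, log-scale
#' intensities with unique probe IDs as row names and unique sample IDs as
#' column names. Every cell must be present (no `NA`), and at least three
#' samples are required for any downstream correlation work.
#'
#' @param values Numeric matrix with rownames (probes) and colnames (samples).
#' @return The validated matrix, invisibly classed as `expression_matrix`.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  probes <- rownames(values)
  samples <- colnames(values)
  if (is.null(probes) || is.null(samples))
    stop("expression matrix must carry probe rownames and sample colnames")
  dup <- probes[duplicated(probes)]
  if (length(dup) > 0)
    stop(sprintf("duplicate probe ID(s): %s", paste(unique(dup), collapse = ", ")))
  if (anyDuplicated(samples))
    stop("duplicate sample IDs in expression matrix")
  if (anyNA(values))
    stop("expression matrix contains missing values; complete matrices are required")
  if (ncol(values) < 3)
    stop("expression matrix needs at least 3 samples")
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample IDs and a first column of probe IDs.
#' Parsing is strict: duplicate probe IDs, ragged rows and non-numeric cells
#' are hard errors that name the offending probe or coordinate. Row and
#' column order are preserved from the file.
#'
#' @param path Path to a tab-delimited text file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("expression file must have a header and >= 1 probe row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- header[-1]
  n_s <- length(samples)
  body <- fields[-1]
  probes <- vapply(body, `[[`, character(1), 1L)
  dup <- probes[duplicated(probes)]
  if (length(dup) > 0)
    stop(sprintf("duplicate probe ID(s) in %s: %s", path, paste(unique(dup), collapse = ", ")))
  widths <- lengths(body)
  bad <- which(widths != n_s + 1L)
  if (length(bad) > 0)
    stop(sprintf("ragged row for probe '%s' (line %d): %d value(s), expected %d",
                 probes[bad[1]], bad[1] + 1L, widths[bad[1]] - 1L, n_s))
  raw <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    i <- which(is.na(vals))[1]
    row <- ((i - 1L) %/% n_s) + 1L
    col <- ((i - 1L) %% n_s) + 1L
    stop(sprintf("non-numeric cell '%s' at probe '%s', sample '%s'",
                 raw[i], probes[row], samples[col]))
  }
  m <- matrix(vals, nrow = length(probes), ncol = n_s, byrow = TRUE,
              dimnames = list(probes, samples))
  expression_matrix(m)
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are serialized at full double precision (17 significant digits)
#' so a write/read round trip is exact.
#'
#' @param mat An expression matrix.
#' @param path Output file path.
#' @export
write_expression <- function(mat, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

# ---- GMT gene-set libraries -------------------------------------------------

#' Construct a gene-set library
#'
#' @param name Library name (e.g. a disease or ontology library label).
#' @param terms Named list mapping term name to a character vector of gene
#'   symbols; symbols are uppercased, sets must be non-empty, term names
#'   unique.
#' @param descriptions Optional named character vector of term descriptions.
#' @return A `gene_set_library` object.
#' @export
gene_set_library <- function(name, terms, descriptions = NULL) {
  if (anyDuplicated(names(terms)))
    stop("duplicate term names in gene-set library")
  terms <- lapply(terms, function(g) unique(toupper(as.character(g))))
  if (any(lengths(terms) == 0))
    stop("every term must contain at least one gene symbol")
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(terms)), names(terms))
  }
  structure(list(name = name, terms = terms,
                 descriptions = descriptions[names(terms)]),
            class = "gene_set_library")
}

#' Read a GMT gene-set library
#'
#' Standard GMT dialect: each line is `term TAB description TAB gene...`.
#' Blank trailing fields are dropped and symbols uppercased. Lines with
#' fewer than three fields and duplicate terms are hard errors.
#'
#' @param path Path to a GMT file.
#' @param name Library name; defaults to the file name without extension.
#' @return A [gene_set_library()].
#' @export
read_gmt <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) f[nzchar(f)])
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  term_names <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(term_names))
    stop(sprintf("duplicate GMT term: %s",
                 term_names[duplicated(term_names)][1]))
  terms <- lapply(fields, function(f) f[-(1:2)])
  names(terms) <- term_names
  descriptions <- setNames(vapply(fields, `[[`, character(1), 2L), term_names)
  gene_set_library(name, terms, descriptions)
}

#' Write a gene-set library in GMT format
#'
#' @param library A [gene_set_library()].
#' @param path Output file path.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library$terms), function(tn) {
    paste(c(tn, library$descriptions[[tn]], library$terms[[tn]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- Probe annotation -------------------------------------------------------

#' Read a platform annotation table
#'
#' Tab-delimited table with header columns `probe_id`, `gene_symbol`,
#' `is_specific`, `is_coding`. An empty symbol field marks the probe as
#' unmappable (`NA` symbol). Duplicate probe rows are a hard error.
#'
#' @param path Path to the annotation TSV.
#' @return A data frame with columns `probe_id`, `gene_symbol` (NA when
#'   unmappable), `is_specific`, `is_coding`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "gene_symbol", "is_specific", "is_coding")
  if (!all(need %in% names(df)))
    stop(sprintf("annotation table must have columns: %s", paste(need, collapse = ", ")))
  if (anyDuplicated(df$probe_id))
    stop(sprintf("duplicate annotation row for probe '%s'",
                 df$probe_id[duplicated(df$probe_id)][1]))
  sym <- toupper(trimws(df$gene_symbol))
  sym[!nzchar(sym)] <- NA_character_
  data.frame(probe_id = df$probe_id,
             gene_symbol = sym,
             is_specific = df$is_specific %in% c("1", "TRUE", "true"),
             is_coding = df$is_coding %in% c("1", "TRUE", "true"),
             stringsAsFactors = FALSE)
}

#' Write a platform annotation table
#' @param annotation Annotation data frame as returned by [read_annotation()].
#' @param path Output file path.
#' @export
write_annotation <- function(annotation, path) {
  out <- data.frame(probe_id = annotation$probe_id,
                    gene_symbol = ifelse(is.na(annotation$gene_symbol), "",
                                         annotation$gene_symbol),
                    is_specific = as.integer(annotation$is_specific),
                    is_coding = as.integer(annotation$is_coding))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- Causal-gene maps -------------------------------------------------------

#' Read a disorder-to-causal-gene map
#'
#' Tab-delimited, two columns: disorder name, then semicolon-separated causal
#' gene symbols (uppercased on read). Empty causal sets and duplicate
#' disorders are hard errors.
#'
#' @param path Path to the TSV.
#' @return A named list mapping disorder name to a character vector of causal
#'   gene symbols.
#' @export
read_causal_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2)
    stop("causal map must have two columns: disorder, causal_genes")
  disorders <- df[[1]]
  if (anyDuplicated(disorders))
    stop(sprintf("duplicate disorder in causal map: %s",
                 disorders[duplicated(disorders)][1]))
  genes <- lapply(df[[2]], function(s) {
    g <- toupper(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
    g <- g[nzchar(g)]
    g
  })
  empty <- which(lengths(genes) == 0)
  if (length(empty) > 0)
    stop(sprintf("empty causal gene set for disorder '%s'", disorders[empty[1]]))
  setNames(genes, disorders)
}

#' Write a disorder-to-causal-gene map
#' @param causal_map Named list as returned by [read_causal_map()].
#' @param path Output file path.
#' @export
write_causal_map <- function(causal_map, path) {
  out <- data.frame(disorder = names(causal_map),
                    causal_genes = vapply(causal_map, paste, character(1),
                                          collapse = ";"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a best-probe map (gene to preferred probe)
#'
#' Two-column TSV (`gene_symbol`, `probe_id`), the external stand-in for a
#' chip-specific best-probe scoring such as jetset's.
#'
#' @param path Path to the TSV.
#' @return Named character vector mapping gene symbol to probe ID.
#' @export
read_best_probe_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("best-probe map must have two columns: gene, probe")
  setNames(df[[2]], toupper(df[[1]]))
}

# ---- Reports ----------------------------------------------------------------

#' Write pipeline reports as deterministic TSV files
#'
#' Emits up to three files into `out_dir`, headers always present even when a
#' stage produced nothing:
#' \describe{
#'   \item{exclusion_ledger.tsv}{columns `criterion`, `n_before`,
#'     `n_excluded` — the probe/gene exclusion flow.}
#'   \item{disorders.tsv}{columns `disorder`, `list_label`, `rho_threshold`,
#'     `list_size`, `overlap`, `overlap_genes`, `p_value`, `q_value`,
#'     `row_type` (`smallest_viable` or `optimal`).}
#'   \item{novel_genes.tsv}{columns `disorder`, `term`, `library`,
#'     `causal_in_term`, `candidates`, `q_value`.}
#' }
#'
#' @param results A list with any of `ledger` (an exclusion ledger),
#'   `disorder_calls` (from [discover_disorders()]), `novel_calls` (from
#'   [call_novel()] / [call_novel_all()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the character vector of files written.
#' @export
write_reports <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir))
  written <- character(0)

  ledger <- results$ledger
  if (is.null(ledger)) ledger <- new_ledger()
  path <- file.path(out_dir, "exclusion_ledger.tsv")
  utils::write.table(as.data.frame(unclass(ledger)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  written <- c(written, path)

  path <- file.path(out_dir, "disorders.tsv")
  utils::write.table(disorder_table(results$disorder_calls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  written <- c(written, path)

  path <- file.path(out_dir, "novel_genes.tsv")
  utils::write.table(novel_gene_table(results$novel_calls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  written <- c(written, path)

  invisible(written)
}

#' Read back an exclusion ledger written by [write_reports()]
#' @param path Path to `exclusion_ledger.tsv`.
#' @return An exclusion ledger data frame.
#' @export
read_ledger <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c("character", "integer", "integer"))
  lg <- new_ledger()
  for (i in seq_len(nrow(df)))
    lg <- ledger_append(lg, df$criterion[i], df$n_before[i], df$n_excluded[i])
  lg
}

# Table 2-shaped disorder report: one row per (disorder, list) with the
# smallest-viable row first and the optimal row flagged.
disorder_table <- function(calls) {
  empty <- data.frame(disorder = character(0), list_label = character(0),
                      rho_threshold = numeric(0), list_size = integer(0),
                      overlap = integer(0), overlap_genes = character(0),
                      p_value = numeric(0), q_value = numeric(0),
                      row_type = character(0))
  if (is.null(calls) || length(calls) == 0) return(empty)
  rows <- lapply(calls, function(call) {
    row_of <- function(entry, type) {
      data.frame(disorder = call$disorder,
                 list_label = entry$list_label,
                 rho_threshold = entry$tau,
                 list_size = entry$list_size,
                 overlap = length(entry$overlap_genes),
                 overlap_genes = paste(sort(entry$overlap_genes), collapse = ";"),
                 p_value = entry$p_value, q_value = entry$q_value,
                 row_type = type)
    }
    sv <- row_of(call$smallest_viable, "smallest_viable")
    if (identical(call$optimal$list_label, call$smallest_viable$list_label))
      return(rbind(sv, row_of(call$optimal, "optimal")))
    rbind(sv, row_of(call$optimal, "optimal"))
  })
  do.call(rbind, rows)
}

novel_gene_table <- function(calls) {
  empty <- data.frame(disorder = character(0), term = character(0),
                      library = character(0), causal_in_term = character(0),
                      candidates = character(0), q_value = numeric(0))
  if (is.null(calls) || length(calls) == 0) return(empty)
  do.call(rbind, lapply(calls, function(nc) {
    data.frame(disorder = nc$disorder, term = nc$term, library = nc$library,
               causal_in_term = paste(sort(nc$causal_in_term), collapse = ";"),
               candidates = paste(sort(nc$candidates), collapse = ";"),
               q_value = nc$q_value)
  }))
}
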
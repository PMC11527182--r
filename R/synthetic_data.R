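# Synthetic expression matrices and gene-set libraries with planted ground
# truth: seed-correlated genes at chosen population correlations, independent
# background genes, skewed contaminant probes, duplicate probes, annotation
# defects, and disease/ontology terms with planted causal and novel genes.

#' Default planted correlation structure
#'
#' Twelve positively and eight negatively seed-correlated genes. Members and
#' novel genes of the planted disorders sit at |rho| in 0.49-0.60 — far
#' enough above the 0.41 top rung of the default ladder that estimation
#' noise at n = 2158 (s.e. about 0.017) cannot push them below it — while
#' the remaining genes ladder down through 0.34-0.44 to populate every rung.
#'
#' @return Named numeric vector gene symbol -> target population rho.
#' @export
default_planted <- function() {
  c(SCP01 = 0.60, SCP02 = 0.58, SCP03 = 0.56, SCP04 = 0.54, SCP05 = 0.52,
    SCP06 = 0.50, SCP07 = 0.49, SCP08 = 0.44, SCP09 = 0.41, SCP10 = 0.38,
    SCP11 = 0.36, SCP12 = 0.34,
    SCN01 = -0.58, SCN02 = -0.55, SCN03 = -0.52, SCN04 = -0.50,
    SCN05 = -0.44, SCN06 = -0.40, SCN07 = -0.37, SCN08 = -0.35)
}

#' Synthetic study configuration
#'
#' Defaults emulate the structure of the cohort the pipeline was designed
#' for: 2158 samples, a single seed probe on a log2 intensity scale, planted
#' seed-correlated genes on both signs, independent background genes, a
#' handful of strongly skewed contaminant probes, duplicate probes for some
#' genes, and annotation rows exercising the unmappable / non-specific /
#' non-coding exclusions.
#'
#' @param n_samples Sample count (>= 10).
#' @param seed_mean,seed_sd Normal parameters of the seed probe (log scale).
#' @param planted Named numeric vector gene -> target rho, |rho| < 1.
#' @param n_background Independent background genes.
#' @param n_nonnormal Contaminant probes drawn from an exponentiated normal.
#' @param n_duplicates Genes receiving a second, noisier probe.
#' @param n_unmappable,n_nonspecific,n_noncoding Annotation-defect probes.
#' @param seed_gene,seed_probe_id Symbol and probe ID of the seed.
#' @param rng_seed Integer seed driving all randomness.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 2158, seed_mean = 7, seed_sd = 1,
                             planted = default_planted(),
                             n_background = 200, n_nonnormal = 10,
                             n_duplicates = 5, n_unmappable = 5,
                             n_nonspecific = 5, n_noncoding = 5,
                             seed_gene = "SOD3",
                             seed_probe_id = "SEED_0001_at",
                             rng_seed = 1L) {
  if (n_samples < 10) stop("n_samples must be >= 10")
  if (length(planted) > 0 && any(abs(planted) >= 1))
    stop("target correlations must satisfy |rho| < 1")
  counts <- c(n_background, n_nonnormal, n_duplicates, n_unmappable,
              n_nonspecific, n_noncoding)
  if (any(counts < 0)) stop("probe counts must be >= 0")
  if (n_duplicates > length(planted))
    stop("cannot duplicate more genes than are planted")
  structure(list(n_samples = as.integer(n_samples), seed_mean = seed_mean,
                 seed_sd = seed_sd, planted = planted,
                 n_background = as.integer(n_background),
                 n_nonnormal = as.integer(n_nonnormal),
                 n_duplicates = as.integer(n_duplicates),
                 n_unmappable = as.integer(n_unmappable),
                 n_nonspecific = as.integer(n_nonspecific),
                 n_noncoding = as.integer(n_noncoding),
                 seed_gene = toupper(seed_gene),
                 seed_probe_id = seed_probe_id,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

probe_of <- function(sym, tag = "a") sprintf("%s_%s_at", sym, tag)

#' Generate a synthetic expression matrix with known truth
#'
#' The seed probe is i.i.d. normal. Each planted gene is built by the linear
#' mixture \eqn{x = \rho z + \sqrt{1-\rho^2}\,\varepsilon} on the
#' standardized seed z, then shifted/rescaled into a positive log-intensity
#' range, so its population correlation with the seed is exactly the target
#' (the sample correlation carries the usual estimation noise). Background
#' genes are independent normals; contaminant probes are exponentiated
#' normals (log-normal), strongly right-skewed so they fail the Jarque-Bera
#' screen with high probability at realistic sample sizes; duplicate probes
#' are noisy copies of their gene's primary probe with distinct dispersions.
#'
#' @param config A [synthetic_config()].
#' @return List with `matrix` (an [expression_matrix()]), `annotation`
#'   (probe annotation data frame), and `truth` (planted rho, contaminant
#'   probes, duplicate groups, background genes, seed identifiers).
#' @export
generate_expression <- function(config) {
  set.seed(config$rng_seed)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  # The seed and every planted gene are guaranteed distributionally clean
  # (Jarque-Bera p >= 0.1): the planted signal must be recoverable by a
  # pipeline whose first stage screens on JB at alpha = 0.05, just as the
  # real study's retained probes all passed that screen. Background and
  # contaminant probes are left unconditioned.
  jb_clean <- function(x) chi2_sf_df2(jarque_bera(x)$jb_statistic) >= 0.1
  z <- stats::rnorm(n)
  while (!jb_clean(z)) z <- stats::rnorm(n)
  zs <- (z - mean(z)) / stats::sd(z)    # standardized seed for the mixture

  rows <- list()
  ann <- list()
  add <- function(probe, values, symbol, specific = TRUE, coding = TRUE) {
    rows[[probe]] <<- values
    ann[[probe]] <<- data.frame(probe_id = probe,
                                gene_symbol = ifelse(is.na(symbol), NA_character_, symbol),
                                is_specific = specific, is_coding = coding,
                                stringsAsFactors = FALSE)
  }

  add(config$seed_probe_id, config$seed_mean + config$seed_sd * z,
      config$seed_gene)

  duplicate_groups <- list()
  planted_names <- names(config$planted)
  dup_genes <- planted_names[seq_len(config$n_duplicates)]
  for (g in planted_names) {
    rho <- config$planted[[g]]
    repeat {
      eps <- stats::rnorm(n)
      x <- rho * zs + sqrt(1 - rho^2) * eps
      if (jb_clean(x)) break
    }
    mu <- stats::runif(1, 5, 9); sdv <- stats::runif(1, 0.5, 1.5)
    primary <- probe_of(g, "a")
    add(primary, mu + sdv * x, g)
    if (g %in% dup_genes) {
      # suboptimal duplicate: compressed dynamic range plus probe-specific
      # noise, so its IQR stays below the primary's (sdv >= 0.5 guarantees
      # shrink^2 sdv^2 + noise^2 < sdv^2 for these settings)
      i <- match(g, dup_genes)
      shrink <- 0.4 + 0.05 * i
      noise <- 0.15 + 0.03 * i
      add(probe_of(g, "b"),
          mu + shrink * sdv * x + stats::rnorm(n, 0, noise), g)
      duplicate_groups[[g]] <- c(primary, probe_of(g, "b"))
    }
  }

  background_genes <- sprintf("BGD%03d", seq_len(config$n_background))
  for (g in background_genes)
    add(probe_of(g), stats::rnorm(n, stats::runif(1, 5, 9),
                                  stats::runif(1, 0.5, 1.5)), g)

  contaminant_probes <- character(0)
  if (config$n_nonnormal > 0) {
    for (i in seq_len(config$n_nonnormal)) {
      p <- probe_of(sprintf("CTM%03d", i))
      add(p, 4 + exp(stats::rnorm(n)), sprintf("CTM%03d", i))
      contaminant_probes <- c(contaminant_probes, p)
    }
  }
  if (config$n_unmappable > 0)
    for (i in seq_len(config$n_unmappable))
      add(sprintf("UNMAP%03d_at", i), stats::rnorm(n, 6, 1), NA_character_)
  if (config$n_nonspecific > 0)
    for (i in seq_len(config$n_nonspecific))
      add(probe_of(sprintf("NSP%03d", i)), stats::rnorm(n, 6, 1),
          sprintf("NSP%03d", i), specific = FALSE)
  if (config$n_noncoding > 0)
    for (i in seq_len(config$n_noncoding))
      add(probe_of(sprintf("NCG%03d", i)), stats::rnorm(n, 6, 1),
          sprintf("NCG%03d", i), coding = FALSE)

  m <- do.call(rbind, rows)
  colnames(m) <- samples
  truth <- structure(list(planted_rho = config$planted,
                          contaminant_probes = contaminant_probes,
                          duplicate_groups = duplicate_groups,
                          background_genes = background_genes,
                          seed_gene = config$seed_gene,
                          seed_probe_id = config$seed_probe_id,
                          planted_disorders = list(),
                          planted_novel = list()),
                     class = "synthetic_truth")
  list(matrix = expression_matrix(m),
       annotation = do.call(rbind, c(ann, list(make.row.names = FALSE))),
       truth = truth)
}

#' Generate a synthetic disease library with planted disorders
#'
#' Builds up to three planted disorder terms from the strongly correlated
#' planted genes (|rho| >= 0.45): two on the positive sign and one on the
#' negative sign, each containing its causal gene(s) (drawn from the
#' background), the seed gene, at least two planted correlated member genes,
#' and random background filler. One strongly correlated gene per disorder
#' is reserved as the planted novel gene: a list gene deliberately left out
#' of the disease term. Decoy terms contain only background genes (never
#' causal genes).
#'
#' @param truth A `synthetic_truth` from [generate_expression()].
#' @param decoys Number of decoy terms (default 20).
#' @param rng_seed Integer seed.
#' @return List with `library` (a [gene_set_library()]), `causal_map`
#'   (named list), and the updated `truth` carrying `planted_disorders` and
#'   `planted_novel`.
#' @export
generate_disease_library <- function(truth, decoys = 20, rng_seed = 1L) {
  set.seed(rng_seed)
  rho <- truth$planted_rho
  if (length(rho) == 0) stop("truth has no planted genes")
  pos <- names(sort(rho[rho >= 0.45], decreasing = TRUE))
  neg <- names(sort(rho[rho <= -0.45]))
  seed <- truth$seed_gene
  bg <- truth$background_genes

  plan <- list()
  if (length(pos) >= 4)
    plan[["Synthetic Disorder Alpha"]] <-
      list(members = pos[1:3], novel = pos[length(pos)], n_causal = 1,
           sign = "positive")
  if (length(pos) >= 6)
    plan[["Synthetic Disorder Beta"]] <-
      list(members = pos[4:5], novel = pos[length(pos) - 1], n_causal = 2,
           sign = "positive")
  if (length(neg) >= 4)
    plan[["Synthetic Disorder Gamma"]] <-
      list(members = neg[1:3], novel = neg[4], n_causal = 1,
           sign = "negative")
  if (length(plan) == 0)
    stop("not enough strongly correlated planted genes to build a disorder")

  n_causal_total <- sum(vapply(plan, `[[`, numeric(1), "n_causal"))
  if (length(bg) < n_causal_total + 4 * length(plan))
    stop("not enough background genes for causal sets and term filler")
  causal_pool <- sample(bg, n_causal_total)
  filler_pool <- setdiff(bg, causal_pool)

  terms <- list(); descriptions <- character(0)
  causal_map <- list()
  ci <- 0
  for (d in names(plan)) {
    p <- plan[[d]]
    causal <- causal_pool[(ci + 1):(ci + p$n_causal)]; ci <- ci + p$n_causal
    filler <- sample(filler_pool, 4)
    terms[[d]] <- c(causal, seed, p$members, filler)
    descriptions[d] <- "planted disorder"
    causal_map[[d]] <- causal
    truth$planted_disorders[[d]] <-
      list(members = p$members, causal = causal, sign = p$sign,
           expected_overlap = if (p$sign == "positive") c(seed, p$members)
                              else p$members)
    truth$planted_novel[[d]] <- p$novel
  }

  if (decoys > 0) {
    if (length(filler_pool) < 12)
      stop("decoy request exceeds the available background genes")
    for (i in seq_len(decoys)) {
      nm <- sprintf("Decoy Disorder %02d", i)
      terms[[nm]] <- sample(filler_pool, sample(6:12, 1))
      descriptions[nm] <- "decoy"
    }
  }
  # sanity: every planted novel gene is a planted correlated gene
  stopifnot(all(unlist(truth$planted_novel) %in% names(rho)))
  list(library = gene_set_library("synthetic_disease", terms, descriptions),
       causal_map = causal_map, truth = truth)
}

#' Generate a synthetic ontology library with planted co-membership terms
#'
#' For every planted disorder with a planted novel gene, emits a term
#' containing one of the disorder's causal genes plus the novel gene(s) and
#' background filler, so the novel-gene caller can recover the planted
#' candidates by causal co-membership. Decoy terms contain only background
#' genes.
#'
#' @param truth Updated `synthetic_truth` from [generate_disease_library()].
#' @param decoys Number of decoy terms (default 20).
#' @param rng_seed Integer seed.
#' @return A [gene_set_library()].
#' @export
generate_ontology_library <- function(truth, decoys = 20, rng_seed = 1L) {
  set.seed(rng_seed)
  if (length(truth$planted_novel) == 0)
    stop("truth has no planted novel genes; run generate_disease_library first")
  bad <- setdiff(unlist(truth$planted_novel), names(truth$planted_rho))
  if (length(bad) > 0)
    stop(sprintf("planted novel gene(s) not among planted correlated genes: %s",
                 paste(bad, collapse = ", ")))
  all_causal <- unique(unlist(lapply(truth$planted_disorders, `[[`, "causal")))
  filler_pool <- setdiff(truth$background_genes, all_causal)

  terms <- list(); descriptions <- character(0)
  for (d in names(truth$planted_disorders)) {
    novel <- truth$planted_novel[[d]]
    if (length(novel) == 0) next
    causal <- truth$planted_disorders[[d]]$causal
    nm <- sprintf("%s mechanism", d)
    terms[[nm]] <- c(causal[1], novel, sample(filler_pool, 3))
    descriptions[nm] <- "planted co-membership term"
  }
  if (decoys > 0) {
    for (i in seq_len(decoys)) {
      nm <- sprintf("Decoy Ontology %02d", i)
      terms[[nm]] <- sample(filler_pool, sample(5:10, 1))
      descriptions[nm] <- "decoy"
    }
  }
  gene_set_library("synthetic_ontology", terms, descriptions)
}

#' Write a complete synthetic study to a fixture directory
#'
#' Emits the six artifacts the pipeline reads: `expression.tsv`,
#' `annotation.tsv`, `disease.gmt`, `ontology.gmt`, `causal_map.tsv`, and
#' `truth.R` (the ground truth, serialized with [dput()] for exact
#' round-tripping with [dget()]).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory, created if needed.
#' @param decoys Decoy terms per library (default 20).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_study <- function(config, out_dir, decoys = 20) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_expression(config)
  dl <- generate_disease_library(gen$truth, decoys = decoys,
                                 rng_seed = config$rng_seed + 1L)
  ont <- generate_ontology_library(dl$truth, decoys = decoys,
                                   rng_seed = config$rng_seed + 2L)
  paths <- list(
    expression = file.path(out_dir, "expression.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    disease = file.path(out_dir, "disease.gmt"),
    ontology = file.path(out_dir, "ontology.gmt"),
    causal_map = file.path(out_dir, "causal_map.tsv"),
    truth = file.path(out_dir, "truth.R"))
  write_expression(gen$matrix, paths$expression)
  write_annotation(gen$annotation, paths$annotation)
  write_gmt(dl$library, paths$disease)
  write_gmt(ont, paths$ontology)
  write_causal_map(dl$causal_map, paths$causal_map)
  dput(unclass(dl$truth), file = paths$truth)
  invisible(list(matrix = gen$matrix, annotation = gen$annotation,
                 truth = dl$truth, disease_library = dl$library,
                 ontology_library = ont, causal_map = dl$causal_map,
                 paths = paths))
}
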
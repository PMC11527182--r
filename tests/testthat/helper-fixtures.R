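# Shared fixture builders: everything is generated in code at test time.

tiny_matrix <- function(nprobe = 3, nsample = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(round(rnorm(nprobe * nsample, 7, 1), 4), nprobe, nsample,
              dimnames = list(sprintf("P%d", seq_len(nprobe)),
                              sprintf("S%d", seq_len(nsample))))
  expression_matrix(m)
}

tiny_library <- function() {
  gene_set_library("toy", list(
    TermA = c("SOD3", "MYH11", "TAGLN", "CNN1"),
    TermB = c("MYH11", "DES", "PLN"),
    TermC = c("ACTA2", "ELN", "FBLN5", "EMILIN1", "LMOD1")))
}

# A small study whose generation cost suits per-test use.
small_study <- function(rng_seed = 7, n_samples = 400, decoys = 10) {
  cfg <- synthetic_config(n_samples = n_samples, rng_seed = rng_seed)
  gen <- generate_expression(cfg)
  dl <- generate_disease_library(gen$truth, decoys = decoys,
                                 rng_seed = rng_seed + 1)
  ont <- generate_ontology_library(dl$truth, decoys = decoys,
                                   rng_seed = rng_seed + 2)
  list(config = cfg, matrix = gen$matrix, annotation = gen$annotation,
       truth = dl$truth, disease = dl$library, ontology = ont,
       causal_map = dl$causal_map,
       pconfig = pipeline_config(cfg$seed_probe_id, cfg$seed_gene))
}

# Independent enumeration oracle for the hypergeometric upper tail.
enum_upper_tail <- function(k, n, K, N) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Independent step-down BH oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
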
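test_that("generation is deterministic and honours the config counts", {
  cfg <- synthetic_config(n_samples = 100, n_background = 20, n_nonnormal = 3,
                          n_duplicates = 2, rng_seed = 99)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$annotation, b$annotation)

  expect_length(a$truth$contaminant_probes, 3)
  expect_length(a$truth$duplicate_groups, 2)
  # every truth entry refers to an emitted probe/gene
  expect_true(all(unlist(a$truth$duplicate_groups) %in% rownames(a$matrix)))
  expect_true(all(a$truth$contaminant_probes %in% rownames(a$matrix)))
  syms <- a$annotation$gene_symbol
  expect_true(all(names(a$truth$planted_rho) %in% syms))
  expect_true(all(a$truth$background_genes %in% syms))

  none <- generate_expression(synthetic_config(n_samples = 50,
                                               n_nonnormal = 0, rng_seed = 1))
  expect_length(none$truth$contaminant_probes, 0)
})

test_that("planted correlations are recovered from the emitted matrix", {
  cfg <- synthetic_config(n_samples = 2158, planted = c(HOT = 0.99),
                          n_background = 5, n_nonnormal = 0, n_duplicates = 0,
                          rng_seed = 17)
  gen <- generate_expression(cfg)
  seed <- gen$matrix[cfg$seed_probe_id, ]
  hot <- gen$matrix["HOT_a_at", ]
  expect_gt(cor(seed, hot), 0.9)
  # direct Pearson on a negative plant
  cfg2 <- synthetic_config(n_samples = 2158, planted = c(COLD = -0.8),
                           n_background = 5, n_nonnormal = 0,
                           n_duplicates = 0, rng_seed = 18)
  gen2 <- generate_expression(cfg2)
  expect_lt(cor(gen2$matrix[cfg2$seed_probe_id, ], gen2$matrix["COLD_a_at", ]),
            -0.7)
})

test_that("contaminant probes fail the JB screen in at least 90% of replicates", {
  fails <- 0; total <- 0
  for (s in 1:20) {
    cfg <- synthetic_config(n_samples = 500, planted = c(X = 0.5),
                            n_background = 2, n_nonnormal = 5,
                            n_duplicates = 0, rng_seed = 400 + s)
    gen <- generate_expression(cfg)
    for (p in gen$truth$contaminant_probes) {
      jb <- jarque_bera(gen$matrix[p, ])$jb_statistic
      total <- total + 1
      if (chi2_sf_df2(jb) < 0.05) fails <- fails + 1
    }
  }
  expect_gte(fails / total, 0.9)
})

test_that("duplicate probes have smaller spread than their primary", {
  cfg <- synthetic_config(n_samples = 300, n_duplicates = 5, rng_seed = 5)
  gen <- generate_expression(cfg)
  for (g in names(gen$truth$duplicate_groups)) {
    probes <- gen$truth$duplicate_groups[[g]]
    iqr <- vapply(probes, function(p) IQR(gen$matrix[p, ]), numeric(1))
    expect_gt(iqr[1], iqr[2])
  }
})

test_that("disease library plants disorders with causal, seed, and member genes", {
  study <- small_study(rng_seed = 23)
  truth <- study$truth
  expect_gte(length(truth$planted_disorders), 3)
  for (d in names(truth$planted_disorders)) {
    pd <- truth$planted_disorders[[d]]
    term <- study$disease$terms[[d]]
    expect_true(all(pd$causal %in% term))
    expect_true(truth$seed_gene %in% term)
    expect_gte(sum(pd$members %in% term), 2)
    expect_gte(length(term), 4)
    # the planted novel gene is left out of the disease term
    expect_false(any(truth$planted_novel[[d]] %in% term))
    expect_identical(study$causal_map[[d]], pd$causal)
  }
  decoys <- setdiff(names(study$disease$terms), names(truth$planted_disorders))
  for (dt in decoys)
    expect_true(all(study$disease$terms[[dt]] %in% truth$background_genes))
})

test_that("decoy handling respects counts and limits", {
  cfg <- synthetic_config(n_samples = 60, rng_seed = 2)
  gen <- generate_expression(cfg)
  dl0 <- generate_disease_library(gen$truth, decoys = 0, rng_seed = 3)
  expect_identical(length(dl0$library$terms),
                   length(dl0$truth$planted_disorders))
  small <- generate_expression(synthetic_config(n_samples = 60,
                                                n_background = 8, rng_seed = 4))
  expect_error(generate_disease_library(small$truth, decoys = 5, rng_seed = 3))
})

test_that("ontology library co-locates causal and novel genes", {
  study <- small_study(rng_seed = 29)
  for (d in names(study$truth$planted_novel)) {
    novel <- study$truth$planted_novel[[d]]
    causal <- study$truth$planted_disorders[[d]]$causal
    nm <- sprintf("%s mechanism", d)
    expect_true(nm %in% names(study$ontology$terms))
    expect_true(all(novel %in% study$ontology$terms[[nm]]))
    expect_true(any(causal %in% study$ontology$terms[[nm]]))
  }
  # truth without planted novel genes cannot feed the ontology generator
  bare <- generate_expression(synthetic_config(n_samples = 60, rng_seed = 6))
  expect_error(generate_ontology_library(bare$truth, rng_seed = 1),
               "planted novel")
  # a disorder with no planted novel genes gets no co-membership term
  tr <- study$truth
  dropped <- names(tr$planted_novel)[1]
  tr$planted_novel[[dropped]] <- character(0)
  ont <- generate_ontology_library(tr, decoys = 0, rng_seed = 9)
  expect_false(sprintf("%s mechanism", dropped) %in% names(ont$terms))
  # corrupted truth is rejected
  tr2 <- study$truth
  tr2$planted_novel[[1]] <- "NOT_PLANTED"
  expect_error(generate_ontology_library(tr2, rng_seed = 1), "NOT_PLANTED")
})
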
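test_that("correlation against the seed matches the explicit covariance quotient", {
  seed <- c(7.1, 6.9, 8.3, 5.5, 7.7)
  perturbed <- seed; perturbed[3] <- 7.0
  raw <- rbind(SEED = seed, SAME = seed, NEG = -seed, PERT = perturbed,
               OTHER = c(1.2, 4.5, 3.3, 2.2, 6.0))
  colnames(raw) <- sprintf("s%d", 1:5)
  m <- expression_matrix(raw)
  rec <- pearson_vs_seed(m, "SEED")
  expect_equal(rec$rho[rec$probe_id == "SAME"], 1)
  expect_equal(rec$rho[rec$probe_id == "NEG"], -1)

  # independent oracle: explicit covariance quotient
  oracle <- sum((seed - mean(seed)) * (perturbed - mean(perturbed))) /
    sqrt(sum((seed - mean(seed))^2) * sum((perturbed - mean(perturbed))^2))
  expect_equal(rec$rho[rec$probe_id == "PERT"], oracle, tolerance = 1e-10)

  expect_error(pearson_vs_seed(m, "MISSING_at"), "MISSING_at")
})

test_that("t statistic and two-tail p behave across the rho range", {
  r0 <- correlation_pvalue(0, 100)
  expect_identical(r0$t_statistic, 0)
  expect_identical(r0$p_value, 1)

  r <- correlation_pvalue(0.34, 2158)
  expect_equal(r$t_statistic, 0.34 * sqrt(2156 / (1 - 0.34^2)),
               tolerance = 1e-12)
  expect_equal(r$t_statistic, 16.79, tolerance = 1e-3)

  expect_identical(correlation_pvalue(1, 50)$p_value, 0)
  expect_identical(correlation_pvalue(-1, 50)$p_value, 0)
  expect_error(correlation_pvalue(0.5, 2), "3 samples")

  # t = rho * sqrt((n-2)/(1-rho^2)) and sign(t) = sign(rho), propertywise
  set.seed(8)
  rhos <- runif(50, -0.99, 0.99)
  r <- correlation_pvalue(rhos, 30)
  expect_equal(r$t_statistic, rhos * sqrt(28 / (1 - rhos^2)), tolerance = 1e-8)
  expect_identical(sign(r$t_statistic), sign(rhos))
})

test_that("Bonferroni threshold reproduces the study's adjusted alpha", {
  expect_equal(signif(bonferroni_threshold(0.05, 2158), 2), 2.3e-5)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  # the rejected alternative divisor (probe count) gives a different order
  expect_equal(bonferroni_threshold(0.05, 54675), 9.1e-7, tolerance = 1e-2)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("significance filtering excludes strictly above alpha_cor", {
  rec <- data.frame(probe_id = c("A", "B", "C"),
                    rho = c(0.5, 0.1, 0.01),
                    t_statistic = 0, p_value = c(1e-8, 2.3e-5, 0.6), n = 100)
  out <- filter_significant(rec, 2.3e-5)
  expect_setequal(out$records$probe_id, c("A", "B"))  # boundary retained
  expect_identical(out$ledger$n_excluded[1], 1L)
})

test_that("rho threshold filtering is strict with rounded comparisons", {
  rec <- data.frame(probe_id = c("A", "B", "C", "D"),
                    rho = c(0.34, -0.34, 0.34 - 1e-12, 0.3399),
                    t_statistic = 0, p_value = 0, n = 100)
  out <- filter_rho_threshold(rec, 0.34)
  expect_setequal(out$records$probe_id, c("A", "B", "C"))  # 1e-12 inside rounding
  expect_identical(out$ledger$n_excluded[1], 1L)
})

test_that("ladder construction follows the threshold rule exactly", {
  rec <- data.frame(probe_id = c("pA", "pB", "pC"),
                    gene_symbol = c("A", "B", "C"),
                    rho = c(0.50, -0.36, 0.345),
                    t_statistic = 1, p_value = 0, n = 100)
  cfg <- pipeline_config("seedp", "SEED", tau_min = 0.34, tau_max = 0.35)
  lad <- build_ladder(rec, cfg)
  full_34 <- lad$full[[1]]; full_35 <- lad$full[[2]]
  expect_setequal(names(full_34$genes), c("A", "B", "C", "SEED"))
  expect_setequal(names(full_35$genes), c("A", "B", "SEED"))
  pos_34 <- lad$positive[[1]]; neg_34 <- lad$negative[[1]]
  expect_setequal(names(pos_34$genes), c("A", "C", "SEED"))
  expect_setequal(names(neg_34$genes), "B")
})

test_that("default ladder yields 8 full and 24 signed lists with nesting", {
  set.seed(21)
  rec <- data.frame(probe_id = sprintf("p%02d", 1:40),
                    gene_symbol = sprintf("G%02d", 1:40),
                    rho = runif(40, -0.45, 0.45),
                    t_statistic = 1, p_value = 0, n = 100)
  cfg <- pipeline_config("seedp", "SEED")
  lad <- build_ladder(rec, cfg)
  expect_length(lad$full, 8)
  expect_length(c(lad$full, lad$positive, lad$negative), 24)

  for (sign in c("full", "positive", "negative")) {
    for (i in seq_len(7)) {
      tighter <- names(lad[[sign]][[i + 1]]$genes)
      looser <- names(lad[[sign]][[i]]$genes)
      expect_true(all(tighter %in% looser))
    }
  }
  # the seed gene is in every full and positive list; numbering ascends by count
  for (i in 1:8) {
    expect_true("SEED" %in% names(lad$full[[i]]$genes))
    expect_true("SEED" %in% names(lad$positive[[i]]$genes))
  }
  counts <- vapply(lad$full, function(l) length(l$genes), integer(1))
  nums <- as.integer(sub("list ", "", vapply(lad$full, `[[`, character(1), "label")))
  # numbering ascends with gene count: counts are non-decreasing along
  # ascending list numbers
  expect_false(is.unsorted(counts[order(nums)]))
})

test_that("signed splitting is a disjoint partition", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(2:30, 1)
    genes <- setNames(runif(n, -1, 1), sprintf("G%02d", seq_len(n)))
    genes[genes == 0] <- 0.1
    fl <- seedcor:::threshold_list("list x", 0.0, "full", genes)
    parts <- split_signed(fl)
    expect_setequal(c(names(parts$positive$genes), names(parts$negative$genes)),
                    names(genes))
    expect_length(intersect(names(parts$positive$genes),
                            names(parts$negative$genes)), 0)
    expect_true(all(parts$positive$genes > 0))
    expect_true(all(parts$negative$genes < 0))
  }
  one_sign <- seedcor:::threshold_list("list y", 0.3, "full",
                                       c(A = 0.4, B = 0.5))
  expect_length(split_signed(one_sign)$negative$genes, 0)
  expect_error(split_signed(split_signed(one_sign)$positive), "full")
  zero <- seedcor:::threshold_list("list z", 0, "full", c(A = 0))
  expect_error(split_signed(zero), "sign")
})
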
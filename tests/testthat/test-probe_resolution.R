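make_resolution_fixture <- function() {
  # G1 has two probes with known IQRs; G2 one probe; plus annotation defects
  set.seed(12)
  n <- 40
  base <- rnorm(n, 7, 1)
  m <- rbind(P1 = base + rnorm(n, 0, 2),     # large spread
             P2 = base + rnorm(n, 0, 0.2),   # small spread
             P3 = rnorm(n, 6, 1),
             P4 = rnorm(n, 6, 1),
             P5 = rnorm(n, 6, 1),
             P6 = rnorm(n, 6, 1))
  colnames(m) <- sprintf("s%d", seq_len(n))
  ann <- data.frame(
    probe_id = c("P1", "P2", "P3", "P4", "P5", "P6"),
    gene_symbol = c("G1", "G1", "G2", NA, "G3", "G4"),
    is_specific = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    is_coding = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  rec <- data.frame(probe_id = rownames(m), rho = seq(0.40, 0.45, by = 0.01),
                    t_statistic = 1, p_value = 0, n = n)
  list(matrix = expression_matrix(m), annotation = ann, records = rec)
}

test_that("resolution applies the four exclusion steps in order", {
  fx <- make_resolution_fixture()
  out <- resolve_probes(fx$records, fx$annotation, fx$matrix)
  expect_identical(out$ledger$criterion,
                   c("No Gene Symbol for Probe ID", "Non-specific Probe IDs",
                     "Non-coding Genes", "Duplicated Genes"))
  expect_identical(out$ledger$n_excluded, c(1L, 1L, 1L, 1L))
  expect_identical(ledger_remaining(out$ledger), nrow(out$records))
  # gene -> probe is a bijection after resolution
  expect_false(anyDuplicated(out$records$gene_symbol) > 0)
  expect_false(anyDuplicated(out$records$probe_id) > 0)
})

test_that("duplicate collapse honours the best-probe map and IQR fallback", {
  fx <- make_resolution_fixture()
  # fallback: P1 has the larger IQR
  out <- resolve_probes(fx$records, fx$annotation, fx$matrix)
  expect_identical(out$records$probe_id[out$records$gene_symbol == "G1"], "P1")
  # explicit map overrides the heuristic
  out2 <- resolve_probes(fx$records, fx$annotation, fx$matrix,
                         best_probe_map = c(G1 = "P2"))
  expect_identical(out2$records$probe_id[out2$records$gene_symbol == "G1"], "P2")
  # map naming a non-surviving probe warns and falls back
  expect_warning(
    out3 <- resolve_probes(fx$records, fx$annotation, fx$matrix,
                           best_probe_map = c(G1 = "P99")),
    "fallback")
  expect_identical(out3$records$probe_id[out3$records$gene_symbol == "G1"], "P1")
})

test_that("IQR ties break lexicographically by probe ID", {
  n <- 20
  vals <- rnorm(n)
  m <- rbind(PB = vals, PA = vals)   # identical rows -> identical IQR
  colnames(m) <- sprintf("s%d", seq_len(n))
  ann <- data.frame(probe_id = c("PB", "PA"), gene_symbol = c("G", "G"),
                    is_specific = TRUE, is_coding = TRUE)
  rec <- data.frame(probe_id = c("PB", "PA"), rho = c(0.4, 0.4),
                    t_statistic = 1, p_value = 0, n = n)
  out <- resolve_probes(rec, ann, expression_matrix(m))
  expect_identical(out$records$probe_id, "PA")
})

test_that("a best-probe map reproduces a published duplicate resolution", {
  # the eight duplicated genes and their curated best probes
  best <- c(CAND1 = "208838_at", FBXO28 = "202271_at", HSPB6 = "226304_at",
            MREG = "219648_at", MTF2 = "209705_at", MYH11 = "201497_x_at",
            PLN = "228202_at", QSER1 = "219705_at")
  set.seed(33)
  n <- 30
  probes <- c(unname(best), paste0("alt_", names(best)))
  m <- matrix(rnorm(length(probes) * n, 7, 1), length(probes), n,
              dimnames = list(probes, sprintf("s%d", seq_len(n))))
  ann <- data.frame(probe_id = probes,
                    gene_symbol = rep(names(best), 2),
                    is_specific = TRUE, is_coding = TRUE)
  rec <- data.frame(probe_id = probes, rho = runif(length(probes), 0.35, 0.45),
                    t_statistic = 1, p_value = 0, n = n)
  out <- resolve_probes(rec, ann, expression_matrix(m), best_probe_map = best)
  got <- setNames(out$records$probe_id, out$records$gene_symbol)
  expect_identical(got[names(best)], best)
  expect_identical(out$ledger$n_excluded[out$ledger$criterion == "Duplicated Genes"],
                   8L)
})

test_that("unknown probes in records are a hard error", {
  fx <- make_resolution_fixture()
  bad <- rbind(fx$records,
               data.frame(probe_id = "P_UNKNOWN", rho = 0.4, t_statistic = 1,
                          p_value = 0, n = 40))
  expect_error(resolve_probes(bad, fx$annotation, fx$matrix), "P_UNKNOWN")
})
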
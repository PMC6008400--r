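test_that("paired t-test handles identical and degenerate inputs", {
  res <- paired_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 3L)
  expect_warning(res2 <- paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4)),
                 "constant non-zero")
  expect_equal(res2$p, 0)
  expect_error(paired_t_test(1, 2), "at least 2")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("paired t-test matches the closed formula and stats::t.test", {
  set.seed(314)
  for (i in 1:20) {
    x <- rpois(10, 3); y <- rpois(10, 3)
    if (sd(x - y) == 0) next
    res <- paired_t_test(x, y)
    d <- x - y
    t_manual <- mean(d) / (sd(d) / sqrt(10))
    expect_equal(res$t, t_manual, tolerance = 1e-12)
    expect_equal(res$p, 2 * pt(abs(t_manual), 9, lower.tail = FALSE),
                 tolerance = 1e-12)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_adjust(0.2), 0.2)  # m = 1 identity
  set.seed(99)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # monotone in rank order
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

mk_manifest <- function(n) {
  data.frame(pair_id = sprintf("P%02d", 1:n),
             case_sample_id = sprintf("P%02d_case", 1:n),
             control_sample_id = sprintf("P%02d_ctrl", 1:n),
             pair_kind = "case_control", stringsAsFactors = FALSE)
}

mk_burden_calls <- function(manifest, counts_case, counts_ctrl,
                            gene = "TP53", vaf = 0.3,
                            effect = "missense") {
  rows <- list()
  add <- function(sid, n) {
    if (n == 0) return()
    rows[[length(rows) + 1]] <<- mk_calls(
      rep("c1", n), sample.int(10000, n), rep("A", n), rep("T", n),
      sample_id = sid, tumor_depth = 100L,
      tumor_alt = as.integer(vaf * 100),
      gene = gene, effect = effect)
  }
  for (i in seq_len(nrow(manifest))) {
    add(manifest$case_sample_id[i], counts_case[i])
    add(manifest$control_sample_id[i], counts_ctrl[i])
  }
  do.call(rbind, rows)
}

test_that("burden tables count per pair and respect strata boundaries", {
  m <- mk_manifest(4)
  calls <- mk_burden_calls(m, c(2, 0, 1, 3), c(1, 1, 0, 0))
  b <- build_burden_table(calls, m, "all")
  expect_equal(b$case_count, c(2L, 0L, 1L, 3L))
  expect_equal(b$control_count, c(1L, 1L, 0L, 0L))
  # empty call set: all-zero table over the manifest
  b0 <- build_burden_table(variant_calls(), m, "all")
  expect_equal(b0$case_count, rep(0L, 4))
  # VAF exactly 0.25 is excluded from the founding-clone stratum
  calls25 <- mk_burden_calls(m, c(1, 0, 0, 0), rep(0, 4), vaf = 0.25)
  expect_equal(sum(build_burden_table(calls25, m,
                                      "founding_clone")$case_count), 0L)
  calls26 <- mk_burden_calls(m, c(1, 0, 0, 0), rep(0, 4), vaf = 0.26)
  expect_equal(sum(build_burden_table(calls26, m,
                                      "founding_clone")$case_count), 1L)
  # silent calls drop out of the non-silent stratum
  silent <- mk_burden_calls(m, c(1, 1, 1, 1), rep(0, 4),
                            effect = "silent")
  expect_equal(sum(build_burden_table(silent, m,
                                      "non_silent")$case_count), 0L)
  # unknown sample errors
  stray <- mk_burden_calls(mk_manifest(5)[5, ], 1, 0)
  expect_error(build_burden_table(rbind(calls, stray), m, "all"),
               "not in manifest")
})

test_that("per-gene tests report untested genes and BH-adjust the rest", {
  m <- mk_manifest(6)
  calls <- rbind(
    mk_burden_calls(m, c(2, 1, 2, 1, 2, 1), c(0, 0, 1, 0, 0, 0),
                    gene = "KIT"),
    mk_burden_calls(m, c(1, 0, 1, 0, 1, 0), c(0, 1, 0, 1, 0, 1),
                    gene = "TP53"))
  tabs <- build_burden_table(calls, m, "per_gene",
                             genes = c("KIT", "TP53", "BRCA1"))
  res <- per_gene_tests(tabs)
  expect_setequal(res$gene, c("KIT", "TP53", "BRCA1"))
  brca <- res[res$gene == "BRCA1", ]
  expect_true(is.na(brca$p))
  expect_equal(brca$n_cases_mutated, 0L)
  tested <- res[!is.na(res$p), ]
  expect_equal(tested$fdr, bh_oracle(tested$p), tolerance = 1e-12)
})

test_that("exclusivity lists genes mutated in exactly one arm", {
  m <- mk_manifest(6)
  calls <- rbind(
    mk_burden_calls(m, c(1, 1, 1, 1, 1, 0), rep(0, 6), gene = "KIT"),
    mk_burden_calls(m, c(1, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0),
                    gene = "TP53"))
  tabs <- build_burden_table(calls, m, "per_gene")
  ex <- exclusivity_summary(tabs)
  expect_equal(ex$case_exclusive$gene, "KIT")
  expect_equal(ex$case_exclusive$n_mutated, 5L)
  expect_false("TP53" %in% ex$case_exclusive$gene)
  expect_equal(nrow(ex$control_exclusive), 0L)
})

test_that("hotspot contrast matches hypergeometric enumeration", {
  m <- mk_manifest(10)
  mk_res_calls <- function(sids, residue) {
    mk_calls(rep("c1", length(sids)), sample.int(5000, length(sids)),
             rep("A", length(sids)), rep("T", length(sids)),
             sample_id = NA, gene = "PIK3CA", effect = "missense",
             residue = residue) |>
      within(sample_id <- sids)
  }
  # balanced table: no association, p = 1
  calls <- rbind(
    mk_res_calls(m$case_sample_id[1:2], 1047L),
    mk_res_calls(m$case_sample_id[3:4], 500L),
    mk_res_calls(m$control_sample_id[1:2], 1047L),
    mk_res_calls(m$control_sample_id[3:4], 500L))
  res <- hotspot_contrast(calls, m, "PIK3CA", 1047L)
  expect_equal(res$p, 1)
  # 5,0 / 0,5 extreme table vs enumeration oracle
  calls2 <- rbind(
    mk_res_calls(m$case_sample_id[1:5], 1047L),
    mk_res_calls(m$control_sample_id[1:5], 500L))
  res2 <- hotspot_contrast(calls2, m, "PIK3CA", 1047L)
  expect_equal(unname(res2$table[1, ]), c(5L, 0L))
  expect_equal(res2$p, fisher_oracle(5, 0, 0, 5), tolerance = 1e-10)
  expect_error(hotspot_contrast(calls2, m, "EMPTYGENE", 1L),
               "no mutations")
})

test_that("gene-set permutation p equals exhaustive enumeration", {
  m <- mk_manifest(5)
  calls <- rbind(
    mk_burden_calls(m, c(3, 1, 2, 0, 1), c(1, 0, 1, 1, 0), gene = "KIT"),
    mk_burden_calls(m, c(0, 2, 1, 1, 0), c(1, 1, 0, 2, 1), gene = "TP53"))
  tabs <- build_burden_table(calls, m, "per_gene")
  res <- geneset_enrichment(tabs, list(S = c("KIT", "TP53")),
                            n_permutations = 1000, seed = 3)
  expect_true(res$exhaustive)
  # independent exhaustive oracle over all 2^5 sign assignments
  d <- (tabs$KIT$case_count + tabs$TP53$case_count) -
    (tabs$KIT$control_count + tabs$TP53$control_count)
  signs <- expand.grid(rep(list(c(1, -1)), 5))
  null_stats <- apply(signs, 1, function(s) mean(s * d))
  p_exact <- mean(abs(null_stats) >= abs(mean(d)) - 1e-12)
  expect_equal(res$p, p_exact, tolerance = 1e-12)
})

test_that("permutation p is deterministic and order-invariant", {
  m <- mk_manifest(14)
  set.seed(8)
  calls <- mk_burden_calls(m, rpois(14, 2), rpois(14, 2), gene = "KIT")
  tabs <- build_burden_table(calls, m, "per_gene")
  r1 <- geneset_enrichment(tabs, list(S = "KIT"), n_permutations = 500,
                           seed = 4)
  r2 <- geneset_enrichment(tabs, list(S = "KIT"), n_permutations = 500,
                           seed = 4)
  expect_false(r1$exhaustive)
  expect_equal(r1$p, r2$p)
  # pair reordering leaves the permutation p unchanged
  perm <- sample(14)
  tabs_perm <- list(KIT = tabs$KIT[perm, ])
  r3 <- geneset_enrichment(tabs_perm, list(S = "KIT"),
                           n_permutations = 500, seed = 4)
  expect_equal(r3$p, r1$p)
  # identical case/control counts give p = 1
  same <- build_burden_table(
    mk_burden_calls(m, rep(1, 14), rep(1, 14), gene = "KIT"), m,
    "per_gene")
  r4 <- geneset_enrichment(same, list(S = "KIT"), n_permutations = 500,
                           seed = 4)
  expect_equal(r4$p, 1)
  expect_warning(geneset_enrichment(tabs, list(EMPTY = "NOTAGENE"),
                                    n_permutations = 10, seed = 1),
                 "skipped")
})
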
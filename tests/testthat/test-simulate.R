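test_that("configs validate rates and geometry", {
  expect_error(simulation_config(exon_length = 2), "exon length")
  expect_error(simulation_config(error_rate = 2), "rate outside")
  expect_error(simulation_config(intron_length = 10, flank = 10),
               "introns")
  cfg <- simulation_config()
  expect_equal(cfg$n_pairs, 218)
  expect_equal(cfg$mean_depth, 90.4)
})

test_that("substreams are stable: extra samples never perturb earlier ones", {
  cfg1 <- small_sim(n_pairs = 4)
  cfg2 <- small_sim(n_pairs = 6)
  co1 <- generate_cohort(cfg1)
  co2 <- generate_cohort(cfg2)
  shared <- co1$manifest$case_sample_id
  t1 <- co1$truth[co1$truth$sample_id %in% shared, ]
  t2 <- co2$truth[co2$truth$sample_id %in% shared, ]
  expect_equal(t1, t2, ignore_attr = TRUE)
})

test_that("the panel honours symbol list, geometry and determinism", {
  cfg <- small_sim()
  panel <- generate_panel(cfg)
  expect_equal(length(panel$genes), cfg$n_genes)
  expect_equal(names(panel$genes)[1:6], panel_gene_symbols()[1:6])
  for (g in panel$genes) {
    len <- sum(g$cds$end - g$cds$start + 1L)
    expect_equal(len %% 3L, 0L)
  }
  # single-exon request: exact CDS length
  cfg1 <- simulation_config(n_genes = 1, exons_per_gene = 1,
                            exon_length = 300, seed = 2)
  p1 <- generate_panel(cfg1)
  expect_equal(sum(p1$genes[[1]]$cds$end - p1$genes[[1]]$cds$start + 1L),
               300L)
  # symbols beyond the published list are synthetic
  cfg90 <- simulation_config(n_genes = 90, seed = 2)
  p90 <- generate_panel(cfg90)
  expect_true("SYNGENE007" %in% names(p90$genes))
  # same seed, same bytes
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_panel(generate_panel(cfg), d1)
  write_panel(generate_panel(cfg), d2)
  expect_equal(unname(tools::md5sum(file.path(d1, "panel.fa"))),
               unname(tools::md5sum(file.path(d2, "panel.fa"))))
})

test_that("cohort files are byte-identical across reruns of one seed", {
  cfg <- small_sim(n_pairs = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_equal(f1, f2)
  expect_equal(unname(tools::md5sum(file.path(d1, f1))),
               unname(tools::md5sum(file.path(d2, f2))))
})

test_that("null config with zero somatic rate yields no somatic truth", {
  cfg <- small_sim(somatic_rate = 0, false_call_rate = 0,
                   ffpe_sample_fraction = 0, pon_rate = 0)
  co <- generate_cohort(cfg)
  expect_false(any(co$truth$origin == "somatic"))
})

test_that("every emitted caller call is traceable to one truth record", {
  cfg <- small_sim()
  co <- generate_cohort(cfg)
  truth_keys <- paste(co$truth$sample_id,
                      co$truth$contig, co$truth$pos, co$truth$ref,
                      co$truth$alt)
  expect_equal(anyDuplicated(truth_keys), 0L)
  for (sid in names(co$caller_calls)) {
    for (calls in co$caller_calls[[sid]]) {
      if (nrow(calls) == 0) next
      k <- paste(calls$sample_id, calls$contig, calls$pos, calls$ref,
                 calls$alt)
      expect_true(all(k %in% truth_keys))
    }
  }
})

test_that("depths, artifact VAFs and germline VAFs match their models", {
  cfg <- simulation_config(seed = 5)
  # law-of-large-numbers check of the configured mean depth
  depths <- bbdsomatic:::with_substream(5, "depthcheck", {
    bbdsomatic:::draw_depth(1e4, cfg)
  })
  expect_lt(abs(mean(depths) - 90.4) / 90.4, 0.02)

  co <- generate_cohort(small_sim(ffpe_sample_fraction = 0.5,
                                  germline_rate = 5))
  art <- co$truth[co$truth$origin == "ffpe_artifact", ]
  expect_gt(nrow(art), 5)
  expect_true(all(art$true_vaf < 0.10))
  germ_keys <- co$truth$origin == "germline"
  rc_keys <- paste(co$readcounts$sample_id, co$readcounts$contig,
                   co$readcounts$pos)
  g <- co$readcounts[rc_keys %in% paste(co$truth$sample_id[germ_keys],
                                        co$truth$contig[germ_keys],
                                        co$truth$pos[germ_keys]), ]
  expect_gt(nrow(g), 30)
  expect_lt(abs(mean(g$tumor_alt / g$tumor_depth) - 0.5), 0.05)
})

test_that("FFPE artifacts sit in CG>TG-compatible context by construction", {
  co <- generate_cohort(small_sim(ffpe_sample_fraction = 1,
                                  ffpe_artifact_rate = 5))
  art <- co$truth[co$truth$origin == "ffpe_artifact", ]
  expect_gt(nrow(art), 10)
  ctx <- is_ffpe_context(art$contig, art$pos, art$ref, art$alt,
                         co$panel$reference)
  expect_true(all(ctx))
})

test_that("an injected case-exclusive gene lands only in case samples", {
  cfg <- small_sim(exclusive_gene = list(gene = "AKT1", n_cases = 4))
  co <- generate_cohort(cfg)
  akt <- co$truth[co$truth$gene == "AKT1" & co$truth$origin == "somatic", ]
  expect_gte(length(unique(akt$sample_id)), 4)
  expect_true(all(grepl("_case$", akt$sample_id)))
})

test_that("progression sharing follows the configured fraction", {
  cfg <- small_sim()
  shared_keys <- function(pairs) {
    vapply(pairs, function(p) {
      bbd <- p$truth[p$truth$role == "bbd", ]
      ibc <- p$truth[p$truth$role == "ibc", ]
      length(intersect(paste(bbd$contig, bbd$pos, bbd$ref, bbd$alt),
                       paste(ibc$contig, ibc$pos, ibc$ref, ibc$alt)))
    }, 0L)
  }
  none <- generate_progression_pairs(cfg, n_pairs = 7,
                                     shared_fraction = 0)
  expect_equal(length(none), 7L)
  expect_true(all(shared_keys(none) == 0L))

  all_shared <- generate_progression_pairs(cfg, n_pairs = 5,
                                           shared_fraction = 1)
  for (p in all_shared) {
    bbd <- p$truth[p$truth$role == "bbd", ]
    ibc_keys <- with(p$truth[p$truth$role == "ibc", ],
                     paste(contig, pos, ref, alt))
    expect_true(all(paste(bbd$contig, bbd$pos, bbd$ref, bbd$alt) %in%
                      ibc_keys))
  }

  half <- generate_progression_pairs(small_sim(seed = 21), n_pairs = 20,
                                     shared_fraction = 0.5,
                                     somatic_rate = 10)
  n_bbd <- sum(vapply(half, function(p) sum(p$truth$role == "bbd"), 0L))
  n_shared <- sum(shared_keys(half))
  expect_gt(n_bbd, 150)
  expect_lt(abs(n_shared - 0.5 * n_bbd), 3 * sqrt(n_bbd * 0.25))
})

test_that("pair-count marginals are Poisson at the configured rate", {
  set.seed(77)
  counts <- simulate_pair_counts(4000, somatic_rate = 2.3,
                                 case_effect = 1.0)
  expect_equal(nrow(counts), 4000)
  expect_lt(abs(mean(counts$case_count) - 2.3), 0.1)
  expect_lt(abs(mean(counts$control_count) - 2.3), 0.1)
  boosted <- simulate_pair_counts(4000, somatic_rate = 2, case_effect = 2)
  expect_lt(abs(mean(boosted$case_count) - 4), 0.15)
})
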
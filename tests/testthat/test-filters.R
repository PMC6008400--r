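test_that("coverage filter requires 20x in both tumor and normal", {
  calls <- mk_calls(rep("c1", 3), c(1L, 2L, 3L), rep("A", 3), rep("T", 3),
                    tumor_depth = c(19L, 20L, 100L),
                    tumor_alt = c(5L, 5L, 5L),
                    normal_depth = c(100L, 20L, 19L),
                    normal_alt = 0L)
  out <- coverage_filter(calls)
  expect_equal(out$pos, 2L)
  expect_equal(out$filter_history, "coverage:pass")
})

test_that("coverage filter equals the brute-force predicate on random depths", {
  set.seed(5)
  n <- 200
  calls <- mk_calls(rep("c1", n), seq_len(n), rep("A", n), rep("T", n),
                    tumor_depth = sample(0:60, n, replace = TRUE) + 1L,
                    tumor_alt = 0L,
                    normal_depth = sample(0:60, n, replace = TRUE) + 1L,
                    normal_alt = 0L)
  out <- coverage_filter(calls, min_depth = 20)
  expect_equal(sort(out$pos),
               sort(calls$pos[calls$tumor_depth >= 20 &
                                calls$normal_depth >= 20]))
})

test_that("panel-of-normals filter is exact set difference", {
  calls <- mk_calls(rep("c1", 50), 1:50, rep("A", 50), rep("T", 50))
  expect_equal(nrow(pon_filter(calls, character(0))), 50)
  blacklist <- call_key(calls[sample(50, 10), ])
  out <- pon_filter(calls, blacklist)
  expect_setequal(call_key(out), setdiff(call_key(calls), blacklist))
})

test_that("unnormalized blacklist keys are rejected when checkable", {
  ref <- tiny_ref()
  expect_error(pon_filter(mk_calls("run1", 4L, "C", "T"),
                          "run1:5:AA:A", reference = ref),
               "not normalized")
  out <- pon_filter(mk_calls("run1", 4L, "C", "T"), "run1:4:CA:C",
                    reference = ref)
  expect_equal(nrow(out), 1)
})

test_that("population-frequency filter reads 'exceeded 0.1%' strictly", {
  calls <- mk_calls(rep("c1", 3), 1:3, rep("A", 3), rep("T", 3))
  fm <- data.frame(key = c("c1:1:A:T", "c1:2:A:T"),
                   frequency = c(0.001, 0.002))
  out <- popfreq_filter(calls, fm)
  # boundary kept, 0.002 removed, absent key kept
  expect_setequal(call_key(out), c("c1:1:A:T", "c1:3:A:T"))
  expect_error(popfreq_filter(calls, data.frame(key = "c1:1:A:T",
                                                frequency = 1.5)),
               "\\[0, 1\\]")
})

test_that("classifier labels obvious reference, germline and somatic sites", {
  ref0 <- classify_somatic(100L, 0L, 100L, 0L)
  expect_equal(ref0$label, "reference_noise")
  expect_lte(ref0$somatic_margin, 0)

  germ <- classify_somatic(100L, 50L, 100L, 48L)
  expect_equal(germ$label, "germline")

  som <- classify_somatic(100L, 30L, 100L, 0L)
  expect_equal(som$label, "somatic")
  expect_gt(som$somatic_margin, 5)
})

test_that("classifier log-likelihoods match an independent log-pmf oracle", {
  e <- 0.001
  grid <- expand.grid(t_dp = c(30L, 100L), t_alt = c(0L, 1L, 5L, 30L),
                      n_dp = c(25L, 80L), n_alt = c(0L, 2L, 12L))
  grid <- grid[grid$t_alt <= grid$t_dp & grid$n_alt <= grid$n_dp, ]
  res <- classify_somatic(grid$t_dp, grid$t_alt, grid$n_dp, grid$n_alt, e)
  for (i in seq_len(nrow(grid))) {
    t_dp <- grid$t_dp[i]; t_alt <- grid$t_alt[i]
    n_dp <- grid$n_dp[i]; n_alt <- grid$n_alt[i]
    ll_ref <- log_binom_pmf(t_alt, t_dp, e) + log_binom_pmf(n_alt, n_dp, e)
    ll_germ <- log_binom_pmf(t_alt, t_dp, 0.5) +
      log_binom_pmf(n_alt, n_dp, 0.5)
    vaf <- max(t_alt / t_dp, e)
    ll_som <- (if (t_alt == t_dp) 0 else
      log_binom_pmf(t_alt, t_dp, vaf)) + log_binom_pmf(n_alt, n_dp, e)
    expect_equal(res$ll_reference_noise[i], ll_ref, tolerance = 1e-10)
    expect_equal(res$ll_germline[i], ll_germ, tolerance = 1e-10)
    expect_equal(res$ll_somatic[i], ll_som, tolerance = 1e-10)
    expect_equal(res$somatic_margin[i], ll_som - max(ll_ref, ll_germ),
                 tolerance = 1e-10)
  }
})

test_that("somatic margin rises with alt evidence against the noise model", {
  res <- classify_somatic(rep(100L, 41), 0:40, rep(100L, 41), rep(0L, 41))
  # against reference noise the margin is monotone over the whole grid
  expect_true(all(diff(res$ll_somatic - res$ll_reference_noise) >= -1e-9))
  # the full margin is monotone wherever reference noise is still the
  # best competing model; once the germline model overtakes (tumor VAF
  # approaching 0.5) the margin correctly declines
  noise_regime <- res$ll_reference_noise >= res$ll_germline
  expect_true(all(diff(res$somatic_margin[noise_regime]) >= -1e-9))
})

test_that("somatic filter applies the margin threshold inclusively", {
  calls <- mk_calls("c1", 1L, "A", "T", tumor_depth = 100L,
                    tumor_alt = 30L, normal_depth = 100L, normal_alt = 0L)
  m <- classify_somatic(100L, 30L, 100L, 0L)$somatic_margin
  expect_equal(nrow(somatic_filter(calls, threshold = m)), 1)
  expect_equal(nrow(somatic_filter(calls, threshold = m + 1e-6)), 0)
  expect_error(classify_somatic(0L, 0L, 10L, 0L), "positive depth")
  expect_error(classify_somatic(10L, 0L, 10L, 0L, error_rate = 0.7),
               "error_rate")
})

# A 10-call fixture engineered so each cascade stage removes exactly one
# call: attrition must read 10 -> 9 -> 8 -> 7 -> 6.
cascade_fixture <- function() {
  calls <- mk_calls(rep("c1", 10), 1:10, rep("A", 10), rep("T", 10),
                    tumor_depth = 100L, tumor_alt = 30L,
                    normal_depth = 100L, normal_alt = 0L)
  calls$tumor_depth[1] <- 15L; calls$tumor_alt[1] <- 5L  # fails coverage
  # pos 2 blacklisted; pos 3 common in population
  calls$tumor_alt[4] <- 50L; calls$normal_alt[4] <- 49L  # germline-like
  calls$vaf <- calls$tumor_alt / calls$tumor_depth
  list(calls = calls,
       pon = "c1:2:A:T",
       popfreq = data.frame(key = "c1:3:A:T", frequency = 0.01))
}

test_that("the cascade applies filters in order and reports attrition", {
  fx <- cascade_fixture()
  res <- run_filter_cascade(fx$calls, pon = fx$pon, popfreq = fx$popfreq)
  expect_equal(res$attrition$stage,
               c("coverage", "pon", "popfreq", "somatic_classifier"))
  expect_equal(res$attrition$n_in, c(10L, 9L, 8L, 7L))
  expect_equal(res$attrition$n_out, c(9L, 8L, 7L, 6L))
  expect_setequal(call_key(res$calls),
                  paste0("c1:", 5:10, ":A:T"))
  # four pass entries recorded on every survivor
  expect_true(all(vapply(strsplit(res$calls$filter_history, ";"),
                         length, 0L) == 4))
})

test_that("filter order changes attribution but not the surviving set", {
  fx <- cascade_fixture()
  ordered <- run_filter_cascade(fx$calls, fx$pon, fx$popfreq)$calls
  permuted <- somatic_filter(
    popfreq_filter(
      pon_filter(
        coverage_filter(fx$calls) , fx$pon), fx$popfreq))
  permuted2 <- coverage_filter(
    pon_filter(
      somatic_filter(
        popfreq_filter(fx$calls, fx$popfreq)), fx$pon))
  expect_setequal(call_key(ordered), call_key(permuted))
  expect_setequal(call_key(ordered), call_key(permuted2))
})

test_that("each filter is idempotent on its own output", {
  fx <- cascade_fixture()
  once <- coverage_filter(fx$calls)
  expect_equal(nrow(coverage_filter(once)), nrow(once))
  once <- somatic_filter(fx$calls)
  expect_equal(call_key(somatic_filter(once)), call_key(once))
})
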
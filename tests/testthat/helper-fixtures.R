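# Shared fixtures: tiny references, call builders and independent oracles
# used across test files.  Everything is built in code at test time.

# A hand-written reference with known CpG motifs and homopolymer runs.
#   run1: pos 1..12  "TTGCAAAAATTT"  (C at 4, A-run 5..9; for left-align)
#   cpg1: "AACGTTACGAA"              (CG at 3-4 and 8-9)
tiny_ref <- function() {
  panel_ref(c(run1 = "TTGCAAAAATTT",
              cpg1 = "AACGTTACGAA"))
}

# Minimal call rows with sensible count defaults.
mk_calls <- function(contig, pos, ref, alt, sample_id = "S1",
                     callers = "mutect", tumor_depth = 100L,
                     tumor_alt = 30L, normal_depth = 100L,
                     normal_alt = 0L, ...) {
  variant_calls(sample_id = sample_id, contig = contig, pos = pos,
                ref = ref, alt = alt, callers = callers,
                tumor_depth = tumor_depth, tumor_alt = tumor_alt,
                normal_depth = normal_depth, normal_alt = normal_alt, ...)
}

# A small simulation config that keeps cohort tests fast.
small_sim <- function(...) {
  args <- list(n_pairs = 8, n_genes = 6, exons_per_gene = 3,
               exon_length = 120, seed = 11)
  user <- list(...)
  args[names(user)] <- user
  do.call(simulation_config, args)
}

# Apply a variant to a contig sequence; ground truth for normalization.
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(seq, 1, pos - 1), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# Independent binomial log-pmf (lgamma form; no dbinom).
log_binom_pmf <- function(k, n, p) {
  lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
    k * log(p) + (n - k) * log1p(-p)
}

# Brute-force Benjamini-Hochberg: sort, p_(i) * m / i, cumulative min from
# the largest, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force evaluation of the SNV ensemble expression over key sets.
snv_merge_oracle <- function(keysets) {
  inter <- if (all(c("samtools", "sniper") %in% names(keysets))) {
    intersect(keysets[["samtools"]], keysets[["sniper"]])
  } else character(0)
  uni <- unique(unlist(keysets[intersect(c("varscan", "strelka", "mutect"),
                                         names(keysets))]))
  sort(unique(c(inter, uni)))
}

# Exact two-sided Fisher p by hypergeometric enumeration over all tables
# with the observed margins.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- vapply(support, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
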
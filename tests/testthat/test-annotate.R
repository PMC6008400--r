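# Hand-built single-exon gene: CDS = ATG GGA CAA TGG TAG (M G Q W *),
# placed with 10 bp of flanking sequence either side.
plus_strand_panel <- function() {
  cds_seq <- "ATGGGACAATGGTAG"
  flank <- "TTTTTTTTTT"
  contig <- paste0(flank, cds_seq, flank)
  genes <- list(G1 = list(
    symbol = "G1",
    intervals = data.frame(contig = "G1", start = 6L, end = 30L),
    cds = data.frame(contig = "G1", start = 11L, end = 25L, strand = "+",
                     exon_index = 1L)))
  structure(list(genes = genes, reference = panel_ref(c(G1 = contig))),
            class = "gene_panel")
}

# The same gene on the minus strand: contig is the reverse complement, so
# the CDS occupies the mirrored coordinates and is read right-to-left.
minus_strand_panel <- function() {
  plus <- plus_strand_panel()
  contig <- bbdsomatic:::rev_comp(unclass(plus$reference)[["G1"]])
  n <- nchar(contig)
  genes <- list(G1 = list(
    symbol = "G1",
    intervals = data.frame(contig = "G1", start = n - 30L + 1L,
                           end = n - 6L + 1L),
    cds = data.frame(contig = "G1", start = n - 25L + 1L,
                     end = n - 11L + 1L, strand = "-", exon_index = 1L)))
  structure(list(genes = genes, reference = panel_ref(c(G1 = contig))),
            class = "gene_panel")
}

ann1 <- function(panel, pos, ref, alt) {
  out <- annotate_calls(mk_calls("G1", pos, ref, alt), panel)
  out[, c("gene", "effect", "residue")]
}

test_that("coding SNVs classify by codon change on the plus strand", {
  p <- plus_strand_panel()
  # GGA -> GGG at codon 2 third base (pos 16): silent (Gly)
  expect_equal(ann1(p, 16L, "A", "G"),
               data.frame(gene = "G1", effect = "silent", residue = 2L))
  # CAA -> TAA at codon 3 first base (pos 17): nonsense
  expect_equal(ann1(p, 17L, "C", "T"),
               data.frame(gene = "G1", effect = "nonsense", residue = 3L))
  # GGA -> GAA at codon 2 second base (pos 15): missense
  expect_equal(ann1(p, 15L, "G", "A"),
               data.frame(gene = "G1", effect = "missense", residue = 2L))
})

test_that("minus-strand annotation equals the mirrored construction", {
  m <- minus_strand_panel()
  n <- nchar(unclass(m$reference)[["G1"]])
  # image of plus pos 16 A>G is minus pos n-16+1 T>C
  expect_equal(ann1(m, n - 16L + 1L, "T", "C"),
               data.frame(gene = "G1", effect = "silent", residue = 2L))
  expect_equal(ann1(m, n - 17L + 1L, "G", "A"),
               data.frame(gene = "G1", effect = "nonsense", residue = 3L))
  expect_equal(ann1(m, n - 15L + 1L, "C", "T"),
               data.frame(gene = "G1", effect = "missense", residue = 2L))
})

test_that("in-CDS indels are frameshift unless a multiple of three", {
  p <- plus_strand_panel()
  seq <- unclass(p$reference)[["G1"]]
  # 2-bp deletion wholly inside CDS
  ref2 <- substr(seq, 14, 16)
  expect_equal(ann1(p, 14L, ref2, substr(ref2, 1, 1))$effect, "frameshift")
  # 3-bp deletion: inframe
  ref3 <- substr(seq, 14, 17)
  expect_equal(ann1(p, 14L, ref3, substr(ref3, 1, 1))$effect, "inframe")
  # 1-bp insertion inside CDS: frameshift
  anchor <- substr(seq, 14, 14)
  expect_equal(ann1(p, 14L, anchor, paste0(anchor, "A"))$effect,
               "frameshift")
})

test_that("splice window and noncoding classification follow the panel", {
  p <- plus_strand_panel()
  # 2 bp before CDS start (pos 9, 10): splice; pos 8: noncoding
  expect_equal(ann1(p, 10L, "T", "A")$effect, "splice")
  expect_equal(ann1(p, 9L, "T", "A")$effect, "splice")
  expect_equal(ann1(p, 8L, "T", "A")$effect, "noncoding")
  # 2 bp after CDS end
  expect_equal(ann1(p, 26L, "T", "A")$effect, "splice")
  expect_equal(ann1(p, 28L, "T", "A")$effect, "noncoding")
  expect_error(ann1(p, 2L, "T", "A"), "outside all panel intervals")
})

test_that("non-silent covers protein-altering effects only", {
  expect_true(all(is_non_silent(c("missense", "nonsense", "splice",
                                  "frameshift", "inframe"))))
  expect_false(any(is_non_silent(c("silent", "noncoding",
                                   "unannotated"))))
})

test_that("full CDS translation matches an independent Biostrings path", {
  cfg <- small_sim()
  panel <- generate_panel(cfg)
  for (sym in names(panel$genes)[1:3]) {
    g <- panel$genes[[sym]]
    contig_seq <- unclass(panel$reference)[[g$cds$contig[1]]]
    cds <- g$cds[order(g$cds$start), ]  # genomic left-to-right
    genomic <- paste(mapply(function(s, e) substr(contig_seq, s, e),
                            cds$start, cds$end), collapse = "")
    dna <- if (cds$strand[1] == "+") genomic else {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(genomic)))
    }
    expected <- as.character(Biostrings::translate(
      Biostrings::DNAString(dna), no.init.codon = TRUE))
    expect_equal(cds_protein(panel, sym), expected)
  }
})

test_that("simulated cohort calls annotate without leaving the panel", {
  cfg <- small_sim()
  cohort <- generate_cohort(cfg)
  res <- run_cohort_analysis(cohort, pipeline_config(
    sim = cfg, n_permutations = 50))
  expect_true(all(res$calls$effect %in%
                    c("silent", "missense", "nonsense", "splice",
                      "frameshift", "inframe", "noncoding")))
  expect_true(all(!is.na(res$calls$gene)))
})
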
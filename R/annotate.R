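# Effect annotation against the panel CDS model.
#
# One CDS model per gene (single transcript).  Coding SNVs are translated
# through the standard nuclear codon table on the coding strand; indels in
# CDS are frameshift unless their length is a multiple of 3; variants
# within 2 bp outside a CDS exon boundary are splice; anything else inside
# the panel is noncoding.

NON_SILENT_EFFECTS <- c("missense", "nonsense", "splice", "frameshift",
                        "inframe")

# Genomic positions of a gene's CDS in coding (5'->3' of the mRNA) order.
cds_coding_positions <- function(gene) {
  cds <- gene$cds[order(gene$cds$exon_index), , drop = FALSE]
  unlist(lapply(seq_len(nrow(cds)), function(i) {
    if (cds$strand[i] == "+") seq(cds$start[i], cds$end[i])
    else seq(cds$end[i], cds$start[i])
  }), use.names = FALSE)
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

# Coding-strand base at coding index i (complement on minus strand).
coding_base <- function(reference, gene, genomic_pos) {
  b <- ref_seq(reference, gene$cds$contig[1], genomic_pos, genomic_pos)
  if (gene$cds$strand[1] == "-") comp_base(b) else b
}

#' Translate a gene's full CDS to protein
#'
#' @param panel a \code{gene_panel}.
#' @param symbol gene symbol.
#' @return single-character-per-residue protein string (stop = \code{*}).
#' @export
cds_protein <- function(panel, symbol) {
  gene <- panel$genes[[symbol]]
  if (is.null(gene) || nrow(gene$cds) == 0)
    stop("no CDS model for gene ", symbol)
  pos <- cds_coding_positions(gene)
  bases <- vapply(pos, function(p) coding_base(panel$reference, gene, p),
                  character(1))
  dna <- paste(bases, collapse = "")
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

# Interval lookup table: one row per panel interval.
panel_interval_table <- function(panel) {
  do.call(rbind, lapply(panel$genes, function(g) {
    data.frame(gene = g$symbol, contig = g$intervals$contig,
               start = g$intervals$start, end = g$intervals$end,
               stringsAsFactors = FALSE)
  }))
}

# Rightmost genomic position affected by any equivalent placement of a
# left-aligned indel (repeat-context walk).  An indel in a repeat run
# affects the whole run, so annotation must consider its full span.
indel_equiv_end <- function(contig, pos, ref, alt, reference) {
  seg <- if (nchar(ref) > nchar(alt)) substr(ref, 2, nchar(ref))
         else substr(alt, 2, nchar(alt))
  end <- pos + nchar(ref) - 1L
  if (!nzchar(seg)) return(end)
  j <- 0L
  while (j < 200L) {
    nxt <- ref_seq(reference, contig, pos + nchar(ref) + j,
                   pos + nchar(ref) + j)
    if (is.na(nxt) || nxt != substr(seg, j %% nchar(seg) + 1L,
                                    j %% nchar(seg) + 1L)) break
    j <- j + 1L
  }
  pos + nchar(ref) - 1L + j
}

annotate_one <- function(contig, pos, ref, alt, panel, itab,
                         splice_window = 2L) {
  snv <- nchar(ref) == 1 && nchar(alt) == 1
  span_end <- if (snv) pos else
    indel_equiv_end(contig, pos, ref, alt, panel$reference)
  hit <- itab[itab$contig == contig & itab$start <= span_end &
                itab$end >= pos, , drop = FALSE]
  if (nrow(hit) == 0)
    stop("variant outside all panel intervals: ", contig, ":", pos)
  gene <- panel$genes[[hit$gene[1]]]
  if (nrow(gene$cds) == 0) {
    return(list(gene = gene$symbol, effect = "noncoding",
                residue = NA_integer_))
  }
  cpos <- cds_coding_positions(gene)
  affected <- seq(pos, span_end)
  in_cds <- if (snv) pos %in% cpos else {
    # any equivalent placement touching CDS: deletion affects bases after
    # the anchor, insertion the junction, across the whole repeat span
    region <- seq(min(pos + 1L, span_end), max(span_end, pos + 1L))
    any(region %in% cpos)
  }
  if (in_cds && !snv) {
    indel_len <- abs(nchar(ref) - nchar(alt))
    eff <- if (indel_len %% 3L == 0L) "inframe" else "frameshift"
    ci <- match(intersect(affected, cpos)[1], cpos)
    return(list(gene = gene$symbol, effect = eff,
                residue = as.integer(ceiling(ci / 3))))
  }
  if (in_cds && snv) {
    i <- match(pos, cpos)
    codon_idx <- ceiling(i / 3)
    codon_pos <- (i - 1L) %% 3L + 1L
    codon_genomic <- cpos[((codon_idx - 1L) * 3L + 1L):(codon_idx * 3L)]
    ref_codon <- paste(vapply(codon_genomic, function(p) {
      coding_base(panel$reference, gene, p)
    }, character(1)), collapse = "")
    alt_base <- if (gene$cds$strand[1] == "-") comp_base(alt) else alt
    alt_codon <- ref_codon
    substr(alt_codon, codon_pos, codon_pos) <- alt_base
    ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
    alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
    eff <- if (ref_aa == alt_aa) "silent"
           else if (alt_aa == "*") "nonsense"
           else "missense"
    return(list(gene = gene$symbol, effect = eff,
                residue = as.integer(codon_idx)))
  }
  # not coding: splice if within the window outside a CDS exon boundary
  for (k in seq_len(nrow(gene$cds))) {
    s <- gene$cds$start[k]; e <- gene$cds$end[k]
    near <- (max(affected) >= s - splice_window && min(affected) < s) ||
            (min(affected) <= e + splice_window && max(affected) > e)
    if (near)
      return(list(gene = gene$symbol, effect = "splice",
                  residue = NA_integer_))
  }
  list(gene = gene$symbol, effect = "noncoding", residue = NA_integer_)
}

#' Annotate calls with gene and predicted coding effect
#'
#' Effects: \code{silent}, \code{missense}, \code{nonsense} (stop gain),
#' \code{frameshift}, \code{inframe}, \code{splice} (within 2 bp outside a
#' CDS exon boundary), \code{noncoding} (in panel, outside CDS).
#' \code{residue} is the 1-based amino-acid position for coding variants.
#'
#' @param calls call table.
#' @param panel a \code{gene_panel} with CDS models.
#' @param splice_window bp outside a CDS exon boundary counted as splice.
#' @return the call table with gene/effect/residue columns filled.
#' @export
annotate_calls <- function(calls, panel, splice_window = 2L) {
  if (nrow(calls) == 0) return(calls)
  itab <- panel_interval_table(panel)
  for (i in seq_len(nrow(calls))) {
    a <- annotate_one(calls$contig[i], calls$pos[i], calls$ref[i],
                      calls$alt[i], panel, itab, splice_window)
    calls$gene[i] <- a$gene
    calls$effect[i] <- a$effect
    calls$residue[i] <- a$residue
  }
  calls
}

#' Is an effect non-silent?
#'
#' Non-silent effects alter the protein product: missense, nonsense,
#' splice, frameshift and in-frame indels.  Silent and noncoding variants
#' count toward overall mutation totals but not non-silent totals.
#'
#' @param effect character vector of effect labels.
#' @return logical vector.
#' @export
is_non_silent <- function(effect) {
  effect %in% NON_SILENT_EFFECTS
}
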
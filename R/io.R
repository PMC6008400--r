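# Readers/writers for the standard formats the pipeline touches.
#
# VCF parsing goes through vcfR; the emitter is a small text writer because
# the pipeline's VCF output must stay uncompressed and round-trippable.
# Coordinates are 1-based closed internally (VCF convention); BED input is
# converted on read.

VCF_HEADER_LINES <- c(
  "##fileformat=VCFv4.2",
  "##source=bbdsomatic",
  "##INFO=<ID=CALLERS,Number=1,Type=String,Description=\"Plus-joined ensemble caller labels\">",
  "##INFO=<ID=FH,Number=1,Type=String,Description=\"Pipe-joined filter history (name:pass|name:fail)\">",
  "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene symbol\">",
  "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Predicted coding effect\">",
  "##INFO=<ID=RESIDUE,Number=1,Type=Integer,Description=\"1-based amino-acid position\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
  "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Alt-supporting read count\">"
)

info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  out <- rep(NA_character_, length(info))
  hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
  val <- sub(paste0("^.*", key, "="), "", m)
  out[hit] <- val
  out
}

#' Read somatic calls from a VCF file
#'
#' Reads a VCF 4.x file into the package's call table.  Multi-allelic records
#' are decomposed into one call per ALT allele (read counts are reused across
#' the decomposed alleles).  Tumor/normal depth and alt-support are taken from
#' per-sample FORMAT fields.
#'
#' @param path VCF file (uncompressed or bgzipped; anything vcfR reads).
#' @param sample_id sample identifier to stamp on every call.
#' @param caller_label caller provenance for all calls; when \code{NULL} the
#'   \code{CALLERS} INFO key written by \code{\link{write_vcf}} is used.
#' @param format_depth,format_alt FORMAT field names for depth and
#'   alt-support.
#' @param tumor_col,normal_col names of the tumor and normal sample columns.
#' @return A call data.frame (see \code{\link{variant_calls}}).
#' @export
read_vcf <- function(path, sample_id, caller_label = NULL,
                     format_depth = "DP", format_alt = "AD",
                     tumor_col = "TUMOR", normal_col = "NORMAL") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(variant_calls())
  gt <- v@gt
  for (col in c(tumor_col, normal_col)) {
    if (!col %in% colnames(gt))
      stop("configuration error: sample column '", col, "' not in ", path)
  }
  fmt <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
  get_fmt <- function(col, field) {
    vals <- strsplit(gt[, col], ":", fixed = TRUE)
    vapply(seq_along(vals), function(i) {
      j <- match(field, fmt[[i]])
      if (is.na(j) || j > length(vals[[i]]))
        stop("configuration error: FORMAT field '", field,
             "' missing in ", path)
      as.integer(vals[[i]][[j]])
    }, integer(1))
  }
  t_dp <- get_fmt(tumor_col, format_depth)
  t_ad <- get_fmt(tumor_col, format_alt)
  n_dp <- get_fmt(normal_col, format_depth)
  n_ad <- get_fmt(normal_col, format_alt)
  callers <- info_field(fix$INFO, "CALLERS")
  if (!is.null(caller_label)) {
    check_caller_labels(caller_label)
    callers <- rep(caller_label, nrow(fix))
  } else if (anyNA(callers)) {
    stop("no caller_label given and CALLERS INFO key absent in ", path)
  }
  fh <- info_field(fix$INFO, "FH")
  fh <- ifelse(is.na(fh), "", gsub("|", ";", fh, fixed = TRUE))
  gene <- info_field(fix$INFO, "GENE")
  effect <- info_field(fix$INFO, "EFFECT")
  residue <- suppressWarnings(as.integer(info_field(fix$INFO, "RESIDUE")))

  # decompose multi-allelic ALT fields
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alts))
  variant_calls(
    sample_id = sample_id,
    contig = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alts),
    callers = callers[idx],
    tumor_depth = t_dp[idx], tumor_alt = t_ad[idx],
    normal_depth = n_dp[idx], normal_alt = n_ad[idx],
    gene = gene[idx], effect = effect[idx], residue = residue[idx],
    filter_history = fh[idx]
  )
}

#' Write a call table to VCF
#'
#' Emits an uncompressed VCF 4.2 with one record per call, sorted by
#' (contig, pos, ref, alt), with caller provenance, filter history and any
#' effect annotation encoded as INFO keys, and tumor/normal counts as
#' \code{DP:AD} sample columns.  \code{read_vcf} round-trips the output.
#'
#' @param calls call table for a single sample.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(calls, path) {
  validate_calls(calls)
  if (nrow(calls) > 0 && length(unique(calls$sample_id)) > 1)
    stop("write_vcf expects calls from a single sample")
  calls <- sort_calls(calls)
  contigs <- unique(calls$contig)
  bad <- contigs[is.na(contigs) | !nzchar(contigs)]
  if (length(bad) > 0)
    stop("unsortable contig names: ", paste(bad, collapse = ", "))
  info <- paste0("CALLERS=", calls$callers)
  has_fh <- nzchar(calls$filter_history)
  info[has_fh] <- paste0(info[has_fh], ";FH=",
                         gsub(";", "|", calls$filter_history[has_fh],
                              fixed = TRUE))
  ann <- !is.na(calls$gene)
  info[ann] <- paste0(info[ann], ";GENE=", calls$gene[ann])
  ann <- !is.na(calls$effect)
  info[ann] <- paste0(info[ann], ";EFFECT=", calls$effect[ann])
  ann <- !is.na(calls$residue)
  info[ann] <- paste0(info[ann], ";RESIDUE=", calls$residue[ann])
  body <- if (nrow(calls) == 0) character() else paste(
    calls$contig, calls$pos, ".", calls$ref, calls$alt, ".", "PASS", info,
    "DP:AD",
    paste0(calls$tumor_depth, ":", calls$tumor_alt),
    paste0(calls$normal_depth, ":", calls$normal_alt),
    sep = "\t"
  )
  header <- c(
    VCF_HEADER_LINES,
    paste0("##contig=<ID=", sort(contigs), ">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", "NORMAL", sep = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a read-count sidecar table
#'
#' The sidecar is the single source of truth for depths and alt support
#' (one row per sample/site/allele), mirroring bam-readcount-style output.
#'
#' @param path TSV with columns sample_id, contig, pos, ref, alt,
#'   tumor_depth, tumor_alt, normal_depth, normal_alt.
#' @export
read_readcounts <- function(path) {
  rc <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = c(
                     sample_id = "character", contig = "character",
                     pos = "integer", ref = "character", alt = "character",
                     tumor_depth = "integer", tumor_alt = "integer",
                     normal_depth = "integer", normal_alt = "integer"))
  needed <- c("sample_id", "contig", "pos", "ref", "alt", "tumor_depth",
              "tumor_alt", "normal_depth", "normal_alt")
  missing_cols <- setdiff(needed, names(rc))
  if (length(missing_cols) > 0)
    stop("read-count sidecar missing columns: ",
         paste(missing_cols, collapse = ", "))
  rc
}

#' @rdname read_readcounts
#' @param rc read-count data.frame.
#' @export
write_readcounts <- function(rc, path) {
  write.table(rc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a case/control pair manifest
#'
#' @param path TSV with columns pair_id, case_sample_id, control_sample_id,
#'   pair_kind (\code{case_control} or \code{bbd_ibc}).
#' @return data.frame of sample pairs; duplicate pair ids or a sample id
#'   appearing in more than one pair are errors.
#' @export
read_pair_manifest <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = "character")
  validate_manifest(m)
}

#' @rdname read_pair_manifest
#' @param manifest a manifest data.frame.
#' @export
validate_manifest <- function(manifest) {
  needed <- c("pair_id", "case_sample_id", "control_sample_id", "pair_kind")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols) > 0)
    stop("pair manifest missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(manifest$pair_id))
    stop("duplicate pair_id in manifest")
  samples <- c(manifest$case_sample_id, manifest$control_sample_id)
  if (anyDuplicated(samples))
    stop("sample id appears in more than one manifest slot: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (any(manifest$case_sample_id == manifest$control_sample_id))
    stop("case and control sample ids must differ within a pair")
  if (!all(manifest$pair_kind %in% c("case_control", "bbd_ibc")))
    stop("pair_kind must be 'case_control' or 'bbd_ibc'")
  manifest
}

#' @rdname read_pair_manifest
#' @export
write_pair_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#' @return named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("GMT line with fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read a population allele-frequency table
#'
#' @param path TSV with columns contig, pos, ref, alt, frequency.
#' @return data.frame with a \code{key} column and \code{frequency} in
#'   \code{[0, 1]} (out-of-range frequencies are errors).
#' @export
read_popfreq <- function(path) {
  pf <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(contig = "character", pos = "integer",
                                  ref = "character", alt = "character",
                                  frequency = "numeric"))
  if (any(pf$frequency < 0 | pf$frequency > 1))
    stop("population frequencies must be in [0, 1]")
  pf$key <- call_key(pf)
  pf
}

#' @rdname read_popfreq
#' @export
write_popfreq <- function(pf, path) {
  write.table(pf[, c("contig", "pos", "ref", "alt", "frequency")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a panel-of-normals blacklist
#'
#' @param path TSV with columns contig, pos, ref, alt (normalized keys).
#' @return character vector of blacklist keys.
#' @export
read_pon <- function(path) {
  pon <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(contig = "character", pos = "integer",
                                   ref = "character", alt = "character"))
  call_key(pon)
}

#' @rdname read_pon
#' @param pon data.frame with contig/pos/ref/alt columns.
#' @export
write_pon <- function(pon, path) {
  write.table(pon[, c("contig", "pos", "ref", "alt")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a targeted gene panel (BED + FASTA + CDS model)
#'
#' BED intervals (0-based half-open) are converted to the package's 1-based
#' closed convention.  The CDS model lists coding exons in coding order with
#' strand; each complete model must have total length divisible by 3.
#'
#' @param bed_path BED file: contig, start, end, gene symbol.
#' @param fasta_path panel reference FASTA.
#' @param cds_path TSV with columns gene, contig, start, end, strand,
#'   exon_index (1-based closed coordinates).
#' @return A \code{gene_panel} object: list with \code{genes} (per-gene list
#'   of symbol/intervals/cds) and \code{reference} (a \code{panel_ref}).
#' @export
read_panel <- function(bed_path, fasta_path, cds_path) {
  bed <- read.table(bed_path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE,
                    col.names = c("contig", "start", "end", "gene"),
                    colClasses = c("character", "integer", "integer",
                                   "character"))
  bed$start <- bed$start + 1L  # BED half-open 0-based -> 1-based closed
  cds <- read.table(cds_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(gene = "character", contig = "character",
                                   start = "integer", end = "integer",
                                   strand = "character",
                                   exon_index = "integer"))
  orphan <- setdiff(unique(cds$gene), unique(bed$gene))
  if (length(orphan) > 0)
    stop("gene(s) in CDS model absent from BED: ",
         paste(orphan, collapse = ", "))
  reference <- read_panel_fasta(fasta_path)
  genes <- lapply(split(bed, bed$gene), function(b) {
    b <- b[order(b$contig, b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)] &
                           b$contig[-1] == b$contig[-nrow(b)]))
      stop("overlapping panel intervals for gene ", b$gene[1])
    g_cds <- cds[cds$gene == b$gene[1], , drop = FALSE]
    g_cds <- g_cds[order(g_cds$exon_index), , drop = FALSE]
    if (nrow(g_cds) > 0) {
      len <- sum(g_cds$end - g_cds$start + 1L)
      if (len %% 3L != 0L)
        stop("CDS length for gene ", b$gene[1], " not divisible by 3")
    }
    list(symbol = b$gene[1],
         intervals = b[, c("contig", "start", "end")],
         cds = g_cds[, c("contig", "start", "end", "strand", "exon_index")])
  })
  structure(list(genes = genes, reference = reference),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("gene_panel:", length(x$genes), "genes,",
      length(unclass(x$reference)), "contigs\n")
  invisible(x)
}

#' The published 83-gene targeted panel gene list
#'
#' Symbols of the breast-cancer panel targeted by the study design this
#' package reproduces, shipped as a plain-text file.
#'
#' @return character vector of 83 unique gene symbols.
#' @export
panel_gene_symbols <- function() {
  path <- system.file("extdata", "panel_genes.txt", package = "bbdsomatic",
                      mustWork = TRUE)
  readLines(path)
}
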
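# Domain types: variant calls are plain data.frames with a fixed column set.
# A "variant key" is the canonical identity (contig, pos, ref, alt) with pos
# 1-based and alleles uppercase A/C/G/T strings.

SNV_CALLERS <- c("samtools", "sniper", "varscan", "strelka", "mutect")
INDEL_CALLERS <- c("gatk", "varscan", "strelka")
ALL_CALLERS <- union(SNV_CALLERS, INDEL_CALLERS)

EFFECT_LEVELS <- c("silent", "missense", "nonsense", "splice", "frameshift",
                   "inframe", "noncoding", "unannotated")

CALL_COLUMNS <- c("sample_id", "contig", "pos", "ref", "alt", "callers",
                  "tumor_depth", "tumor_alt", "normal_depth", "normal_alt",
                  "vaf", "gene", "effect", "residue", "filter_history")

#' Construct a validated variant-call table
#'
#' The package-wide representation of variant calls is a data.frame with one
#' row per (sample, variant) observation.  Alleles follow VCF conventions:
#' 1-based positions, uppercase \code{A/C/G/T} strings, indels anchored with a
#' leading reference base.  \code{callers} is a \code{"+"}-joined sorted label
#' set (e.g. \code{"mutect+strelka"}); \code{filter_history} accumulates
#' \code{"name:pass"} / \code{"name:fail"} entries separated by \code{";"}.
#'
#' @param sample_id character sample identifiers.
#' @param contig,pos,ref,alt variant key fields (pos 1-based).
#' @param callers character, \code{"+"}-joined caller labels per call.
#' @param tumor_depth,tumor_alt,normal_depth,normal_alt read counts.
#' @param gene,effect,residue optional annotation fields (NA until annotated).
#' @param filter_history optional accumulated filter record.
#' @return A data.frame with the package's canonical call columns, including
#'   a recomputed \code{vaf = tumor_alt / tumor_depth} (NA at zero depth).
#' @export
variant_calls <- function(sample_id = character(), contig = character(),
                          pos = integer(), ref = character(),
                          alt = character(), callers = character(),
                          tumor_depth = integer(), tumor_alt = integer(),
                          normal_depth = integer(), normal_alt = integer(),
                          gene = NA_character_, effect = NA_character_,
                          residue = NA_integer_, filter_history = "") {
  n <- length(contig)
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    contig = as.character(contig),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    callers = rep_len(as.character(callers), n),
    tumor_depth = as.integer(rep_len(tumor_depth, n)),
    tumor_alt = as.integer(rep_len(tumor_alt, n)),
    normal_depth = as.integer(rep_len(normal_depth, n)),
    normal_alt = as.integer(rep_len(normal_alt, n)),
    gene = rep_len(as.character(gene), n),
    effect = rep_len(as.character(effect), n),
    residue = as.integer(rep_len(residue, n)),
    filter_history = rep_len(as.character(filter_history), n),
    stringsAsFactors = FALSE
  )
  df$vaf <- ifelse(df$tumor_depth > 0, df$tumor_alt / df$tumor_depth, NA_real_)
  df <- df[, CALL_COLUMNS]
  validate_calls(df)
  df
}

#' @rdname variant_calls
#' @param calls a candidate call data.frame.
#' @export
validate_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  missing_cols <- setdiff(CALL_COLUMNS, names(calls))
  if (length(missing_cols) > 0)
    stop("call table missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(calls) == 0) return(invisible(calls))
  bad <- !grepl("^[ACGT]+$", calls$ref) | !grepl("^[ACGT]+$", calls$alt)
  if (any(bad))
    stop("alleles must be non-empty uppercase A/C/G/T strings (rows ",
         paste(head(which(bad)), collapse = ","), ")")
  if (any(calls$ref == calls$alt))
    stop("ref and alt alleles must differ")
  if (any(calls$pos < 1)) stop("positions are 1-based; pos < 1 found")
  cnt_bad <- calls$tumor_alt > calls$tumor_depth |
    calls$normal_alt > calls$normal_depth |
    calls$tumor_alt < 0 | calls$normal_alt < 0 |
    calls$tumor_depth < 0 | calls$normal_depth < 0
  if (any(cnt_bad, na.rm = TRUE))
    stop("read counts must satisfy 0 <= alt <= depth")
  invisible(calls)
}

#' Canonical string form of a variant key
#'
#' @param calls a call data.frame (or any data.frame with contig/pos/ref/alt).
#' @return character vector \code{"contig:pos:ref:alt"}, usable as a set
#'   membership key.
#' @export
call_key <- function(calls) {
  paste(calls$contig, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' @rdname call_key
#' @export
is_snv <- function(calls) {
  nchar(calls$ref) == 1L & nchar(calls$alt) == 1L
}

# Split "a+b" caller strings into sorted label vectors and back.
split_callers <- function(x) strsplit(x, "+", fixed = TRUE)

join_callers <- function(labels) paste(sort(unique(labels)), collapse = "+")

check_caller_labels <- function(labels, allowed = ALL_CALLERS) {
  unknown <- setdiff(labels, allowed)
  if (length(unknown) > 0)
    stop("unknown caller label(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  invisible(labels)
}

# Append one filter outcome to the history column of a call table.
append_filter_history <- function(calls, filter_name, keep) {
  entry <- paste0(filter_name, ":", ifelse(keep, "pass", "fail"))
  calls$filter_history <- ifelse(
    nzchar(calls$filter_history),
    paste(calls$filter_history, entry, sep = ";"),
    entry
  )
  calls
}

#' Sort a call table in genomic order
#'
#' Orders by (contig, pos, ref, alt); ties broken lexicographically so the
#' order is total and reproducible.
#' @param calls a call data.frame.
#' @export
sort_calls <- function(calls) {
  calls[order(calls$contig, calls$pos, calls$ref, calls$alt), , drop = FALSE]
}
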
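# Ensemble merge: combine per-caller call sets for one sample using the
# study's set algebra.
#
#   SNVs:   (samtools INTERSECT sniper) UNION varscan UNION strelka UNION mutect
#   indels: gatk UNION varscan UNION strelka
#
# Caller-internal filters (varscan-high-confidence, false-positive filter,
# Strelka depth filters) are assumed already applied to the input VCFs.

merge_expression <- function(keysets, branches_union, branch_intersect) {
  inter <- NULL
  if (length(branch_intersect) > 0) {
    present <- intersect(branch_intersect, names(keysets))
    if (length(present) == length(branch_intersect)) {
      inter <- Reduce(intersect, keysets[branch_intersect])
    }
  }
  uni <- unique(unlist(keysets[intersect(branches_union, names(keysets))]))
  unique(c(inter, uni))
}

# Shared worker: evaluates a set expression over per-caller call tables and
# assembles the merged call table with complete caller provenance and
# sidecar-sourced read counts.
merge_callsets <- function(calls_by_caller, allowed, branches_union,
                           branch_intersect, readcounts = NULL,
                           expect_snv = NULL) {
  check_caller_labels(names(calls_by_caller), allowed)
  calls_by_caller <- calls_by_caller[vapply(calls_by_caller, nrow,
                                            0L) > 0]
  if (length(calls_by_caller) == 0) return(variant_calls())
  sample_ids <- unique(unlist(lapply(calls_by_caller,
                                     function(x) x$sample_id)))
  if (length(sample_ids) > 1)
    stop("merge expects calls from a single sample, got: ",
         paste(sample_ids, collapse = ", "))
  if (!is.null(expect_snv)) {
    for (caller in names(calls_by_caller)) {
      snv <- is_snv(calls_by_caller[[caller]])
      if (expect_snv && any(!snv))
        stop("indel key in SNV bundle for caller ", caller)
      if (!expect_snv && any(snv))
        stop("SNV key in indel bundle for caller ", caller)
    }
  }
  keysets <- lapply(calls_by_caller, call_key)
  keep_keys <- merge_expression(keysets, branches_union, branch_intersect)
  if (length(keep_keys) == 0) return(variant_calls())
  all_calls <- do.call(rbind, c(calls_by_caller,
                                list(make.row.names = FALSE)))
  all_keys <- call_key(all_calls)
  out <- all_calls[match(keep_keys, all_keys), , drop = FALSE]
  # callers field: exact set of input callers containing each key
  out$callers <- vapply(keep_keys, function(k) {
    join_callers(names(keysets)[vapply(keysets, function(ks) k %in% ks,
                                       TRUE)])
  }, character(1), USE.NAMES = FALSE)
  if (!is.null(readcounts)) {
    rc <- readcounts[readcounts$sample_id == sample_ids, , drop = FALSE]
    m <- match(keep_keys, call_key(rc))
    if (anyNA(m))
      stop("read-count sidecar missing sites: ",
           paste(head(keep_keys[is.na(m)]), collapse = ", "))
    out$tumor_depth <- rc$tumor_depth[m]
    out$tumor_alt <- rc$tumor_alt[m]
    out$normal_depth <- rc$normal_depth[m]
    out$normal_alt <- rc$normal_alt[m]
    out$vaf <- ifelse(out$tumor_depth > 0,
                      out$tumor_alt / out$tumor_depth, NA_real_)
  }
  rownames(out) <- NULL
  sort_calls(out)
}

#' Merge per-caller SNV call sets for one sample
#'
#' Implements the ensemble rule
#' \code{(samtools} \eqn{\cap}{ intersect } \code{sniper)} \eqn{\cup}{ union }
#' \code{varscan} \eqn{\cup}{ union } \code{strelka} \eqn{\cup}{ union }
#' \code{mutect}: a key reported only by samtools (or only by Somatic
#' Sniper) is excluded; a key reported by any of the other three callers is
#' included.  The output \code{callers} field records every caller that
#' reported each surviving key.  When a read-count sidecar is supplied it is
#' the single source of truth for depths and alt support, overriding
#' caller-specific counts.
#'
#' @param calls_by_caller named list of single-caller call tables (names
#'   from \code{samtools, sniper, varscan, strelka, mutect}).
#' @param readcounts optional sidecar from \code{\link{read_readcounts}}.
#' @return merged call table, sorted, one row per variant key.
#' @export
merge_snvs <- function(calls_by_caller, readcounts = NULL) {
  merge_callsets(calls_by_caller, allowed = SNV_CALLERS,
                 branches_union = c("varscan", "strelka", "mutect"),
                 branch_intersect = c("samtools", "sniper"),
                 readcounts = readcounts, expect_snv = TRUE)
}

#' Merge per-caller indel call sets for one sample
#'
#' Implements \code{gatk} \eqn{\cup}{ union } \code{varscan}
#' \eqn{\cup}{ union } \code{strelka}.
#'
#' @inheritParams merge_snvs
#' @export
merge_indels <- function(calls_by_caller, readcounts = NULL) {
  merge_callsets(calls_by_caller, allowed = INDEL_CALLERS,
                 branches_union = INDEL_CALLERS,
                 branch_intersect = character(),
                 readcounts = readcounts, expect_snv = FALSE)
}

#' Merge all call sets for one sample (SNVs and indels)
#'
#' Splits each caller's calls into SNV and indel classes, normalizes keys
#' when a reference is given (so representation differences between callers
#' cannot defeat the set algebra), applies \code{\link{merge_snvs}} and
#' \code{\link{merge_indels}}, and concatenates the results.
#'
#' @param calls_by_caller named list of single-caller call tables.
#' @param readcounts optional read-count sidecar.
#' @param reference optional \code{\link{panel_ref}} for key normalization.
#' @export
merge_sample <- function(calls_by_caller, readcounts = NULL,
                         reference = NULL) {
  if (!is.null(reference)) {
    calls_by_caller <- lapply(calls_by_caller, normalize_calls,
                              reference = reference)
    if (!is.null(readcounts)) {
      readcounts <- normalize_calls(readcounts, reference)
      readcounts <- readcounts[!duplicated(
        paste(readcounts$sample_id, call_key(readcounts))), , drop = FALSE]
    }
  }
  snv_bundle <- list()
  indel_bundle <- list()
  for (caller in names(calls_by_caller)) {
    calls <- calls_by_caller[[caller]]
    snv <- is_snv(calls)
    if (caller %in% SNV_CALLERS && any(snv))
      snv_bundle[[caller]] <- calls[snv, , drop = FALSE]
    if (caller %in% INDEL_CALLERS && any(!snv))
      indel_bundle[[caller]] <- calls[!snv, , drop = FALSE]
  }
  out <- rbind(merge_snvs(snv_bundle, readcounts),
               merge_indels(indel_bundle, readcounts))
  rownames(out) <- NULL
  sort_calls(out)
}
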
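# FFPE deamination artifact screen.
#
# Formalin fixation deaminates cytosine, producing spurious low-VAF C>T
# calls preferentially in CpG context.  The screen flags samples carrying
# at least `min_artifacts` putative artifacts (CG>TG context AND
# VAF < vaf_cutoff) and removes exactly those putative artifacts from
# flagged samples; unflagged samples are left untouched.

#' Is a variant in CG>TG deamination context?
#'
#' TRUE iff the SNV is \code{C>T} with reference base \code{G} immediately
#' following, or (when \code{both_strands}) its reverse-strand image
#' \code{G>A} with reference base \code{C} immediately preceding.  Non-SNVs
#' are never context matches; positions lacking the required neighbour at a
#' contig edge return FALSE with a warning.
#'
#' @param contig,pos,ref,alt variant key fields (vectorized).
#' @param reference a \code{\link{panel_ref}}.
#' @param both_strands screen the reverse-strand image too (default TRUE;
#'   deamination is strand-symmetric in sequencing output).
#' @return logical vector.
#' @export
is_ffpe_context <- function(contig, pos, ref, alt, reference,
                            both_strands = TRUE) {
  n <- length(pos)
  out <- logical(n)
  for (i in seq_len(n)) {
    if (nchar(ref[i]) != 1 || nchar(alt[i]) != 1) next
    if (ref[i] == "C" && alt[i] == "T") {
      nxt <- ref_seq(reference, contig[i], pos[i] + 1L, pos[i] + 1L)
      if (is.na(nxt)) {
        warning("no base after ", contig[i], ":", pos[i],
                "; treating as non-CpG context")
        next
      }
      out[i] <- nxt == "G"
    } else if (both_strands && ref[i] == "G" && alt[i] == "A") {
      if (pos[i] <= 1L) {
        warning("no base before ", contig[i], ":", pos[i],
                "; treating as non-CpG context")
        next
      }
      prv <- ref_seq(reference, contig[i], pos[i] - 1L, pos[i] - 1L)
      out[i] <- !is.na(prv) && prv == "C"
    }
  }
  out
}

#' Screen one sample for FFPE artifacts
#'
#' A putative artifact is a call in CG>TG context with VAF strictly below
#' \code{vaf_cutoff}.  If the sample carries at least \code{min_artifacts}
#' of them it is flagged and exactly its putative artifacts are removed
#' (other calls in flagged samples are retained); below the threshold
#' nothing is removed.
#'
#' @param calls call table for a single sample with defined VAFs.
#' @param reference a \code{\link{panel_ref}}.
#' @param vaf_cutoff strict VAF upper bound for an artifact (default 0.10).
#' @param min_artifacts flagging threshold, inclusive (default 3).
#' @param both_strands see \code{\link{is_ffpe_context}}.
#' @return list with \code{calls} (survivors) and \code{report}
#'   (sample_id, n_putative_artifacts, flagged, removed_keys).
#' @export
screen_sample <- function(calls, reference, vaf_cutoff = 0.10,
                          min_artifacts = 3, both_strands = TRUE) {
  sid <- if (nrow(calls) > 0) unique(calls$sample_id) else NA_character_
  if (length(sid) > 1)
    stop("screen_sample expects calls from a single sample")
  context <- if (nrow(calls) > 0) {
    is_ffpe_context(calls$contig, calls$pos, calls$ref, calls$alt,
                    reference, both_strands)
  } else logical(0)
  putative <- context & !is.na(calls$vaf) & calls$vaf < vaf_cutoff
  flagged <- sum(putative) >= min_artifacts
  removed_keys <- if (flagged) call_key(calls[putative, , drop = FALSE])
                  else character(0)
  keep <- if (flagged) !putative else rep(TRUE, nrow(calls))
  calls <- append_filter_history(calls, "ffpe_screen", keep)
  list(calls = calls[keep, , drop = FALSE],
       report = list(sample_id = sid,
                     n_putative_artifacts = sum(putative),
                     flagged = flagged,
                     removed_keys = removed_keys))
}

#' Screen every sample in a cohort for FFPE artifacts
#'
#' @param calls call table covering any number of samples.
#' @inheritParams screen_sample
#' @return list with \code{calls} (survivors across all samples) and
#'   \code{report}: data.frame (sample_id, n_putative_artifacts, flagged,
#'   n_removed) plus attributes-free totals in \code{flagged_samples} and
#'   \code{n_removed_total}.
#' @export
screen_cohort <- function(calls, reference, vaf_cutoff = 0.10,
                          min_artifacts = 3, both_strands = TRUE) {
  if (nrow(calls) == 0) {
    return(list(calls = calls,
                report = data.frame(sample_id = character(),
                                    n_putative_artifacts = integer(),
                                    flagged = logical(),
                                    n_removed = integer()),
                flagged_samples = character(),
                n_removed_total = 0L))
  }
  pieces <- split(calls, calls$sample_id)
  screened <- lapply(pieces, screen_sample, reference = reference,
                     vaf_cutoff = vaf_cutoff, min_artifacts = min_artifacts,
                     both_strands = both_strands)
  out_calls <- do.call(rbind, c(lapply(screened, `[[`, "calls"),
                                list(make.row.names = FALSE)))
  report <- data.frame(
    sample_id = vapply(screened, function(s) s$report$sample_id, ""),
    n_putative_artifacts = vapply(screened, function(s)
      as.integer(s$report$n_putative_artifacts), 0L),
    flagged = vapply(screened, function(s) s$report$flagged, TRUE),
    n_removed = vapply(screened, function(s)
      length(s$report$removed_keys), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  list(calls = out_calls,
       report = report,
       flagged_samples = report$sample_id[report$flagged],
       n_removed_total = sum(report$n_removed))
}
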
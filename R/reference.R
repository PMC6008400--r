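# Panel reference sequences and variant-key normalization.
#
# The reference is held as a named character vector of contig sequences
# (class "panel_ref"); lookups are plain substring operations, which is fast
# enough for targeted panels and keeps the normalizer dependency-free.

#' Load panel reference sequences from FASTA
#'
#' @param path FASTA file of panel contigs.
#' @return A named character vector of uppercase sequences, one per contig,
#'   with class \code{"panel_ref"}.
#' @export
read_panel_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ref <- toupper(as.character(seqs))
  # keep only the first whitespace token of each FASTA header
  names(ref) <- sub("\\s.*$", "", names(ref))
  structure(ref, class = "panel_ref")
}

#' @rdname read_panel_fasta
#' @param sequences named character vector of contig sequences.
#' @export
panel_ref <- function(sequences) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  structure(toupper(sequences), class = "panel_ref")
}

# Substring of a contig; returns NA if out of bounds.
ref_seq <- function(reference, contig, start, end) {
  s <- reference[[contig]]
  if (is.null(s) || is.na(s)) stop("contig not in reference: ", contig)
  if (start < 1 || end > nchar(s)) return(NA_character_)
  substr(s, start, end)
}

#' Normalize a variant key (left-align and trim indels)
#'
#' Reduces each allele pair to its parsimonious, left-aligned representation
#' so that keys from different callers are comparable by equality: shared
#' trailing bases are trimmed (extending the alleles leftward with reference
#' bases when one allele would empty), then shared leading bases are trimmed.
#' SNVs pass through unchanged.  The transformation is idempotent.
#'
#' @param contig,pos,ref,alt scalar variant key fields (pos 1-based).
#' @param reference a \code{\link{panel_ref}} object covering the locus.
#' @return list with fields \code{contig}, \code{pos}, \code{ref}, \code{alt}.
#' @export
normalize_key <- function(contig, pos, ref, alt, reference) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
    stop("alleles must be non-empty A/C/G/T strings")
  if (ref == alt)
    stop("invalid key at ", contig, ":", pos, ": ref equals alt (", ref, ")")
  obs <- ref_seq(reference, contig, pos, pos + nchar(ref) - 1L)
  if (is.na(obs) || obs != ref)
    stop("ref allele disagrees with reference at ", contig, ":", pos,
         " (expected ", obs, ", got ", ref, ")")
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 && !(nr == 1 && na == 1) &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1, nr - 1L)
      alt <- substr(alt, 1, na - 1L)
      if (nchar(ref) == 0 || nchar(alt) == 0) {
        if (pos <= 1L)
          stop("cannot left-extend allele at start of contig ", contig)
        pos <- pos - 1L
        b <- ref_seq(reference, contig, pos, pos)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
      next
    }
    if (nchar(ref) > 1 && nchar(alt) > 1 &&
        substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref))
      alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1L
      next
    }
    break
  }
  list(contig = contig, pos = as.integer(pos), ref = ref, alt = alt)
}

#' Normalize every key in a call table
#'
#' @param calls call data.frame.
#' @param reference a \code{\link{panel_ref}}.
#' @return the call table with contig/pos/ref/alt replaced by their
#'   normalized forms.
#' @export
normalize_calls <- function(calls, reference) {
  if (nrow(calls) == 0) return(calls)
  for (i in seq_len(nrow(calls))) {
    k <- normalize_key(calls$contig[i], calls$pos[i],
                       calls$ref[i], calls$alt[i], reference)
    calls$pos[i] <- k$pos
    calls$ref[i] <- k$ref
    calls$alt[i] <- k$alt
  }
  calls
}

# Reverse complement without external deps (used by fixtures and annotation).
rev_comp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
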
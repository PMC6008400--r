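# BBD/IBC progression overlap: categorize every mutation observed in a
# matched benign-lesion / later-tumor pair using force-called read counts
# at the union of both call sets' sites.

OVERLAP_CATEGORIES <- c("bbd_only", "ibc_only", "candidate_shared",
                        "definitively_shared")

#' Categorize mutation sharing within one BBD/IBC pair
#'
#' Every key in the union of the two call sets is placed in exactly one
#' category from the force-called alt counts: \code{candidate_shared}
#' requires alt reads above zero in both samples; \code{definitively_shared}
#' additionally requires at least \code{min_support} alt reads in both
#' (default 3 — the direct negation of "two or fewer supporting reads in
#' one of the samples"); otherwise \code{bbd_only} / \code{ibc_only} by
#' which sample carries the alt reads.
#'
#' @param pair_id identifier for the pair.
#' @param bbd_calls,ibc_calls call tables from the two samples.
#' @param counts force-called counts at the union of sites: data.frame
#'   with key, bbd_depth, bbd_alt, ibc_depth, ibc_alt (as produced by
#'   \code{\link{generate_progression_pairs}}).
#' @param min_support minimum alt reads in both samples for a definitive
#'   share.
#' @return data.frame: pair_id, key, bbd_vaf, ibc_vaf, bbd_alt, ibc_alt,
#'   category.
#' @export
overlap_pair <- function(pair_id, bbd_calls, ibc_calls, counts,
                         min_support = 3) {
  union_keys <- unique(c(call_key(bbd_calls), call_key(ibc_calls)))
  if (length(union_keys) == 0) {
    return(data.frame(pair_id = character(), key = character(),
                      bbd_vaf = numeric(), ibc_vaf = numeric(),
                      bbd_alt = integer(), ibc_alt = integer(),
                      category = character(), stringsAsFactors = FALSE))
  }
  m <- match(union_keys, counts$key)
  if (anyNA(m))
    stop("missing force-called counts at site(s): ",
         paste(union_keys[is.na(m)], collapse = ", "))
  cc <- counts[m, , drop = FALSE]
  both <- cc$bbd_alt > 0 & cc$ibc_alt > 0
  definitive <- cc$bbd_alt >= min_support & cc$ibc_alt >= min_support
  category <- ifelse(both & definitive, "definitively_shared",
              ifelse(both, "candidate_shared",
              ifelse(cc$bbd_alt > 0, "bbd_only", "ibc_only")))
  data.frame(pair_id = pair_id, key = union_keys,
             bbd_vaf = ifelse(cc$bbd_depth > 0,
                              cc$bbd_alt / cc$bbd_depth, NA_real_),
             ibc_vaf = ifelse(cc$ibc_depth > 0,
                              cc$ibc_alt / cc$ibc_depth, NA_real_),
             bbd_alt = cc$bbd_alt, ibc_alt = cc$ibc_alt,
             category = category, stringsAsFactors = FALSE)
}

#' Summarize overlap records across pairs
#'
#' @param records row-bound output of \code{\link{overlap_pair}}.
#' @return list with \code{total} mutations, \code{by_category} counts
#'   (always covering all four categories), and \code{scatter}: the
#'   per-mutation VAF-vs-VAF table for plotting.
#' @export
overlap_report <- function(records) {
  by_cat <- setNames(integer(length(OVERLAP_CATEGORIES)),
                     OVERLAP_CATEGORIES)
  if (nrow(records) > 0) {
    tab <- table(factor(records$category, levels = OVERLAP_CATEGORIES))
    by_cat[names(tab)] <- as.integer(tab)
  }
  list(total = nrow(records), by_category = by_cat,
       scatter = records[, intersect(c("pair_id", "key", "bbd_vaf",
                                       "ibc_vaf", "category"),
                                     names(records)), drop = FALSE])
}

#' VAF-vs-VAF scatter of BBD/IBC overlap records
#'
#' Base-graphics scatter of the force-called VAFs, with shared mutations
#' highlighted.
#'
#' @param records overlap records.
#' @param ... passed to \code{plot}.
#' @export
plot_overlap <- function(records, ...) {
  shared <- records$category %in% c("candidate_shared",
                                    "definitively_shared")
  plot(records$bbd_vaf, records$ibc_vaf,
       xlab = "BBD VAF", ylab = "IBC VAF",
       pch = 19, col = ifelse(shared, "red", "grey40"),
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey70")
  invisible(records)
}
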
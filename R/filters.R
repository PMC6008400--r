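# Post-merge somatic filter cascade: coverage, panel-of-normals,
# population frequency, and the three-model binomial log-likelihood
# somatic classifier.  Applied in that order.

#' Coverage filter
#'
#' Keeps calls with at least \code{min_depth} reads in both the tumor and
#' the matched normal (boundary inclusive; default the study's 20x).  Both
#' samples are required because somatic status is undecidable without
#' adequate normal depth.
#'
#' @param calls call table.
#' @param min_depth minimum depth in each sample.
#' @return surviving calls, with filter history appended to every input row.
#' @export
coverage_filter <- function(calls, min_depth = 20) {
  keep <- calls$tumor_depth >= min_depth & calls$normal_depth >= min_depth
  calls <- append_filter_history(calls, "coverage", keep)
  calls[keep, , drop = FALSE]
}

#' Panel-of-normals filter
#'
#' Removes calls whose normalized key appears in a blacklist of variants
#' recurrently seen across a large panel of normal samples (systematic
#' artifacts; the study used 905 normal exomes).
#'
#' @param calls call table (keys normalized).
#' @param blacklist character vector of normalized keys
#'   (\code{"contig:pos:ref:alt"}), as from \code{\link{read_pon}}.
#' @param reference optional \code{\link{panel_ref}}; when supplied, the
#'   blacklist keys are checked to be normalized (unnormalized keys error).
#' @export
pon_filter <- function(calls, blacklist, reference = NULL) {
  if (!is.null(reference) && length(blacklist) > 0) {
    parts <- strsplit(blacklist, ":", fixed = TRUE)
    for (p in parts) {
      k <- normalize_key(p[1], as.integer(p[2]), p[3], p[4], reference)
      if (k$pos != as.integer(p[2]) || k$ref != p[3] || k$alt != p[4])
        stop("panel-of-normals key not normalized: ",
             paste(p, collapse = ":"))
    }
  }
  keep <- !(call_key(calls) %in% blacklist)
  calls <- append_filter_history(calls, "pon", keep)
  calls[keep, , drop = FALSE]
}

#' Population-frequency filter
#'
#' Removes calls whose population allele frequency exceeds \code{max_freq}
#' (strictly; the boundary value is kept, reading "exceeded 0.1%"
#' literally).  Keys absent from the frequency map are kept.
#'
#' @param calls call table.
#' @param freq_map data.frame with \code{key} and \code{frequency} columns,
#'   as from \code{\link{read_popfreq}}.
#' @param max_freq maximum tolerated population frequency (default 0.001).
#' @export
popfreq_filter <- function(calls, freq_map, max_freq = 0.001) {
  if (nrow(freq_map) > 0 &&
      any(freq_map$frequency < 0 | freq_map$frequency > 1))
    stop("population frequencies must be in [0, 1]")
  freq <- freq_map$frequency[match(call_key(calls), freq_map$key)]
  keep <- is.na(freq) | freq <= max_freq
  calls <- append_filter_history(calls, "popfreq", keep)
  calls[keep, , drop = FALSE]
}

#' Binomial log-likelihood somatic classifier
#'
#' Evaluates three generative models of the tumor/normal alt read counts
#' (natural-log binomial likelihoods summed over the two samples):
#' \describe{
#'   \item{reference_noise}{alt reads in both samples are sequencing error:
#'     \code{alt ~ Binomial(depth, e)} in tumor and normal.}
#'   \item{germline}{a heterozygous variant shared by both samples:
#'     \code{alt ~ Binomial(depth, 0.5)} in tumor and normal.}
#'   \item{somatic}{tumor alt reads at the maximum-likelihood VAF
#'     \code{tumor_alt/tumor_depth} (floored at the error rate, so zero
#'     alt evidence can never favour this model); normal alt reads are
#'     error.}
#' }
#' The class label is the argmax; \code{somatic_margin} is
#' \code{LL(somatic) - max(LL(reference_noise), LL(germline))}.
#'
#' @param tumor_depth,tumor_alt,normal_depth,normal_alt read counts
#'   (vectorized; depths must be positive).
#' @param error_rate assumed per-base error rate \code{e}, in (0, 0.5).
#' @return data.frame with columns \code{label}, \code{ll_reference_noise},
#'   \code{ll_germline}, \code{ll_somatic}, \code{somatic_margin}.
#' @export
classify_somatic <- function(tumor_depth, tumor_alt, normal_depth,
                             normal_alt, error_rate = 0.001) {
  if (any(tumor_depth <= 0) || any(normal_depth <= 0))
    stop("classifier requires positive depth in both samples")
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must be in (0, 0.5)")
  ll_ref <- dbinom(tumor_alt, tumor_depth, error_rate, log = TRUE) +
    dbinom(normal_alt, normal_depth, error_rate, log = TRUE)
  ll_germ <- dbinom(tumor_alt, tumor_depth, 0.5, log = TRUE) +
    dbinom(normal_alt, normal_depth, 0.5, log = TRUE)
  # ML estimate of the somatic VAF, floored at the error rate so that a
  # site with no alt evidence can never out-score the noise model
  vaf_hat <- pmax(tumor_alt / tumor_depth, error_rate)
  ll_som <- dbinom(tumor_alt, tumor_depth, vaf_hat, log = TRUE) +
    dbinom(normal_alt, normal_depth, error_rate, log = TRUE)
  lls <- cbind(reference_noise = ll_ref, germline = ll_germ,
               somatic = ll_som)
  # deterministic tie-break: prefer the least remarkable explanation
  order_pref <- c("reference_noise", "germline", "somatic")
  label <- vapply(seq_len(nrow(lls)), function(i) {
    best <- max(lls[i, ])
    order_pref[order_pref %in% colnames(lls)[lls[i, ] == best]][1]
  }, character(1))
  data.frame(label = label,
             ll_reference_noise = ll_ref,
             ll_germline = ll_germ,
             ll_somatic = ll_som,
             somatic_margin = ll_som - pmax(ll_ref, ll_germ),
             stringsAsFactors = FALSE)
}

#' Somatic classifier filter
#'
#' Keeps calls the classifier labels \code{somatic} with a log-likelihood
#' margin of at least \code{threshold} (default 5, natural-log units).
#'
#' @param calls call table with positive depths in both samples.
#' @param error_rate classifier error rate.
#' @param threshold minimum somatic margin (boundary inclusive).
#' @export
somatic_filter <- function(calls, error_rate = 0.001, threshold = 5) {
  if (nrow(calls) == 0) {
    return(append_filter_history(calls, "somatic_classifier", logical(0)))
  }
  cl <- classify_somatic(calls$tumor_depth, calls$tumor_alt,
                         calls$normal_depth, calls$normal_alt, error_rate)
  keep <- cl$label == "somatic" & cl$somatic_margin >= threshold
  calls <- append_filter_history(calls, "somatic_classifier", keep)
  calls[keep, , drop = FALSE]
}

#' Run the full post-merge filter cascade
#'
#' Applies, in the study's stated order: coverage (20x in tumor and
#' normal), panel-of-normals removal, population-frequency removal (0.1%),
#' then the binomial log-likelihood somatic classifier (margin >= 5).
#'
#' @param calls merged call table for any number of samples.
#' @param pon blacklist key vector (may be empty).
#' @param popfreq frequency map data.frame (may be empty).
#' @param min_depth,max_freq,error_rate,threshold stage parameters.
#' @return list with \code{calls} (survivors) and \code{attrition}
#'   (data.frame of input/output counts per stage).
#' @export
run_filter_cascade <- function(calls, pon = character(),
                               popfreq = data.frame(key = character(),
                                                    frequency = numeric()),
                               min_depth = 20, max_freq = 0.001,
                               error_rate = 0.001, threshold = 5) {
  stages <- list(
    coverage = function(x) coverage_filter(x, min_depth),
    pon = function(x) pon_filter(x, pon),
    popfreq = function(x) popfreq_filter(x, popfreq, max_freq),
    somatic_classifier = function(x) somatic_filter(x, error_rate,
                                                    threshold)
  )
  attrition <- data.frame(stage = names(stages), n_in = NA_integer_,
                          n_out = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(stages)) {
    attrition$n_in[i] <- nrow(calls)
    calls <- stages[[i]](calls)
    attrition$n_out[i] <- nrow(calls)
  }
  list(calls = calls, attrition = attrition)
}
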
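# Matched case-control statistics: paired burden tests, per-gene tests
# with Benjamini-Hochberg correction, exclusivity and hotspot contrasts,
# and a paired-swap permutation gene-set enrichment test.

#' Build a per-pair mutation burden table
#'
#' Counts mutations per subject within the requested stratum and arranges
#' them by matched pair.  Strata: \code{all} (every surviving call,
#' including silent and noncoding), \code{non_silent} (protein-altering
#' effects only), \code{founding_clone} (VAF strictly above
#' \code{founding_clone_vaf}, default the study's 25%), \code{per_gene}
#' (one count column pair per panel gene).
#'
#' @param calls annotated call table.
#' @param manifest pair manifest (see \code{\link{read_pair_manifest}}).
#' @param stratum one of \code{all}, \code{non_silent},
#'   \code{founding_clone}, \code{per_gene}.
#' @param founding_clone_vaf strict VAF lower bound for the founding-clone
#'   stratum.
#' @param genes gene universe for \code{per_gene} (default: genes observed).
#' @return For scalar strata, a data.frame (pair_id, case_count,
#'   control_count); for \code{per_gene}, a list of such data.frames, one
#'   per gene.
#' @export
build_burden_table <- function(calls, manifest,
                               stratum = c("all", "non_silent",
                                           "founding_clone", "per_gene"),
                               founding_clone_vaf = 0.25, genes = NULL) {
  stratum <- match.arg(stratum)
  validate_manifest(manifest)
  known <- c(manifest$case_sample_id, manifest$control_sample_id)
  stray <- setdiff(unique(calls$sample_id), known)
  if (length(stray) > 0)
    stop("sample(s) in calls but not in manifest: ",
         paste(stray, collapse = ", "))
  subset_calls <- switch(stratum,
    all = calls,
    non_silent = calls[is_non_silent(calls$effect), , drop = FALSE],
    founding_clone = calls[!is.na(calls$vaf) &
                             calls$vaf > founding_clone_vaf, ,
                           drop = FALSE],
    per_gene = calls)
  count_for <- function(x) {
    tab <- table(x$sample_id)
    case_count <- as.integer(tab[manifest$case_sample_id])
    control_count <- as.integer(tab[manifest$control_sample_id])
    data.frame(pair_id = manifest$pair_id,
               case_count = ifelse(is.na(case_count), 0L, case_count),
               control_count = ifelse(is.na(control_count), 0L,
                                      control_count),
               stringsAsFactors = FALSE)
  }
  if (stratum != "per_gene") return(count_for(subset_calls))
  if (is.null(genes)) genes <- sort(unique(subset_calls$gene))
  genes <- genes[!is.na(genes)]
  setNames(lapply(genes, function(g) {
    count_for(subset_calls[!is.na(subset_calls$gene) &
                             subset_calls$gene == g, , drop = FALSE])
  }), genes)
}

#' Paired t-test on matched case/control counts
#'
#' Tests the mean of the within-pair differences \code{d_i = case_i -
#' control_i}: \code{t = mean(d) / (sd(d) / sqrt(n))} with \code{n - 1}
#' degrees of freedom, two-sided.  Degenerate cases follow explicit
#' conventions: all-zero differences give \code{t = 0, p = 1}; a constant
#' non-zero difference (sd = 0) gives \code{p = 0} with a warning.
#'
#' @param case_vec,control_vec equal-length numeric vectors, paired by
#'   index, \code{n >= 2}.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
paired_t_test <- function(case_vec, control_vec) {
  if (length(case_vec) != length(control_vec))
    stop("case and control vectors must have equal length")
  n <- length(case_vec)
  if (n < 2) stop("paired t-test requires at least 2 pairs")
  d <- case_vec - control_vec
  s <- sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1L, p = 1))
    warning("constant non-zero paired difference; reporting p = 0")
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, df = n - 1L,
       p = 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over \code{p.adjust(method = "BH")}, exposed so the
#' adjustment applied across per-gene tests can be reused and checked
#' directly.  With 83 tests, a raw p of 0.0302 among otherwise null
#' p-values adjusts to 1 (0.0302 x 83 > 1).
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Per-gene paired tests with Benjamini-Hochberg adjustment
#'
#' Runs one paired t-test per gene on per-subject mutation counts and
#' adjusts the raw p-values by Benjamini-Hochberg across all tested genes.
#' Genes with zero mutations in both arms are reported untested (NA
#' statistics) and excluded from the adjustment family.
#'
#' @param gene_tables named list of per-gene burden tables, as from
#'   \code{build_burden_table(..., stratum = "per_gene")}.
#' @return data.frame: gene, t, df, p, fdr, n_cases_mutated,
#'   n_controls_mutated, ordered by raw p.
#' @export
per_gene_tests <- function(gene_tables) {
  rows <- lapply(names(gene_tables), function(g) {
    b <- gene_tables[[g]]
    n_cases <- sum(b$case_count > 0)
    n_controls <- sum(b$control_count > 0)
    if (n_cases == 0 && n_controls == 0) {
      return(data.frame(gene = g, t = NA_real_, df = NA_integer_,
                        p = NA_real_, n_cases_mutated = 0L,
                        n_controls_mutated = 0L, stringsAsFactors = FALSE))
    }
    tt <- suppressWarnings(paired_t_test(b$case_count, b$control_count))
    data.frame(gene = g, t = tt$t, df = tt$df, p = tt$p,
               n_cases_mutated = n_cases, n_controls_mutated = n_controls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  tested <- !is.na(out$p)
  out$fdr[tested] <- bh_adjust(out$p[tested])
  out <- out[order(out$p, out$gene, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("gene", "t", "df", "p", "fdr", "n_cases_mutated",
          "n_controls_mutated")]
}

#' Genes mutated exclusively in one arm
#'
#' @param gene_tables named list of per-gene burden tables.
#' @return list with \code{case_exclusive} and \code{control_exclusive}
#'   data.frames (gene, n_mutated).
#' @export
exclusivity_summary <- function(gene_tables) {
  rows <- lapply(names(gene_tables), function(g) {
    b <- gene_tables[[g]]
    data.frame(gene = g, n_cases = sum(b$case_count > 0),
               n_controls = sum(b$control_count > 0),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(
    case_exclusive = setNames(
      tab[tab$n_cases > 0 & tab$n_controls == 0, c("gene", "n_cases")],
      c("gene", "n_mutated")),
    control_exclusive = setNames(
      tab[tab$n_controls > 0 & tab$n_cases == 0, c("gene", "n_controls")],
      c("gene", "n_mutated")))
}

#' Hotspot-vs-elsewhere contrast within a gene
#'
#' Builds the 2x2 table (case/control x at-residue/elsewhere) over a
#' gene's annotated mutations and applies a two-sided Fisher exact test
#' (e.g. hotspot codon 1047 of PIK3CA against all other PIK3CA mutations).
#'
#' @param calls annotated call table.
#' @param manifest pair manifest.
#' @param gene gene symbol.
#' @param residue 1-based amino-acid hotspot position.
#' @return list with \code{table} (2x2 matrix) and \code{p}.
#' @export
hotspot_contrast <- function(calls, manifest, gene, residue) {
  g <- calls[!is.na(calls$gene) & calls$gene == gene, , drop = FALSE]
  if (nrow(g) == 0) stop("no mutations in gene ", gene)
  is_case <- g$sample_id %in% manifest$case_sample_id
  at_res <- !is.na(g$residue) & g$residue == residue
  tab <- matrix(c(sum(is_case & at_res), sum(is_case & !at_res),
                  sum(!is_case & at_res), sum(!is_case & !at_res)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("at_residue", "elsewhere")))
  list(table = tab, p = fisher.test(tab)$p.value)
}

#' Paired-swap permutation gene-set enrichment test
#'
#' For each gene set, the statistic is the mean within-pair difference of
#' per-subject mutation counts summed over the set's genes.  The null is
#' generated by independently swapping case/control labels within each
#' pair.  When every swap assignment can be enumerated
#' (\code{2^n_pairs <= n_permutations}) the null is exhaustive and
#' \code{p = #\{|null| >= |observed|\} / 2^n} (the identity assignment is
#' included, so p is never zero); otherwise \code{n_permutations} random
#' assignments are drawn and the add-one estimator
#' \code{p = (1 + #\{|null| >= |obs|\}) / (1 + n_permutations)} is used.
#'
#' @param gene_tables named list of per-gene burden tables.
#' @param gene_sets named list of gene symbol vectors (from
#'   \code{\link{read_gmt}}).
#' @param n_permutations random permutations when not exhaustive.
#' @param seed integer seed for the random draws.
#' @return data.frame: set, n_genes, statistic, p, exhaustive.
#' @export
geneset_enrichment <- function(gene_tables, gene_sets,
                               n_permutations = 10000, seed = 1) {
  all_genes <- names(gene_tables)
  rows <- list()
  for (set_name in names(gene_sets)) {
    genes <- intersect(gene_sets[[set_name]], all_genes)
    if (length(genes) == 0) {
      warning("gene set ", set_name, " has no panel genes; skipped")
      next
    }
    case_mat <- sapply(genes, function(g) gene_tables[[g]]$case_count)
    ctrl_mat <- sapply(genes, function(g) gene_tables[[g]]$control_count)
    case_tot <- if (is.matrix(case_mat)) rowSums(case_mat) else
      sum(case_mat)
    ctrl_tot <- if (is.matrix(ctrl_mat)) rowSums(ctrl_mat) else
      sum(ctrl_mat)
    d <- case_tot - ctrl_tot
    n <- length(d)
    obs <- mean(d)
    exhaustive <- 2^n <= n_permutations
    if (exhaustive) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      null_stats <- as.numeric(signs %*% d) / n
      p <- sum(abs(null_stats) >= abs(obs) - 1e-12) / nrow(signs)
    } else {
      # signs are symmetric iid, so the null may be drawn against the
      # sorted |d|; this makes the Monte Carlo p invariant to pair order
      da <- sort(abs(d))
      null_stats <- with_substream(seed, paste0("geneset:", set_name), {
        vapply(seq_len(n_permutations), function(i) {
          mean(da * sample(c(1, -1), n, replace = TRUE))
        }, numeric(1))
      })
      p <- (1 + sum(abs(null_stats) >= abs(obs) - 1e-12)) /
        (1 + n_permutations)
    }
    rows[[set_name]] <- data.frame(set = set_name,
                                   n_genes = length(genes),
                                   statistic = obs, p = p,
                                   exhaustive = exhaustive,
                                   stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(set = character(), n_genes = integer(),
                      statistic = numeric(), p = numeric(),
                      exhaustive = logical())
  out
}
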
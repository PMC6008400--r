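# Synthetic matched-cohort simulator with full ground truth.
#
# Emulates what the pipeline consumes from a targeted FFPE tumor/normal
# panel study: per-sample per-caller VCFs, a read-count sidecar, the panel
# (BED/FASTA/CDS), a panel-of-normals blacklist, a population allele
# frequency table, gene sets and a pair manifest.  Every emitted call is
# traceable to exactly one truth record.

# ---- deterministic substreams -------------------------------------------

# One global seed drives named substreams (one per sample/stage) so adding
# samples never perturbs draws for earlier samples.
substream_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 1103) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

# ---- configuration -------------------------------------------------------

#' Simulation configuration
#'
#' Defaults mirror the study this package models: 218 matched case/control
#' pairs (436 BBD samples), an 83-gene targeted panel, mean variant coverage
#' 90.4x, an expected 2.3 true somatic mutations per sample, base error rate
#' 0.001, and FFPE deamination artifacts concentrated in a small fraction of
#' samples (about 4% of samples affected, about 4.7 artifacts each).
#' \code{case_effect} multiplies the somatic rate in case samples (1 = null,
#' matching the study's finding of no burden difference).
#'
#' @param n_pairs matched pairs to simulate.
#' @param n_genes,exons_per_gene,exon_length,intron_length,flank panel
#'   geometry (bp); BED intervals are exons padded by \code{flank}.
#' @param mean_depth,depth_dispersion negative-binomial read-depth model
#'   (FFPE depth is overdispersed; dispersion is the NB size parameter).
#' @param error_rate per-base sequencing error rate.
#' @param somatic_rate expected true somatic mutations per sample.
#' @param somatic_vaf_shape1,somatic_vaf_shape2 Beta parameters of the
#'   somatic VAF distribution.
#' @param indel_fraction fraction of somatic mutations that are indels.
#' @param germline_rate expected heterozygous germline variants per sample
#'   (drawn from a shared population site pool; sampled at VAF 0.5).
#' @param n_pop_sites,popfreq_common_fraction population site pool size and
#'   the fraction of pool sites with frequency above 0.1%.
#' @param germline_leak probability that a somatic caller leaks a germline
#'   variant into its call set (scaled by the caller's sensitivity).
#' @param ffpe_sample_fraction fraction of samples receiving FFPE artifacts.
#' @param ffpe_artifact_rate expected artifacts per affected sample.
#' @param artifact_vaf_shape1,artifact_vaf_shape2 Beta parameters for
#'   artifact VAFs (draws are rejected until below 0.10).
#' @param pon_sites,pon_rate panel-of-normals pool size and expected
#'   blacklisted artifact calls per sample.
#' @param caller_sensitivity named per-caller detection probabilities.
#' @param false_call_rate expected spurious calls per caller per sample.
#' @param false_call_vaf underlying alt-read fraction at spurious-call
#'   sites (error-level: these calls have no real variant beneath them).
#' @param vaf_logistic_sensitivity if TRUE, sensitivity is scaled by a
#'   logistic curve in VAF (midpoint \code{vaf50}, slope \code{vaf_slope}).
#' @param vaf50,vaf_slope logistic sensitivity parameters.
#' @param case_effect multiplicative shift of the somatic rate in cases.
#' @param exclusive_gene optional list(gene=, n_cases=): a gene mutated only
#'   in that many case samples (injected signal for recovery tests).
#' @param seed global integer seed.
#' @return a validated \code{simulation_config} list.
#' @export
simulation_config <- function(n_pairs = 218,
                              n_genes = 83,
                              exons_per_gene = 4,
                              exon_length = 150,
                              intron_length = 90,
                              flank = 10,
                              mean_depth = 90.4,
                              depth_dispersion = 8,
                              error_rate = 0.001,
                              somatic_rate = 2.3,
                              somatic_vaf_shape1 = 2,
                              somatic_vaf_shape2 = 6,
                              indel_fraction = 0.1,
                              germline_rate = 3,
                              n_pop_sites = 200,
                              popfreq_common_fraction = 0.8,
                              germline_leak = 0.3,
                              ffpe_sample_fraction = 18 / 436,
                              ffpe_artifact_rate = 84 / 18,
                              artifact_vaf_shape1 = 2,
                              artifact_vaf_shape2 = 40,
                              pon_sites = 30,
                              pon_rate = 0.3,
                              caller_sensitivity = c(samtools = 0.95,
                                                     sniper = 0.93,
                                                     varscan = 0.90,
                                                     strelka = 0.92,
                                                     mutect = 0.95,
                                                     gatk = 0.90),
                              false_call_rate = 0.5,
                              false_call_vaf = 0.002,
                              vaf_logistic_sensitivity = FALSE,
                              vaf50 = 0.05,
                              vaf_slope = 60,
                              case_effect = 1.0,
                              exclusive_gene = NULL,
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_pairs >= 1, cfg$n_genes >= 1, cfg$exons_per_gene >= 1)
  if (cfg$exon_length < 3) stop("config error: exon length < 3")
  if (cfg$intron_length < 2 * cfg$flank + 1)
    stop("config error: introns must exceed twice the flank")
  rates <- c(cfg$error_rate, cfg$indel_fraction, cfg$ffpe_sample_fraction,
             cfg$popfreq_common_fraction, cfg$germline_leak,
             cfg$false_call_vaf, cfg$caller_sensitivity)
  if (any(rates < 0 | rates > 1)) stop("config error: rate outside [0, 1]")
  check_caller_labels(names(cfg$caller_sensitivity))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "simulation_config")
}

# ---- panel generation ----------------------------------------------------

#' Generate a synthetic targeted gene panel
#'
#' Builds one contig per gene: exons of near-equal length separated by
#' introns, padded ends, random sequence.  CDS total length is forced to a
#' multiple of 3 by trimming the last exon.  Strand alternates so both
#' orientations are exercised.  Gene symbols are taken from the packaged
#' 83-gene panel list while available, synthetic symbols beyond.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param seed optional override of \code{config$seed}.
#' @return a \code{gene_panel} (as from \code{\link{read_panel}}).
#' @export
generate_panel <- function(config, seed = config$seed) {
  symbols <- panel_gene_symbols()
  n <- config$n_genes
  if (n <= length(symbols)) {
    symbols <- symbols[seq_len(n)]
  } else {
    symbols <- c(symbols, sprintf("SYNGENE%03d", seq_len(n - length(symbols))))
  }
  pad <- 50L
  genes <- list()
  sequences <- character()
  for (gi in seq_along(symbols)) {
    sym <- symbols[gi]
    exon_lens <- rep(config$exon_length, config$exons_per_gene)
    excess <- sum(exon_lens) %% 3L
    exon_lens[length(exon_lens)] <- exon_lens[length(exon_lens)] - excess
    strand <- if (gi %% 2 == 0) "-" else "+"
    contig_len <- pad + sum(exon_lens) +
      (config$exons_per_gene - 1L) * config$intron_length + pad
    seq_chars <- with_substream(seed, paste0("panel:", sym), {
      sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
    })
    sequences[[sym]] <- paste(seq_chars, collapse = "")
    starts <- pad + 1L +
      cumsum(c(0L, head(exon_lens, -1) + config$intron_length))
    ends <- starts + exon_lens - 1L
    cds <- data.frame(contig = sym, start = starts, end = ends,
                      strand = strand, stringsAsFactors = FALSE)
    # coding order: left-to-right on +, right-to-left on -
    cds <- if (strand == "+") cds else cds[rev(seq_len(nrow(cds))), ]
    cds$exon_index <- seq_len(nrow(cds))
    intervals <- data.frame(contig = sym,
                            start = pmax(1L, starts - config$flank),
                            end = pmin(contig_len, ends + config$flank),
                            stringsAsFactors = FALSE)
    genes[[sym]] <- list(symbol = sym, intervals = intervals,
                         cds = cds[, c("contig", "start", "end", "strand",
                                       "exon_index")])
  }
  structure(list(genes = genes, reference = panel_ref(unlist(sequences))),
            class = "gene_panel")
}

#' Write panel files (FASTA, BED, CDS model)
#'
#' @param panel a \code{gene_panel}.
#' @param dir output directory.
#' @return named list of the three file paths.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "panel.fa")
  seqs <- Biostrings::DNAStringSet(unclass(panel$reference))
  Biostrings::writeXStringSet(seqs, fasta, width = 70L)
  bed <- file.path(dir, "panel.bed")
  bed_df <- do.call(rbind, lapply(panel$genes, function(g) {
    data.frame(contig = g$intervals$contig, start = g$intervals$start - 1L,
               end = g$intervals$end, gene = g$symbol,
               stringsAsFactors = FALSE)
  }))
  write.table(bed_df, bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cds <- file.path(dir, "panel_cds.tsv")
  cds_df <- do.call(rbind, lapply(panel$genes, function(g) {
    cbind(gene = g$symbol, g$cds)
  }))
  write.table(cds_df, cds, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, bed = bed, cds = cds)
}

# ---- panel position indexes ---------------------------------------------

# All in-panel positions, with gene labels, as parallel vectors.
panel_positions <- function(panel) {
  pieces <- lapply(panel$genes, function(g) {
    pos <- unlist(mapply(seq, g$intervals$start, g$intervals$end,
                         SIMPLIFY = FALSE))
    list(contig = rep(g$intervals$contig[1], length(pos)), pos = pos,
         gene = rep(g$symbol, length(pos)))
  })
  list(contig = unlist(lapply(pieces, `[[`, "contig"), use.names = FALSE),
       pos = unlist(lapply(pieces, `[[`, "pos"), use.names = FALSE),
       gene = unlist(lapply(pieces, `[[`, "gene"), use.names = FALSE))
}

# In-panel positions compatible with the CG>TG deamination motif:
# C followed by G (C>T on the forward strand) and G preceded by C
# (the reverse-strand image, G>A).
ffpe_compatible_positions <- function(panel) {
  ref <- unclass(panel$reference)
  idx <- panel_positions(panel)
  out <- list(contig = character(), pos = integer(), ref = character(),
              alt = character())
  for (contig in names(ref)) {
    s <- ref[[contig]]
    cg <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (cg[1] == -1) next
    sel <- idx$pos[idx$contig == contig]
    c_pos <- intersect(as.integer(cg), sel)           # C of CG: C>T
    g_pos <- intersect(as.integer(cg) + 1L, sel)      # G of CG: G>A
    out$contig <- c(out$contig, rep(contig, length(c_pos) + length(g_pos)))
    out$pos <- c(out$pos, c_pos, g_pos)
    out$ref <- c(out$ref, rep("C", length(c_pos)), rep("G", length(g_pos)))
    out$alt <- c(out$alt, rep("T", length(c_pos)), rep("A", length(g_pos)))
  }
  out
}

# ---- low-level draws -----------------------------------------------------

draw_depth <- function(n, config) {
  pmax(1L, rnbinom(n, size = config$depth_dispersion,
                   mu = config$mean_depth))
}

draw_artifact_vaf <- function(n, config) {
  v <- numeric(0)
  while (length(v) < n) {
    cand <- rbeta(n, config$artifact_vaf_shape1, config$artifact_vaf_shape2)
    v <- c(v, cand[cand < 0.10])
  }
  v[seq_len(n)]
}

caller_detect_prob <- function(caller, vaf, config) {
  s <- config$caller_sensitivity[[caller]]
  if (isTRUE(config$vaf_logistic_sensitivity)) {
    s <- s / (1 + exp(-config$vaf_slope * (vaf - config$vaf50)))
  }
  s
}

# Draw a random SNV alt allele different from ref.
random_alt <- function(ref_base) {
  vapply(ref_base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1), USE.NAMES = FALSE)
}

# ---- cohort-level shared resources --------------------------------------

# Pool of population (germline) sites with allele frequencies.
make_population_pool <- function(panel, config) {
  idx <- panel_positions(panel)
  with_substream(config$seed, "population_pool", {
    n <- min(config$n_pop_sites, length(idx$pos))
    pick <- sample(length(idx$pos), n)
    ref <- vapply(seq_len(n), function(i) {
      ref_seq(panel$reference, idx$contig[pick[i]], idx$pos[pick[i]],
              idx$pos[pick[i]])
    }, character(1))
    alt <- random_alt(ref)
    common <- runif(n) < config$popfreq_common_fraction
    freq <- ifelse(common, runif(n, 0.002, 0.5), runif(n, 0, 0.001))
    data.frame(contig = idx$contig[pick], pos = idx$pos[pick],
               ref = ref, alt = alt, frequency = freq, gene = idx$gene[pick],
               stringsAsFactors = FALSE)
  })
}

# Pool of recurrent artifact sites forming the panel-of-normals blacklist.
make_pon_pool <- function(panel, config) {
  idx <- panel_positions(panel)
  with_substream(config$seed, "pon_pool", {
    n <- min(config$pon_sites, length(idx$pos))
    pick <- sample(length(idx$pos), n)
    ref <- vapply(seq_len(n), function(i) {
      ref_seq(panel$reference, idx$contig[pick[i]], idx$pos[pick[i]],
              idx$pos[pick[i]])
    }, character(1))
    data.frame(contig = idx$contig[pick], pos = idx$pos[pick],
               ref = ref, alt = random_alt(ref), gene = idx$gene[pick],
               stringsAsFactors = FALSE)
  })
}

# Simple gene-set definitions over the panel: consecutive chunks of 10.
make_gene_sets <- function(panel) {
  syms <- vapply(panel$genes, `[[`, "", "symbol", USE.NAMES = FALSE)
  chunks <- split(syms, ceiling(seq_along(syms) / 10))
  setNames(chunks, sprintf("SET%02d", seq_along(chunks)))
}

# ---- per-sample truth generation ----------------------------------------

# Draw one somatic variant (SNV or indel) at a uniform panel position.
draw_somatic_site <- function(panel, idx, config) {
  i <- sample(length(idx$pos), 1)
  contig <- idx$contig[i]; pos <- idx$pos[i]; gene <- idx$gene[i]
  ref_base <- ref_seq(panel$reference, contig, pos, pos)
  if (runif(1) >= config$indel_fraction) {
    list(contig = contig, pos = pos, ref = ref_base,
         alt = random_alt(ref_base), gene = gene)
  } else {
    len <- sample(1:3, 1)
    if (runif(1) < 0.5) {  # insertion after pos
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      list(contig = contig, pos = pos, ref = ref_base,
           alt = paste0(ref_base, ins), gene = gene)
    } else {               # deletion of the next len bases
      del_end <- pos + len
      ref_all <- ref_seq(panel$reference, contig, pos, del_end)
      if (is.na(ref_all)) {  # contig edge: fall back to SNV
        return(list(contig = contig, pos = pos, ref = ref_base,
                    alt = random_alt(ref_base), gene = gene))
      }
      list(contig = contig, pos = pos, ref = ref_all, alt = ref_base,
           gene = gene)
    }
  }
}

# Truth records for one sample: somatic, germline, FFPE, PoN origins.
sample_truth <- function(sample_id, is_case, panel, idx, ffpe_idx,
                         pop_pool, pon_pool, config, ffpe_affected,
                         extra_somatic = NULL, idx_somatic = idx) {
  rate <- config$somatic_rate * if (is_case) config$case_effect else 1
  rows <- list()
  add <- function(contig, pos, ref, alt, origin, vaf, gene) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = sample_id, contig = contig, pos = as.integer(pos),
      ref = ref, alt = alt, origin = origin, true_vaf = vaf, gene = gene,
      stringsAsFactors = FALSE)
  }
  n_som <- rpois(1, rate)
  for (k in seq_len(n_som)) {
    s <- draw_somatic_site(panel, idx_somatic, config)
    vaf <- rbeta(1, config$somatic_vaf_shape1, config$somatic_vaf_shape2)
    add(s$contig, s$pos, s$ref, s$alt, "somatic", vaf, s$gene)
  }
  if (!is.null(extra_somatic)) {
    for (k in seq_len(nrow(extra_somatic))) {
      add(extra_somatic$contig[k], extra_somatic$pos[k],
          extra_somatic$ref[k], extra_somatic$alt[k], "somatic",
          rbeta(1, config$somatic_vaf_shape1, config$somatic_vaf_shape2),
          extra_somatic$gene[k])
    }
  }
  n_germ <- min(rpois(1, config$germline_rate), nrow(pop_pool))
  if (n_germ > 0) {
    g <- pop_pool[sample(nrow(pop_pool), n_germ), , drop = FALSE]
    for (k in seq_len(nrow(g)))
      add(g$contig[k], g$pos[k], g$ref[k], g$alt[k], "germline", 0.5,
          g$gene[k])
  }
  if (ffpe_affected) {
    if (length(ffpe_idx$pos) == 0)
      stop("simulation error: no CG dinucleotides in panel for FFPE ",
           "artifact placement")
    n_art <- rpois(1, config$ffpe_artifact_rate)
    if (n_art > 0) {
      pick <- sample(length(ffpe_idx$pos), min(n_art, length(ffpe_idx$pos)))
      vafs <- draw_artifact_vaf(length(pick), config)
      gmap <- idx$gene[match(paste(ffpe_idx$contig[pick],
                                   ffpe_idx$pos[pick]),
                             paste(idx$contig, idx$pos))]
      for (k in seq_along(pick))
        add(ffpe_idx$contig[pick[k]], ffpe_idx$pos[pick[k]],
            ffpe_idx$ref[pick[k]], ffpe_idx$alt[pick[k]], "ffpe_artifact",
            vafs[k], gmap[k])
    }
  }
  n_pon <- min(rpois(1, config$pon_rate), nrow(pon_pool))
  if (n_pon > 0) {
    p <- pon_pool[sample(nrow(pon_pool), n_pon), , drop = FALSE]
    for (k in seq_len(nrow(p)))
      add(p$contig[k], p$pos[k], p$ref[k], p$alt[k], "pon_artifact",
          rbeta(1, 2, 20), p$gene[k])
  }
  out <- if (length(rows) == 0) {
    data.frame(sample_id = character(), contig = character(),
               pos = integer(), ref = character(), alt = character(),
               origin = character(), true_vaf = numeric(),
               gene = character(), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  # one origin per site: keep the first draw at any duplicated key
  out[!duplicated(paste(out$contig, out$pos, out$ref, out$alt)), ,
      drop = FALSE]
}

# Read counts + per-caller detection for one sample's truth records.
sample_observations <- function(truth, panel, idx, config) {
  n <- nrow(truth)
  t_dp <- draw_depth(n, config)
  n_dp <- draw_depth(n, config)
  germ <- truth$origin == "germline"
  t_alt <- rbinom(n, t_dp, truth$true_vaf)
  n_alt <- ifelse(germ, rbinom(n, n_dp, 0.5), rbinom(n, n_dp,
                                                     config$error_rate))
  rc <- data.frame(sample_id = truth$sample_id, contig = truth$contig,
                   pos = truth$pos, ref = truth$ref, alt = truth$alt,
                   tumor_depth = t_dp, tumor_alt = t_alt,
                   normal_depth = n_dp, normal_alt = n_alt,
                   stringsAsFactors = FALSE)
  snv <- nchar(truth$ref) == 1 & nchar(truth$alt) == 1
  calls <- list()
  for (caller in names(config$caller_sensitivity)) {
    eligible <- if (caller %in% SNV_CALLERS) snv else !snv
    if (caller %in% SNV_CALLERS && caller %in% INDEL_CALLERS)
      eligible <- rep(TRUE, n)
    # varscan/strelka call both classes
    p <- vapply(seq_len(n), function(i) {
      caller_detect_prob(caller, truth$true_vaf[i], config)
    }, numeric(1))
    p[germ] <- p[germ] * config$germline_leak
    hit <- eligible & t_alt > 0 & runif(n) < p
    # spurious caller-specific calls at novel sites
    n_false <- rpois(1, config$false_call_rate)
    false_rows <- NULL
    if (n_false > 0) {
      fi <- sample(length(idx$pos), n_false)
      f_ref <- vapply(seq_len(n_false), function(k) {
        ref_seq(panel$reference, idx$contig[fi[k]], idx$pos[fi[k]],
                idx$pos[fi[k]])
      }, character(1))
      f_dp <- draw_depth(n_false, config)
      f_alt <- rbinom(n_false, f_dp, config$false_call_vaf)
      f_ndp <- draw_depth(n_false, config)
      false_rows <- data.frame(
        contig = idx$contig[fi], pos = idx$pos[fi], ref = f_ref,
        alt = random_alt(f_ref), tumor_depth = f_dp, tumor_alt = f_alt,
        normal_depth = f_ndp,
        normal_alt = rbinom(n_false, f_ndp, config$error_rate),
        gene = idx$gene[fi], stringsAsFactors = FALSE)
      if (!caller %in% SNV_CALLERS) {
        # indel callers emit spurious single-base insertions
        false_rows$alt <- paste0(false_rows$ref, false_rows$alt)
      }
    }
    calls[[caller]] <- list(hit = which(hit), false_rows = false_rows)
  }
  list(readcounts = rc, detection = calls)
}

# ---- cohort generation ---------------------------------------------------

#' Generate a synthetic matched case/control cohort
#'
#' Produces, in memory, everything the downstream pipeline consumes: the
#' panel, per-sample per-caller call tables, a read-count sidecar covering
#' every emitted call, a pair manifest, the panel-of-normals blacklist, a
#' population frequency table, gene sets, and a truth table in which every
#' alt-supported site has exactly one origin (somatic, germline,
#' ffpe_artifact, pon_artifact or sequencing_error).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{synthetic_cohort} list; see \code{\link{write_cohort}}
#'   to materialize it as files.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- generate_panel(config)
  idx <- panel_positions(panel)
  ffpe_idx <- ffpe_compatible_positions(panel)
  pop_pool <- make_population_pool(panel, config)
  pon_pool <- make_pon_pool(panel, config)
  gene_sets <- make_gene_sets(panel)

  manifest <- data.frame(
    pair_id = sprintf("P%03d", seq_len(config$n_pairs)),
    case_sample_id = sprintf("P%03d_case", seq_len(config$n_pairs)),
    control_sample_id = sprintf("P%03d_ctrl", seq_len(config$n_pairs)),
    pair_kind = "case_control", stringsAsFactors = FALSE)

  samples <- data.frame(
    sample_id = c(rbind(manifest$case_sample_id,
                        manifest$control_sample_id)),
    is_case = rep(c(TRUE, FALSE), config$n_pairs),
    stringsAsFactors = FALSE)

  # which samples receive FFPE artifacts, and exclusive-gene injections
  ffpe_affected <- with_substream(config$seed, "ffpe_samples", {
    runif(nrow(samples)) < config$ffpe_sample_fraction
  })
  # background somatic placement avoids the exclusive gene so that gene is
  # mutated only via the injected case calls
  idx_somatic <- idx
  if (!is.null(config$exclusive_gene)) {
    keep <- idx$gene != config$exclusive_gene$gene
    idx_somatic <- lapply(idx, `[`, keep)
  }
  exclusive <- NULL
  if (!is.null(config$exclusive_gene)) {
    gene <- config$exclusive_gene$gene
    if (!gene %in% names(panel$genes))
      stop("exclusive gene not in panel: ", gene)
    g <- panel$genes[[gene]]
    exclusive <- with_substream(config$seed, "exclusive_gene", {
      case_ids <- sample(manifest$case_sample_id,
                         min(config$exclusive_gene$n_cases, config$n_pairs))
      pos <- vapply(case_ids, function(s) {
        iv <- g$cds[sample(nrow(g$cds), 1), ]
        sample(seq(iv$start, iv$end), 1)
      }, integer(1))
      ref <- vapply(pos, function(p) {
        ref_seq(panel$reference, g$symbol, p, p)
      }, character(1))
      data.frame(sample_id = case_ids, contig = gene, pos = pos, ref = ref,
                 alt = random_alt(ref), gene = gene, stringsAsFactors = FALSE)
    })
  }

  truth_list <- list()
  rc_list <- list()
  call_list <- list()
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    res <- with_substream(config$seed, paste0("sample:", sid), {
      extra <- if (!is.null(exclusive) && sid %in% exclusive$sample_id)
        exclusive[exclusive$sample_id == sid, , drop = FALSE] else NULL
      truth <- sample_truth(sid, samples$is_case[si], panel, idx, ffpe_idx,
                            pop_pool, pon_pool, config, ffpe_affected[si],
                            extra_somatic = extra,
                            idx_somatic = idx_somatic)
      obs <- sample_observations(truth, panel, idx, config)
      list(truth = truth, obs = obs)
    })
    truth <- res$truth
    rc <- res$obs$readcounts
    per_caller <- list()
    err_truth <- list()
    for (caller in names(config$caller_sensitivity)) {
      det <- res$obs$detection[[caller]]
      hit_rows <- rc[det$hit, , drop = FALSE]
      fr <- det$false_rows
      if (!is.null(fr) && nrow(fr) > 0) {
        frc <- data.frame(sample_id = sid, fr[, c("contig", "pos", "ref",
                                                  "alt", "tumor_depth",
                                                  "tumor_alt",
                                                  "normal_depth",
                                                  "normal_alt")],
                          stringsAsFactors = FALSE)
        rc <- rbind(rc, frc)
        hit_rows <- rbind(hit_rows, frc)
        err_truth[[caller]] <- data.frame(
          sample_id = sid, contig = fr$contig, pos = fr$pos, ref = fr$ref,
          alt = fr$alt, origin = "sequencing_error",
          true_vaf = 0, gene = fr$gene, stringsAsFactors = FALSE)
      }
      if (nrow(hit_rows) > 0) {
        per_caller[[caller]] <- variant_calls(
          sample_id = sid, contig = hit_rows$contig, pos = hit_rows$pos,
          ref = hit_rows$ref, alt = hit_rows$alt, callers = caller,
          tumor_depth = hit_rows$tumor_depth,
          tumor_alt = hit_rows$tumor_alt,
          normal_depth = hit_rows$normal_depth,
          normal_alt = hit_rows$normal_alt)
      } else {
        per_caller[[caller]] <- variant_calls()
      }
    }
    if (length(err_truth) > 0) truth <- rbind(truth, do.call(rbind,
                                                             err_truth))
    truth <- truth[!duplicated(paste(truth$contig, truth$pos, truth$ref,
                                     truth$alt)), , drop = FALSE]
    rc <- rc[!duplicated(paste(rc$contig, rc$pos, rc$ref, rc$alt)), ,
             drop = FALSE]
    truth_list[[sid]] <- truth
    rc_list[[sid]] <- rc
    call_list[[sid]] <- per_caller
  }

  structure(list(
    config = config,
    panel = panel,
    manifest = manifest,
    ffpe_affected_samples = samples$sample_id[ffpe_affected],
    truth = do.call(rbind, c(truth_list, list(make.row.names = FALSE))),
    readcounts = do.call(rbind, c(rc_list, list(make.row.names = FALSE))),
    caller_calls = call_list,
    pon = pon_pool,
    popfreq = pop_pool[, c("contig", "pos", "ref", "alt", "frequency")],
    gene_sets = gene_sets
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$manifest), "pairs,",
      length(x$caller_calls), "samples,", nrow(x$truth), "truth records\n")
  invisible(x)
}

#' Materialize a synthetic cohort as pipeline input files
#'
#' Writes per-(sample, caller) VCFs, the read-count sidecar, panel files,
#' pair manifest, PoN blacklist, population-frequency table, gene sets
#' (GMT), the truth table, and the config (YAML).
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return named list of paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  paths <- write_panel(cohort$panel, dir)
  for (sid in names(cohort$caller_calls)) {
    for (caller in names(cohort$caller_calls[[sid]])) {
      calls <- cohort$caller_calls[[sid]][[caller]]
      write_vcf(calls, file.path(dir, "vcf",
                                 paste0(sid, ".", caller, ".vcf")))
    }
  }
  paths$readcounts <- file.path(dir, "readcounts.tsv")
  write_readcounts(cohort$readcounts, paths$readcounts)
  paths$manifest <- file.path(dir, "pairs.tsv")
  write_pair_manifest(cohort$manifest, paths$manifest)
  paths$pon <- file.path(dir, "pon.tsv")
  write_pon(cohort$pon, paths$pon)
  paths$popfreq <- file.path(dir, "popfreq.tsv")
  write_popfreq(cbind(cohort$popfreq,
                      key = call_key(cohort$popfreq))[,
                        c("contig", "pos", "ref", "alt", "frequency")],
                paths$popfreq)
  paths$gmt <- file.path(dir, "genesets.gmt")
  write_gmt(cohort$gene_sets, paths$gmt)
  paths$truth <- file.path(dir, "truth.tsv")
  write.table(cohort$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$config <- file.path(dir, "config.yaml")
  cfg <- unclass(cohort$config)
  cfg$caller_sensitivity <- as.list(cfg$caller_sensitivity)
  yaml::write_yaml(cfg, paths$config, precision = 15)
  paths$vcf_dir <- file.path(dir, "vcf")
  invisible(paths)
}

# ---- progression pairs ---------------------------------------------------

#' Generate paired BBD/IBC progression samples with truth
#'
#' For each of \code{n_pairs} subjects, a BBD sample and a subsequent
#' ipsilateral IBC sample are simulated; each BBD somatic variant recurs in
#' the IBC sample with probability \code{shared_fraction}.  Read counts are
#' force-called in both samples at the union of the pair's variant sites, so
#' the overlap analysis can categorize every site.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param n_pairs number of BBD/IBC subjects (study value: 7).
#' @param shared_fraction probability a BBD somatic variant recurs in IBC.
#' @param somatic_rate expected somatic mutations per sample in this set.
#' @return list of per-pair records: pair_id, bbd/ibc call tables,
#'   force-called \code{counts} at the site union, and \code{truth}.
#' @export
generate_progression_pairs <- function(config, n_pairs = 7,
                                       shared_fraction = 0,
                                       somatic_rate = 2) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1)
  panel <- generate_panel(config)
  idx <- panel_positions(panel)
  pairs <- list()
  for (pi in seq_len(n_pairs)) {
    pid <- sprintf("PRG%02d", pi)
    pairs[[pid]] <- with_substream(config$seed, paste0("progression:", pid), {
      draw_set <- function() {
        n <- rpois(1, somatic_rate)
        if (n == 0) return(NULL)
        rows <- lapply(seq_len(n), function(k) {
          s <- draw_somatic_site(panel, idx, config)
          s$vaf <- rbeta(1, config$somatic_vaf_shape1,
                         config$somatic_vaf_shape2)
          as.data.frame(s, stringsAsFactors = FALSE)
        })
        do.call(rbind, rows)
      }
      bbd <- draw_set()
      shared <- if (!is.null(bbd) && nrow(bbd) > 0) {
        bbd[runif(nrow(bbd)) < shared_fraction, , drop = FALSE]
      } else NULL
      ibc_own <- draw_set()
      if (!is.null(shared) && nrow(shared) > 0) {
        shared$vaf <- rbeta(nrow(shared), config$somatic_vaf_shape1,
                            config$somatic_vaf_shape2)
      }
      ibc <- rbind(shared, ibc_own)
      if (!is.null(ibc))
        ibc <- ibc[!duplicated(paste(ibc$contig, ibc$pos, ibc$ref,
                                     ibc$alt)), , drop = FALSE]
      empty <- data.frame(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene = character(), vaf = numeric(),
                          stringsAsFactors = FALSE)
      if (is.null(bbd)) bbd <- empty
      if (is.null(ibc)) ibc <- empty
      union_keys <- rbind(bbd[, c("contig", "pos", "ref", "alt")],
                          ibc[, c("contig", "pos", "ref", "alt")])
      union_keys <- union_keys[!duplicated(call_key(union_keys)), ,
                               drop = FALSE]
      force_call <- function(variants, union_keys) {
        n <- nrow(union_keys)
        dp <- draw_depth(n, config)
        key <- call_key(union_keys)
        vkey <- call_key(variants)
        vaf <- variants$vaf[match(key, vkey)]
        present <- !is.na(vaf)
        alt <- integer(n)
        alt[present] <- rbinom(sum(present), dp[present], vaf[present])
        alt[!present] <- rbinom(sum(!present), dp[!present],
                                config$error_rate)
        data.frame(key = key, depth = dp, alt = alt,
                   stringsAsFactors = FALSE)
      }
      bbd_counts <- force_call(bbd, union_keys)
      ibc_counts <- force_call(ibc, union_keys)
      counts <- data.frame(
        union_keys,
        key = call_key(union_keys),
        bbd_depth = bbd_counts$depth, bbd_alt = bbd_counts$alt,
        ibc_depth = ibc_counts$depth, ibc_alt = ibc_counts$alt,
        stringsAsFactors = FALSE)
      truth <- rbind(
        if (nrow(bbd) > 0) cbind(role = "bbd", bbd) else NULL,
        if (nrow(ibc) > 0) cbind(role = "ibc", ibc) else NULL)
      mk_calls <- function(variants, role) {
        if (nrow(variants) == 0) return(variant_calls())
        k <- call_key(variants)
        cc <- counts[match(k, counts$key), , drop = FALSE]
        dp <- if (role == "bbd") cc$bbd_depth else cc$ibc_depth
        alt <- if (role == "bbd") cc$bbd_alt else cc$ibc_alt
        keep <- alt > 0
        variant_calls(
          sample_id = paste0(pid, "_", role),
          contig = variants$contig[keep], pos = variants$pos[keep],
          ref = variants$ref[keep], alt = variants$alt[keep],
          callers = "mutect",
          tumor_depth = dp[keep], tumor_alt = alt[keep],
          normal_depth = dp[keep], normal_alt = 0L)
      }
      list(pair_id = pid,
           bbd_calls = mk_calls(bbd, "bbd"),
           ibc_calls = mk_calls(ibc, "ibc"),
           counts = counts,
           truth = truth)
    })
  }
  pairs
}

# ---- count-level null simulator -----------------------------------------

#' Simulate per-pair detected mutation counts only
#'
#' The count-level marginal of \code{\link{generate_cohort}}: per-sample
#' detected somatic mutation counts are Poisson (independent thinning of a
#' Poisson process by detection is Poisson), so burden-test calibration can
#' be studied over thousands of replicate cohorts without materializing
#' calls.
#'
#' @param n_pairs number of matched pairs.
#' @param somatic_rate expected detected somatic mutations per sample.
#' @param case_effect multiplicative case shift (1 = null).
#' @return data.frame with columns pair_id, case_count, control_count.
#' @export
simulate_pair_counts <- function(n_pairs, somatic_rate = 2.3,
                                 case_effect = 1.0) {
  data.frame(
    pair_id = sprintf("P%03d", seq_len(n_pairs)),
    case_count = rpois(n_pairs, somatic_rate * case_effect),
    control_count = rpois(n_pairs, somatic_rate),
    stringsAsFactors = FALSE)
}
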
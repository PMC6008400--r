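# End-to-end orchestration: simulate -> merge -> filter -> ffpe-screen ->
# annotate -> stats (and optional progression overlap), driven by a single
# config that surfaces every threshold.  Defaults are the study's printed
# values.

#' Pipeline configuration
#'
#' Bundles the simulator settings and every analysis threshold.  Threshold
#' defaults follow the study design: 20x minimum depth, 0.1% maximum
#' population frequency, somatic log-likelihood margin 5, FFPE VAF cutoff
#' 10% with flagging at 3 artifacts, founding-clone VAF 25%, and overlap
#' support of 3 reads.
#'
#' @param sim a \code{\link{simulation_config}} (its seed drives all
#'   randomness).
#' @param min_depth,max_popfreq,somatic_threshold,error_rate filter
#'   cascade settings.
#' @param ffpe_vaf_cutoff,ffpe_min_artifacts,ffpe_both_strands FFPE screen
#'   settings.
#' @param founding_clone_vaf strict VAF bound of the founding-clone
#'   stratum.
#' @param overlap_min_support definitive-share read support.
#' @param n_permutations gene-set permutation count.
#' @param progression_pairs,progression_shared_fraction BBD/IBC
#'   progression set size and sharing rate (0 pairs disables the stage).
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            min_depth = 20,
                            max_popfreq = 0.001,
                            somatic_threshold = 5,
                            error_rate = 0.001,
                            ffpe_vaf_cutoff = 0.10,
                            ffpe_min_artifacts = 3,
                            ffpe_both_strands = TRUE,
                            founding_clone_vaf = 0.25,
                            overlap_min_support = 3,
                            n_permutations = 10000,
                            progression_pairs = 7,
                            progression_shared_fraction = 0) {
  cfg <- as.list(environment())
  stopifnot(inherits(sim, "simulation_config"))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$caller_sensitivity <- as.list(x$sim$caller_sensitivity)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_args <- x$sim
  sim_args$caller_sensitivity <- unlist(sim_args$caller_sensitivity)
  if (!is.null(sim_args$exclusive_gene) &&
      length(sim_args$exclusive_gene) == 0)
    sim_args$exclusive_gene <- NULL
  x$sim <- do.call(simulation_config, sim_args)
  do.call(pipeline_config, x)
}

#' Analyse a cohort (merge through statistics), in memory
#'
#' Runs the post-calling pipeline on a simulated (or equivalently loaded)
#' cohort: per-sample ensemble merge with sidecar counts, the filter
#' cascade, the FFPE screen, effect annotation, and the full statistical
#' battery.
#'
#' @param cohort a \code{synthetic_cohort} (or compatible list).
#' @param config a \code{\link{pipeline_config}}.
#' @return list with merged/filtered/annotated calls, per-stage attrition,
#'   the FFPE report, burden tables, per-gene tests, exclusivity,
#'   enrichment results, and overall/non-silent/founding-clone test
#'   results.
#' @export
run_cohort_analysis <- function(cohort, config = pipeline_config()) {
  merged <- do.call(rbind, c(lapply(names(cohort$caller_calls),
    function(sid) {
      merge_sample(cohort$caller_calls[[sid]], readcounts =
                     cohort$readcounts[cohort$readcounts$sample_id == sid, ,
                                       drop = FALSE],
                   reference = cohort$panel$reference)
    }), list(make.row.names = FALSE)))
  cascade <- run_filter_cascade(
    merged, pon = call_key(cohort$pon),
    popfreq = {
      pf <- cohort$popfreq
      pf$key <- call_key(pf)
      pf
    },
    min_depth = config$min_depth, max_freq = config$max_popfreq,
    error_rate = config$error_rate, threshold = config$somatic_threshold)
  screened <- screen_cohort(cascade$calls, cohort$panel$reference,
                            vaf_cutoff = config$ffpe_vaf_cutoff,
                            min_artifacts = config$ffpe_min_artifacts,
                            both_strands = config$ffpe_both_strands)
  annotated <- annotate_calls(screened$calls, cohort$panel)
  burden_all <- build_burden_table(annotated, cohort$manifest, "all")
  burden_ns <- build_burden_table(annotated, cohort$manifest, "non_silent")
  burden_fc <- build_burden_table(annotated, cohort$manifest,
                                  "founding_clone",
                                  founding_clone_vaf =
                                    config$founding_clone_vaf)
  gene_universe <- vapply(cohort$panel$genes, `[[`, "", "symbol",
                          USE.NAMES = FALSE)
  per_gene <- build_burden_table(annotated, cohort$manifest, "per_gene",
                                 genes = gene_universe)
  tests <- list(
    overall = paired_t_test(burden_all$case_count,
                            burden_all$control_count),
    non_silent = paired_t_test(burden_ns$case_count,
                               burden_ns$control_count),
    founding_clone = paired_t_test(burden_fc$case_count,
                                   burden_fc$control_count))
  gene_results <- per_gene_tests(per_gene)
  enrichment <- geneset_enrichment(per_gene, cohort$gene_sets,
                                   n_permutations = config$n_permutations,
                                   seed = cohort$config$seed)
  list(merged = merged,
       filtered = cascade$calls,
       attrition = rbind(
         data.frame(stage = "merge", n_in = NA_integer_,
                    n_out = nrow(merged), stringsAsFactors = FALSE),
         cascade$attrition,
         data.frame(stage = "ffpe_screen", n_in = nrow(cascade$calls),
                    n_out = nrow(screened$calls),
                    stringsAsFactors = FALSE)),
       ffpe_report = screened$report,
       ffpe_flagged_samples = screened$flagged_samples,
       calls = annotated,
       burden = list(all = burden_all, non_silent = burden_ns,
                     founding_clone = burden_fc, per_gene = per_gene),
       tests = tests,
       gene_results = gene_results,
       exclusivity = exclusivity_summary(per_gene),
       enrichment = enrichment)
}

#' Run the whole pipeline from one config and write results
#'
#' Simulates the cohort, writes its input files, runs
#' \code{\link{run_cohort_analysis}}, runs the BBD/IBC progression overlap
#' when configured, writes all stage outputs as TSV/VCF under
#' \code{out_dir}, and records provenance (config hash, seed, versions,
#' per-stage counts).  Outputs carry no timestamps, so a rerun with the
#' same config is byte-identical.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory.
#' @return the analysis result list, invisibly, with \code{paths} added.
#' @export
run_all <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  result <- tryCatch({
    cohort <- generate_cohort(config$sim)
    input_paths <- write_cohort(cohort, file.path(out_dir, "inputs"))
    stage <- "analysis"
    res <- run_cohort_analysis(cohort, config)
    stage <- "progression_overlap"
    overlap <- NULL
    if (config$progression_pairs > 0) {
      prg <- generate_progression_pairs(
        config$sim, n_pairs = config$progression_pairs,
        shared_fraction = config$progression_shared_fraction)
      records <- do.call(rbind, c(lapply(prg, function(p) {
        overlap_pair(p$pair_id, p$bbd_calls, p$ibc_calls, p$counts,
                     min_support = config$overlap_min_support)
      }), list(make.row.names = FALSE)))
      overlap <- list(records = records, report = overlap_report(records))
    }
    stage <- "write_outputs"
    write_vcf_multi <- function(calls, path) {
      # one VCF per sample under a directory
      dir.create(path, showWarnings = FALSE)
      for (sid in unique(calls$sample_id))
        write_vcf(calls[calls$sample_id == sid, , drop = FALSE],
                  file.path(path, paste0(sid, ".vcf")))
    }
    write_vcf_multi(res$calls, file.path(out_dir, "final_calls"))
    tsv <- function(x, name) {
      write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    tsv(res$attrition, "attrition.tsv")
    tsv(res$ffpe_report, "ffpe_report.tsv")
    tsv(res$gene_results, "gene_tests.tsv")
    tsv(res$burden$all, "burden_all.tsv")
    tsv(res$burden$non_silent, "burden_non_silent.tsv")
    tsv(res$burden$founding_clone, "burden_founding_clone.tsv")
    tsv(res$enrichment, "enrichment.tsv")
    overall <- data.frame(
      stratum = c("all", "non_silent", "founding_clone"),
      t = c(res$tests$overall$t, res$tests$non_silent$t,
            res$tests$founding_clone$t),
      df = c(res$tests$overall$df, res$tests$non_silent$df,
             res$tests$founding_clone$df),
      p = c(res$tests$overall$p, res$tests$non_silent$p,
            res$tests$founding_clone$p))
    tsv(overall, "burden_tests.tsv")
    if (!is.null(overlap)) tsv(overlap$records, "overlap.tsv")
    cfg_path <- file.path(out_dir, "pipeline_config.yaml")
    write_pipeline_config(config, cfg_path)
    provenance <- list(
      config_md5 = unname(tools::md5sum(cfg_path)),
      seed = config$sim$seed,
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      package_version = as.character(utils::packageVersion("bbdsomatic")),
      stage_counts = setNames(as.list(res$attrition$n_out),
                              res$attrition$stage),
      n_pairs = nrow(cohort$manifest),
      n_final_calls = nrow(res$calls))
    yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))
    res$overlap <- overlap
    res$paths <- list(out_dir = out_dir, inputs = input_paths)
    res
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
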
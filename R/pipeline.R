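#' End-to-end pipeline orchestration
#'
#' Stages run in a fixed order: CNV QC, gene-wise CNV permutation testing,
#' DNV recurrence testing, evidence integration (Fisher + BH + weighted
#' Bonferroni), locus merging, optional expression and network stages. A
#' run manifest records the configuration hash, seed and stage timings;
#' reruns with the same configuration and seed are reproducible.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Either `simulate = TRUE` (inputs generated from `sim`) or paths to the
#' input tables. Subgroup filters subset cases by subphenotype before
#' testing (controls are always retained).
#'
#' @param seed mandatory seed for every stochastic stage.
#' @param simulate generate inputs with the synthetic-data module.
#' @param sim [sim_config] when simulating (defaults to
#'   `sim_config(seed)`).
#' @param cnv_path,gene_path,mask_paths,probe_path,dnv_path,rate_path,samples_path
#'   input locations when not simulating (`mask_paths`: named list of BEDs
#'   `telomeres`, `centromeres`, `segdups`).
#' @param qc [qc_params].
#' @param n_perm CNV permutations (default 10000).
#' @param n_trios trio count for the DNV test (default: from `sim`).
#' @param n_genes_bonferroni DNV Bonferroni universe (default 18272).
#' @param ihw [ihw_config].
#' @param alpha per-stream significance level.
#' @param exclude_subphenotype,include_only_subphenotype case subgroup
#'   filters (e.g. exclude "TAA", or run "LVOTO" only).
#' @param stratify_by_study permute case/control labels within study
#'   (default FALSE, mirroring the unstratified reference command).
#' @param run_expression,run_network toggles for the downstream stages
#'   (simulated inputs only).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, simulate = TRUE, sim = NULL,
                            cnv_path = NULL, gene_path = NULL,
                            mask_paths = NULL, probe_path = NULL,
                            dnv_path = NULL, rate_path = NULL,
                            samples_path = NULL,
                            qc = qc_params(), n_perm = 10000,
                            n_trios = NULL, n_genes_bonferroni = 18272,
                            ihw = ihw_config(seed = seed), alpha = 0.05,
                            exclude_subphenotype = NULL,
                            include_only_subphenotype = NULL,
                            stratify_by_study = FALSE,
                            run_expression = TRUE, run_network = TRUE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (simulate && is.null(sim)) sim <- sim_config(seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' @param config [pipeline_config].
#' @param outdir output directory for the result bundle (created); NULL
#'   returns results without writing.
#' @return list of class `pipeline_result`: `gene_results`, `loci`,
#'   `cnv_perm`, `dnv`, `qc_report`, `samples`, and (when enabled)
#'   `expression`, `network`, plus `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    tick(name)
    res
  }
  # ---- inputs -------------------------------------------------------
  inputs <- stage("load", {
    if (config$simulate) {
      ann <- simulate_annotation(config$sim)
      coh <- simulate_cnv_cohort(config$sim, ann)
      dnvs <- simulate_trio_dnvs(config$sim, ann)
      list(genes = ann$genes, masks = ann$masks, cnvs = coh$cnvs,
           samples = coh$samples, dnvs = dnvs,
           rates = ann$genes[, c("gene_id", "rate_ptv", "rate_missense",
                                 "rate_silent")],
           n_trios = config$sim$n_trios)
    } else {
      masks <- lapply(config$mask_paths, load_bed)
      list(genes = load_gene_models(config$gene_path),
           masks = c(masks, list(probes = load_probes(config$probe_path))),
           cnvs = load_cnv_table(config$cnv_path)$calls,
           samples = utils::read.table(config$samples_path, header = TRUE,
                                       sep = "\t", stringsAsFactors = FALSE),
           dnvs = load_dnv_table(config$dnv_path),
           rates = load_rate_table(config$rate_path),
           n_trios = config$n_trios)
    }
  })
  samples <- inputs$samples
  # ---- subgroup filters --------------------------------------------
  if (!is.null(config$exclude_subphenotype))
    samples <- samples[samples$phenotype == "control" |
                         !samples$subphenotype %in%
                         config$exclude_subphenotype, , drop = FALSE]
  if (!is.null(config$include_only_subphenotype))
    samples <- samples[samples$phenotype == "control" |
                         samples$subphenotype %in%
                         config$include_only_subphenotype, , drop = FALSE]
  cnvs <- inputs$cnvs[inputs$cnvs$sample_id %in% samples$sample_id, ,
                      drop = FALSE]
  # ---- CNV QC -------------------------------------------------------
  qc <- stage("cnv_qc", {
    n_controls <- sum(samples$phenotype == "control")
    cnvs <- compute_internal_maf(cnvs, n_controls,
                                 config$qc$reciprocal_threshold)
    apply_qc(cnvs, inputs$masks, config$qc, deletions_only = TRUE)
  })
  # ---- CNV association ---------------------------------------------
  cnv_perm <- stage("cnv_test", {
    oc <- gene_overlap_counts(qc$passed, inputs$genes, samples)
    permutation_gene_test(oc, n_perm = config$n_perm, seed = config$seed,
                          strata = if (isTRUE(config$stratify_by_study))
                            samples$study_id else NULL)
  })
  # ---- DNV ----------------------------------------------------------
  dnv <- stage("dnv_test", {
    recs <- filter_dnvs(inputs$dnvs)
    counts <- dnv_gene_counts(recs)
    pois <- poisson_recurrence_test(counts, inputs$rates, inputs$n_trios)
    fin <- finalize_dnv_p(pois$p_poisson,
                          n_genes = config$n_genes_bonferroni)
    cbind(pois, fin)
  })
  # ---- integration --------------------------------------------------
  results <- stage("integrate", {
    assemble_results(cnv_perm, dnv, inputs$genes$gene_id,
                     loeuf = inputs$genes$loeuf, alpha = config$alpha,
                     ihw = config$ihw)
  })
  loci <- stage("loci", {
    sig <- inputs$genes[match(results$gene_id[results$p_cnv_emp2 <
                                                config$alpha],
                              inputs$genes$gene_id), , drop = FALSE]
    merge_significant_loci(sig, qc$passed)
  })
  out <- list(gene_results = results, loci = loci, cnv_perm = cnv_perm,
              dnv = dnv, qc_report = qc$report, qc_passed = qc$passed,
              samples = samples)
  # ---- expression ---------------------------------------------------
  if (isTRUE(config$run_expression) && config$simulate) {
    out$expression <- stage("expression", {
      ex <- simulate_expression(config$sim,
                                gene_ids = utils::head(inputs$genes$gene_id,
                                                       config$sim$expr_n_genes))
      list(stage_summary = stage_means_and_ranks(ex$rpkm, ex$meta),
           de = timecourse_de(ex$cpm, ex$meta, comparator = "liver"),
           truth = ex$truth)
    })
  }
  # ---- network ------------------------------------------------------
  if (isTRUE(config$run_network) && config$simulate) {
    out$network <- stage("network", {
      seeds <- results$gene_id[results$q_bh < 0.05]
      if (length(seeds) >= 5) {
        ppi <- simulate_ppi(config$sim, nodes = seeds)
        g <- build_seed_network(seeds, ppi$edges)
        list(graph = g,
             clusters = cluster_network(g, n_perm = 200,
                                        seed = config$seed))
      } else list(graph = NULL, clusters = list())
    })
  }
  cfg_file <- tempfile(); on.exit(unlink(cfg_file), add = TRUE)
  saveRDS(.stable_config(config), cfg_file)
  out$manifest <- list(
    package_version = as.character(utils::packageVersion("delmeta")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    n_cases = sum(samples$phenotype == "case"),
    n_controls = sum(samples$phenotype == "control"),
    n_genes = nrow(inputs$genes),
    n_perm = config$n_perm,
    timings_sec = as.list(timings))
  class(out) <- "pipeline_result"
  if (!is.null(outdir)) write_pipeline_result(out, outdir)
  out
}

# configuration stripped to stable, serializable fields (hash input)
.stable_config <- function(config) {
  cfg <- unclass(config)
  cfg$ihw <- unclass(cfg$ihw); cfg$qc <- unclass(cfg$qc)
  if (!is.null(cfg$sim)) cfg$sim <- unclass(cfg$sim)
  cfg
}

#' Write the pipeline result bundle as TSVs + manifest JSON
#' @param result `pipeline_result`.
#' @param outdir directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(result$gene_results, file.path(outdir, "gene_results.tsv"))
  write_tsv(result$loci, file.path(outdir, "loci.tsv"))
  write_tsv(result$cnv_perm, file.path(outdir, "cnv_permutation.tsv"))
  write_tsv(result$dnv, file.path(outdir, "dnv_results.tsv"))
  write_tsv(result$qc_report, file.path(outdir, "qc_report.tsv"))
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("delmeta pipeline result\n")
  cat(sprintf("  cohort: %d cases / %d controls\n",
              x$manifest$n_cases, x$manifest$n_controls))
  cat(sprintf("  genes tested: %d; permutations: %d\n",
              x$manifest$n_genes, x$manifest$n_perm))
  top <- utils::head(x$gene_results[order(x$gene_results$meta_p), ], 5)
  cat("  top genes by combined p:\n")
  print(top[, c("gene_id", "n_case_cnv", "n_control_cnv", "p_cnv_emp1",
                "n_nsdnv", "p_dnv", "meta_p", "p_ihw")], row.names = FALSE)
  invisible(x)
}
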
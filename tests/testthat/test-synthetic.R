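# n_controls stays well above 1/maf_threshold so chance recurrences among
# background control calls do not cross the 1% internal-frequency gate
small_cfg <- function(seed = 1, ...) {
  sim_config(seed, n_cases = 60, n_controls = 1000, n_genes = 60,
             n_chrom = 4, n_small = 4, n_large = 2, n_lowprobe = 3,
             n_mask = 3, n_nonauto = 2, ...)
}

test_that("simulate_annotation tiles disjoint genes and is deterministic", {
  ann <- simulate_annotation(small_cfg())
  g <- ann$genes
  expect_equal(nrow(g), 60)
  expect_true(all(g$end > g$start))
  # no overlap within chromosomes
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  # genes avoid masks entirely
  masks <- rbind(ann$masks$telomeres[, 1:3], ann$masks$centromeres[, 1:3],
                 ann$masks$segdups[, 1:3])
  cov <- vapply(seq_len(nrow(g)), function(i)
    fraction_covered(iv(g$chrom[i], g$start[i], g$end[i]), masks),
    numeric(1))
  expect_true(all(cov == 0))
  # determinism
  ann2 <- simulate_annotation(small_cfg())
  expect_identical(ann, ann2)
  # risk genes drawn from the low-LOEUF tail
  big <- simulate_annotation(sim_config(3, n_genes = 300, n_chrom = 6,
                                        n_cases = 10, n_controls = 10))
  gb <- big$genes
  expect_lt(mean(gb$loeuf[gb$is_cnv_risk | gb$is_dnv_risk]),
            mean(gb$loeuf[!(gb$is_cnv_risk | gb$is_dnv_risk)]))
  expect_error(simulate_annotation(sim_config(1, n_genes = 5000,
                                              n_chrom = 2,
                                              chrom_length = 1e6)),
               "too small")
})

test_that("simulate_cnv_cohort plants what it claims", {
  cfg <- small_cfg(2)
  ann <- simulate_annotation(cfg)
  coh <- simulate_cnv_cohort(cfg, ann)
  expect_identical(coh, simulate_cnv_cohort(cfg, ann))     # determinism
  cnvs <- coh$cnvs
  expect_equal(nrow(coh$samples), 1060)
  # planted violators fall at their gates; clean calls pass everything
  cnvs <- compute_internal_maf(cnvs, n_controls = 1000)
  qc <- apply_qc(cnvs, ann$masks, qc_params())
  flagged <- qc$removed
  expect_true(all(flagged$planted_qc[flagged$qc_flag == "size"] == "size"))
  expect_true(all(flagged$planted_qc[flagged$qc_flag == "probes"] == "probes"))
  expect_true(all(flagged$planted_qc[flagged$qc_flag == "mask"] == "mask"))
  expect_true(all(flagged$planted_qc[flagged$qc_flag == "maf"] == "maf"))
  expect_true(all(qc$passed$planted_qc == "clean"))
  # each planted class is removed in full
  for (cls in c("size", "probes", "mask", "maf", "non_autosomal"))
    expect_equal(sum(flagged$planted_qc == cls),
                 sum(cnvs$planted_qc == cls))
  # null multipliers leave case/control per-gene rates comparable
  cfg0 <- sim_config(4, cnv_risk_multiplier = 1, n_cases = 150,
                     n_controls = 150, n_genes = 60, n_chrom = 4)
  coh0 <- simulate_cnv_cohort(cfg0, simulate_annotation(cfg0))
  bg <- coh0$cnvs[coh0$cnvs$planted_qc == "clean", ]
  rate_case <- sum(bg$phenotype == "case") / 150
  rate_ctrl <- sum(bg$phenotype == "control") / 150
  se <- sqrt(rate_ctrl / 150 + rate_case / 150)
  expect_lt(abs(rate_case - rate_ctrl), 3 * se)
})

test_that("simulate_trio_dnvs draws counts at the configured rates", {
  cfg <- sim_config(5, n_genes = 200, n_chrom = 6, n_cases = 10,
                    n_controls = 10, dnv_multiplier = 1)
  ann <- simulate_annotation(cfg)
  dnvs <- simulate_trio_dnvs(cfg, ann)
  expect_identical(dnvs, simulate_trio_dnvs(cfg, ann))
  expect_true(all(dnvs$population_maf == 0))
  mu_total <- sum(ann$genes$rate_ptv + ann$genes$rate_missense +
                    ann$genes$rate_silent)
  lam <- 2 * cfg$n_trios * mu_total
  expect_lt(abs(nrow(dnvs) - lam), 3 * sqrt(lam))
  # classified terms are consistent with the class they were drawn for
  cls <- classify_consequence(dnvs$consequence_term)
  expect_true(all(cls %in% c("PTV", "missense", "silent")))
  # enrichment lands in the risk genes
  cfg2 <- sim_config(6, n_genes = 200, n_chrom = 6, n_cases = 10,
                     n_controls = 10, dnv_multiplier = 100)
  ann2 <- simulate_annotation(cfg2)
  dnvs2 <- simulate_trio_dnvs(cfg2, ann2)
  counts <- dnv_gene_counts(filter_dnvs(dnvs2))
  pois <- poisson_recurrence_test(counts, ann2$genes, cfg2$n_trios)
  risk <- ann2$genes$gene_id[ann2$genes$is_dnv_risk]
  expect_gte(sum(pois$gene_id[order(pois$p_poisson)][1:10] %in% risk), 8)
})

test_that("simulated fixtures round-trip through their loaders", {
  cfg <- small_cfg(7)
  ann <- simulate_annotation(cfg)
  coh <- simulate_cnv_cohort(cfg, ann)
  dir <- withr::local_tempdir()
  cp <- file.path(dir, "cnvs.tsv")
  write_cnv_table(coh$cnvs, cp)
  back <- load_cnv_table(cp)
  expect_equal(nrow(back$calls) + nrow(back$rejected), nrow(coh$cnvs))
  auto <- coh$cnvs[coh$cnvs$chrom %in% as.character(1:22), ]
  expect_equal(back$calls$start, auto$start)
  expect_equal(back$calls$sample_id, auto$sample_id)
  gp <- file.path(dir, "genes.tsv")
  write_tsv(data.frame(chrom = ann$genes$chrom, start = ann$genes$start,
                       end = ann$genes$end, gene = ann$genes$gene_id,
                       loeuf = ann$genes$loeuf), gp)
  gm <- load_gene_models(gp)
  expect_equal(gm$start, ann$genes$start)
  pp <- file.path(dir, "probes.tsv")
  write_tsv(ann$masks$probes, pp)
  expect_equal(nrow(load_probes(pp)), nrow(ann$masks$probes))
})

test_that("simulate_expression plants recoverable structure", {
  cfg <- sim_config(8, expr_n_genes = 80, expr_n_deg = 8, expr_n_high = 8)
  ex <- simulate_expression(cfg)
  expect_identical(ex, simulate_expression(cfg))
  expect_equal(dim(ex$cpm), c(80, nrow(ex$meta)))
  # >= 2 replicates per organ/time by construction
  expect_true(all(table(ex$meta$organ, ex$meta$days) >= 2))
  # planted DEGs recovered, flat genes quiet
  de <- timecourse_de(ex$cpm, ex$meta, comparator = "liver")
  expect_gte(sum(de$deg[ex$truth$is_deg], na.rm = TRUE), 7)
  fp <- mean(de$deg[!ex$truth$is_deg & !ex$truth$is_high], na.rm = TRUE)
  expect_lte(fp, 0.01 + 3 * sqrt(0.01 * 0.99 / 64))
  # planted high-in-heart genes land in the top quartile
  ss <- stage_means_and_ranks(ex$rpkm, ex$meta)
  expect_gte(mean(ss$top_quartile[ex$truth$is_high]), 0.95)
})

test_that("simulate_ppi emits deduplicated symmetric edges", {
  cfg <- sim_config(9)
  ppi <- simulate_ppi(cfg)
  expect_identical(ppi, simulate_ppi(cfg))
  key <- paste(pmin(ppi$edges$gene_a, ppi$edges$gene_b),
               pmax(ppi$edges$gene_a, ppi$edges$gene_b))
  expect_false(any(duplicated(key)))
  expect_true(all(ppi$edges$gene_a != ppi$edges$gene_b))
})
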
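test_that("gene_overlap_counts applies the carrier rule", {
  samples <- make_samples(3, 2)
  genes <- make_genes("1", c(1000, 3000, 5000), c(2000, 4000, 6000))
  cnvs <- rbind(
    # one deletion spanning all 3 genes (case S001)
    make_cnvs("1", 500, 7000, "S001"),
    # two deletions from the same case over gene 1: counted once
    make_cnvs("1", c(1100, 1200), c(1500, 1600), "S002"),
    # control carrier on gene 1
    make_cnvs("1", 900, 2100, "S004", "control"))
  oc <- gene_overlap_counts(cnvs, genes, samples)
  expect_equal(oc$counts$case_carriers, c(2L, 1L, 1L))
  expect_equal(oc$counts$control_carriers, c(1L, 0L, 0L))
  expect_setequal(oc$carriers$G01, c("S001", "S002", "S004"))
  expect_error(gene_overlap_counts(cnvs, genes[0, ], samples), "empty")
})

test_that("permutation matches exact enumeration on all small cohorts", {
  # toy from the contract: 2 cases carry, 2 controls do not -> p = 1/6
  samples <- make_samples(2, 2)
  genes <- make_genes("1", 1000, 2000)
  cnvs <- make_cnvs("1", c(900, 900), c(2100, 2100), c("S001", "S002"))
  oc <- gene_overlap_counts(cnvs, genes, samples)
  exact <- enumerate_exact_p(oc$incidence, oc$phenotype)
  expect_equal(exact, 1 / 6)
  pr <- permutation_gene_test(oc, n_perm = 10000, seed = 1)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(pr$emp1 - exact), 3 * se + 1 / 10001)

  # randomized cohorts of size <= 8, several genes (oracle equivalence)
  set.seed(202)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    k <- sample(2:(n - 2), 1)
    samples <- make_samples(k, n - k)
    ng <- sample(2:4, 1)
    genes <- make_genes("1", (0:(ng - 1)) * 10000 + 1000,
                        (0:(ng - 1)) * 10000 + 2000)
    carriers <- lapply(seq_len(ng), function(g)
      sample(samples$sample_id, sample.int(n, 1)))
    cnvs <- do.call(rbind, lapply(seq_len(ng), function(g)
      make_cnvs("1", genes$start[g] - 50, genes$end[g] + 50, carriers[[g]],
                phenotype = "case")))
    oc <- gene_overlap_counts(cnvs, genes, samples)
    exact <- enumerate_exact_p(oc$incidence, oc$phenotype)
    pr <- permutation_gene_test(oc, n_perm = 10000, seed = rep)
    for (g in seq_len(ng)) {
      se <- sqrt(exact[g] * (1 - exact[g]) / 10000)
      expect_lt(abs(pr$emp1[g] - exact[g]), 3 * se + 2 / 10001)
    }
  }
})

test_that("emp1 hits the permutation floor and emp2 >= emp1", {
  samples <- make_samples(20, 40)
  genes <- make_genes("1", c(1000, 50000), c(2000, 60000))
  # all 12 carriers of gene 1 are cases: far beyond any permutation
  cnvs <- rbind(
    make_cnvs("1", 900, 2100, sprintf("S%03d", 1:12)),
    make_cnvs("1", 49000, 61000, c("S013", "S030")))
  oc <- gene_overlap_counts(cnvs, genes, samples)
  pr <- permutation_gene_test(oc, n_perm = 10000, seed = 5)
  expect_equal(pr$emp1[1], 1 / 10001)
  expect_gte(pr$emp2[1], pr$emp1[1])
  expect_true(all(pr$emp2 >= pr$emp1))
  expect_true(all(pr$emp1 >= 1 / 10001 & pr$emp1 <= 1))
  # balanced carrier gene in a balanced cohort is unremarkable
  samples2 <- make_samples(30, 30)
  cnvs2 <- make_cnvs("1", 900, 2100, sprintf("S%03d", c(1:5, 31:35)),
                     phenotype = rep(c("case", "control"), each = 5))
  oc2 <- gene_overlap_counts(cnvs2, genes[1, ], samples2)
  pr2 <- permutation_gene_test(oc2, n_perm = 4000, seed = 6)
  expect_gte(pr2$emp1, 0.4)
})

test_that("permutation test is deterministic under a fixed seed and errors sanely", {
  samples <- make_samples(5, 5)
  genes <- make_genes("1", 1000, 2000)
  cnvs <- make_cnvs("1", 900, 2100, c("S001", "S002"))
  oc <- gene_overlap_counts(cnvs, genes, samples)
  a <- permutation_gene_test(oc, n_perm = 500, seed = 9)
  b <- permutation_gene_test(oc, n_perm = 500, seed = 9)
  expect_identical(a, b)
  expect_error(permutation_gene_test(oc, n_perm = 0), "n_perm")
  all_case <- make_samples(4, 0)
  oc2 <- gene_overlap_counts(make_cnvs("1", 900, 2100, "S001"), genes,
                             all_case)
  expect_error(permutation_gene_test(oc2, n_perm = 100), "cases and controls")
})

test_that("emp1 is non-increasing in the observed case-carrier count", {
  # fixed margins: 6 carriers of a gene, vary how many are cases
  set.seed(31)
  samples <- make_samples(10, 10)
  genes <- make_genes("1", 1000, 2000)
  emp1 <- vapply(2:6, function(k) {
    carriers <- c(sprintf("S%03d", seq_len(k)),              # cases
                  sprintf("S%03d", 10 + seq_len(6 - k)))     # controls
    cnvs <- make_cnvs("1", 900, 2100, carriers,
                      phenotype = rep(c("case", "control"), c(k, 6 - k)))
    oc <- gene_overlap_counts(cnvs, genes, samples)
    permutation_gene_test(oc, n_perm = 3000, seed = 77)$emp1
  }, numeric(1))
  expect_true(all(diff(emp1) <= 0))
})

test_that("syndrome_region_test works from a BED file", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t1000\t20000\tdel_syndrome_A",
               "2\t5000\t9000\tdel_syndrome_B"), bed)
  samples <- make_samples(10, 20)
  cnvs <- make_cnvs("1", 1500, 15000, sprintf("S%03d", 1:6))
  pr <- syndrome_region_test(cnvs, bed, samples, n_perm = 2000, seed = 3)
  expect_equal(pr$target, c("del_syndrome_A", "del_syndrome_B"))
  expect_lt(pr$emp1[1], 0.05)       # case-only cluster near the floor
  expect_equal(pr$emp1[2], 1.0)     # region with no CNVs
  expect_equal(pr$case_carriers[1], 6L)
  writeLines("1\t1000", bed)
  expect_error(syndrome_region_test(cnvs, bed, samples, 2000, 1),
               "malformed BED")
})

test_that("merge_significant_loci joins genes sharing case deletions", {
  genes <- make_genes("1", c(1000, 3000, 5000, 90000),
                      c(2000, 4000, 6000, 95000),
                      gene_id = c("A", "B", "C", "D"))
  # one deletion spans A-B, another spans B-C; D isolated
  cnvs <- rbind(make_cnvs("1", 500, 4500, "S1"),
                make_cnvs("1", 3500, 6500, "S2"),
                make_cnvs("1", 89000, 96000, "S3"))
  loci <- merge_significant_loci(genes, cnvs)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$member_genes[1], "A,B,C")     # transitive closure
  expect_equal(loci$n_genes, c(3L, 1L))
  expect_equal(loci$start[1], 1000)
  expect_equal(loci$end[1], 6000)
  # control-only sharing does not merge
  cnvs2 <- rbind(make_cnvs("1", 500, 4500, "S1", "control"),
                 make_cnvs("1", 89000, 96000, "S3"))
  loci2 <- merge_significant_loci(genes, cnvs2)
  expect_equal(nrow(loci2), 4)
})

test_that("logistic burden test: null, planted effect and separation", {
  # null: predictor independent of phenotype
  ok <- 0
  for (r in 1:10) {
    co <- build_burden_cohort(r, n = 1000)
    br <- geneset_burden_logistic(co$cnvs, co$genes, co$gene_set,
                                  co$samples)
    ok <- ok + (br$odds_ratio > 0.8 && br$odds_ratio < 1.25 &&
                  br$p_value > 0.05)
    expect_true(br$ci_low <= br$odds_ratio && br$odds_ratio <= br$ci_high)
  }
  expect_gte(ok, 8)
  # planted 3x case excess is recovered
  co <- build_burden_cohort(100, effect = 3)
  br <- geneset_burden_logistic(co$cnvs, co$genes, co$gene_set,
                                co$samples)
  expect_gt(br$odds_ratio, 1)
  expect_lt(br$p_value, 0.05)
  expect_equal(br$status, "ok")
  # complete separation is flagged, not a crash
  samples <- make_samples(5, 5)
  genes <- make_genes("1", 1000, 2000)
  cnvs <- make_cnvs("1", 900, 2100, sprintf("S%03d", 1:5))
  br2 <- geneset_burden_logistic(cnvs, genes, "G01", samples)
  expect_equal(br2$status, "separation")
  expect_error(geneset_burden_logistic(cnvs, genes, character(0), samples),
               "empty gene set")
})

test_that("study-stratified permutation preserves per-stratum case counts", {
  samples <- make_samples(10, 10, n_studies = 2)
  genes <- make_genes("1", 1000, 2000)
  cnvs <- make_cnvs("1", 900, 2100, sprintf("S%03d", 1:6))
  oc <- gene_overlap_counts(cnvs, genes, samples)
  a <- permutation_gene_test(oc, n_perm = 500, seed = 3,
                             strata = samples$study_id)
  expect_identical(a, permutation_gene_test(oc, n_perm = 500, seed = 3,
                                            strata = samples$study_id))
  expect_true(a$emp1 >= 1 / 501 && a$emp1 <= 1)
  # extreme stratification: labels fixed within single-individual strata,
  # so the permutation distribution is degenerate at the observed value
  b <- permutation_gene_test(oc, n_perm = 200, seed = 3,
                             strata = samples$sample_id)
  expect_equal(b$emp1, 1)
})

test_that("burden OR decreases across oeLOF bins when effects are planted low", {
  # genes binned by constraint: 10 at oeLOF < 0.01, 15 in [0.01, 0.1),
  # 15 at >= 0.1; case excess planted only in the most constrained bin
  set.seed(61)
  co <- build_burden_cohort(61, effect = 6, n = 2000)
  co$genes$oe_lof <- c(rep(0.005, 10), rep(0.05, 15), rep(0.5, 15))
  sets <- list(lt01 = co$genes$gene_id[co$genes$oe_lof < 0.01],
               lt1 = co$genes$gene_id[co$genes$oe_lof < 0.1],
               ge1 = co$genes$gene_id[co$genes$oe_lof >= 0.1])
  ors <- vapply(sets, function(s)
    geneset_burden_logistic(co$cnvs, co$genes, s, co$samples)$odds_ratio,
    numeric(1))
  expect_gt(ors[["lt01"]], ors[["lt1"]])
  expect_gt(ors[["lt1"]], ors[["ge1"]])
  # (no near-1 assertion for the unplanted bin: conditioning on the
  # segment-count covariate pulls it below 1 when cases carry extra
  # planted segments elsewhere)
  expect_gt(ors[["lt01"]], 1.5)
})

test_that("min-p adjustment controls FWER under a global null", {
  # labels shuffled before testing; fraction of emp2 < 0.05 should be small
  set.seed(55)
  samples <- make_samples(25, 25)
  genes <- make_genes("1", (0:14) * 10000 + 1000, (0:14) * 10000 + 3000)
  cnvs <- do.call(rbind, lapply(1:15, function(g)
    make_cnvs("1", genes$start[g] - 50, genes$end[g] + 50,
              sample(samples$sample_id, 8))))
  cnvs$phenotype <- samples$phenotype[match(cnvs$sample_id,
                                            samples$sample_id)]
  rejections <- vapply(1:20, function(r) {
    shuffled <- samples
    shuffled$phenotype <- sample(shuffled$phenotype)
    oc <- gene_overlap_counts(cnvs, genes, shuffled)
    sum(permutation_gene_test(oc, n_perm = 1000, seed = r)$emp2 < 0.05)
  }, numeric(1))
  expect_lte(mean(rejections > 0), 0.05 + 3 * sqrt(0.05 * 0.95 / 20))
})
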
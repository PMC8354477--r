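#' Seeded synthetic-data generators
#'
#' Generators for every input the pipeline consumes, on a miniature genome
#' (22 autosomes, 30 Mb each by default) so a full run takes minutes. The
#' stated world: a case-control deletion cohort with study structure, a
#' trio DNV cohort drawn from per-gene mutation rates, risk genes with
#' case-only deletion enrichment and/or DNV enrichment (drawn from the
#' low-LOEUF tail), planted QC-gate violators, a three-organ developmental
#' expression time course, and a PPI edge list with planted modules.
#' Every generator is bit-reproducible under a fixed seed.
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' Defaults emulate, at desk scale, the structure of a large CHD
#' deletion/DNV meta-analysis: carrier ratios of roughly 10-30 case vs 0-2
#' control carriers at risk genes (deletion-rate multiplier 20), top-gene
#' nsDNV counts of ~5-18 in 2,489 trios (DNV multiplier 100 on large,
#' mutation-prone risk genes), ~2 background deletions per individual, and
#' risk-gene LOEUF centred near 0.3 against 0.9 for background genes.
#'
#' @param seed mandatory RNG seed.
#' @param n_cases,n_controls,n_studies cohort structure.
#' @param n_genes,n_chrom,chrom_length gene/genome geometry (bases).
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene lengths.
#' @param n_cnv_risk,n_dnv_risk,n_joint planted risk genes (joint genes are
#'   counted inside both totals).
#' @param cnv_risk_multiplier case deletion-rate multiplier at risk genes.
#' @param dnv_multiplier DNV rate multiplier at risk genes.
#' @param background_del_rate Poisson mean deletions per individual.
#' @param cnv_len_meanlog,cnv_len_sdlog log-normal deletion lengths.
#' @param min_clean_len lower truncation of background deletion lengths so
#'   clean calls always clear the size and probe gates.
#' @param probe_spacing regular probe grid spacing (bases).
#' @param n_trios trio cohort size.
#' @param mu_meanlog,mu_sdlog log-normal total per-gene mutation rates.
#' @param class_shares rate shares for PTV/missense/silent.
#' @param risk_rate_scale rate scale factor for DNV risk genes (they
#'   emulate large genes).
#' @param loeuf_risk,loeuf_null,loeuf_sdlog LOEUF log-normal medians/spread.
#' @param n_small,n_large,n_lowprobe,n_mask,n_nonauto planted QC violators.
#' @param common_frac control frequency of the planted common deletion.
#' @param expr_n_genes,expr_noise_sd,expr_n_deg,expr_n_high expression
#'   generator shape (see [simulate_expression]).
#' @param ppi_module_sizes,ppi_p_within,ppi_p_background,ppi_n_extra PPI
#'   generator shape (see [simulate_ppi]).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_cases = 500, n_controls = 1000, n_studies = 5,
                       n_genes = 400, n_chrom = 22, chrom_length = 30e6,
                       gene_length_meanlog = log(2e4),
                       gene_length_sdlog = 0.4,
                       n_cnv_risk = 10, n_dnv_risk = 10, n_joint = 3,
                       cnv_risk_multiplier = 100, dnv_multiplier = 100,
                       background_del_rate = 2,
                       cnv_len_meanlog = log(6e4), cnv_len_sdlog = 0.5,
                       min_clean_len = 25e3,
                       probe_spacing = 2e3,
                       n_trios = 2489,
                       mu_meanlog = log(1.5e-5), mu_sdlog = 0.8,
                       class_shares = c(PTV = 0.1, missense = 0.6,
                                        silent = 0.3),
                       risk_rate_scale = 3,
                       loeuf_risk = 0.3, loeuf_null = 0.9, loeuf_sdlog = 0.4,
                       n_small = 20, n_large = 10, n_lowprobe = 15,
                       n_mask = 15, n_nonauto = 10, common_frac = 0.02,
                       expr_n_genes = 200, expr_noise_sd = 0.3,
                       expr_n_deg = 20, expr_n_high = 20,
                       ppi_module_sizes = c(8, 8), ppi_p_within = 0.9,
                       ppi_p_background = 0.01, ppi_n_extra = 30) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_joint <= min(n_cnv_risk, n_dnv_risk),
            cnv_risk_multiplier >= 1, dnv_multiplier >= 1,
            background_del_rate > 0, abs(sum(class_shares) - 1) < 1e-9)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Simulate gene annotation, masks and probes
#'
#' Genes are tiled without overlap across the autosomes, avoiding the mask
#' regions (telomere analogues at chromosome ends, a centromere analogue
#' block in the middle, random segmental-duplication blocks) and a
#' designated probe desert per chromosome. Probes sit on a regular grid
#' outside the desert. LOEUF is sampled log-normally, risk genes biased
#' low; per-gene mutation rates are log-normal with fixed class shares,
#' DNV risk genes scaled up (large-gene analogues).
#'
#' @param config [sim_config].
#' @return list: `genes` (`gene_models` with truth columns `is_cnv_risk`,
#'   `is_dnv_risk`), `masks` (list of BED-like data.frames + `probes` +
#'   `desert`), `chromosomes` (lengths).
#' @export
simulate_annotation <- function(config) {
  cfg <- config
  with_seed(cfg$seed, {
    chroms <- as.character(seq_len(cfg$n_chrom))
    clen <- stats::setNames(rep(cfg$chrom_length, cfg$n_chrom), chroms)
    tel <- 5e4; cen_w <- 1e5
    telomeres <- do.call(rbind, lapply(chroms, function(ch) data.frame(
      chrom = ch, start = c(0, clen[ch] - tel), end = c(tel, clen[ch]))))
    centromeres <- do.call(rbind, lapply(chroms, function(ch) data.frame(
      chrom = ch, start = clen[ch] / 2 - cen_w / 2,
      end = clen[ch] / 2 + cen_w / 2)))
    segdups <- do.call(rbind, lapply(chroms, function(ch) {
      st <- round(stats::runif(3, 0.05, 0.45) * clen[ch])
      data.frame(chrom = ch, start = st, end = st + 5e4)
    }))
    # probe desert: a fixed 1 Mb window in the 3rd quarter of each chromosome
    desert <- do.call(rbind, lapply(chroms, function(ch) data.frame(
      chrom = ch, start = round(clen[ch] * 0.70),
      end = round(clen[ch] * 0.70) + 1e6)))
    probes <- do.call(rbind, lapply(chroms, function(ch) {
      pos <- seq(cfg$probe_spacing, clen[ch], by = cfg$probe_spacing)
      d <- desert[desert$chrom == ch, ]
      data.frame(chrom = ch, pos = pos[pos <= d$start | pos > d$end])
    }))
    # window reserved for the planted common deletion (see
    # simulate_cnv_cohort): genes and clean background calls keep clear so
    # the frequency gate removes exactly the planted carriers
    common_window <- data.frame(chrom = "1",
                                start = round(clen[["1"]] * 0.6) - 2e5,
                                end = round(clen[["1"]] * 0.6) + 3e5)
    blocked <- rbind(telomeres[, 1:3], centromeres[, 1:3], segdups[, 1:3],
                     desert[, 1:3], common_window)
    # tile genes uniformly, rejecting overlaps with masks/desert/other genes
    per_chrom <- table(factor(rep_len(chroms, cfg$n_genes), levels = chroms))
    gene_rows <- list()
    for (ch in chroms) {
      need <- per_chrom[[ch]]
      if (need == 0) next
      placed <- blocked[blocked$chrom == ch, c("start", "end")]
      got <- 0L; guard <- 0L
      while (got < need) {
        guard <- guard + 1L
        if (guard > 50000)
          stop("genome too small for n_genes", call. = FALSE)
        len <- round(stats::rlnorm(1, cfg$gene_length_meanlog,
                                   cfg$gene_length_sdlog))
        st <- round(stats::runif(1, 0, clen[ch] - len))
        if (any(pmin(placed$end, st + len) - pmax(placed$start, st) > 0))
          next
        placed <- rbind(placed, data.frame(start = st, end = st + len))
        got <- got + 1L
        gene_rows[[length(gene_rows) + 1]] <-
          data.frame(chrom = ch, start = st, end = st + len)
      }
    }
    genes <- do.call(rbind, gene_rows)
    genes <- genes[order(as.integer(genes$chrom), genes$start), ]
    genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
    # planted risk structure
    idx <- sample.int(nrow(genes), cfg$n_cnv_risk + cfg$n_dnv_risk -
                        cfg$n_joint)
    joint <- idx[seq_len(cfg$n_joint)]
    cnv_only <- idx[cfg$n_joint + seq_len(cfg$n_cnv_risk - cfg$n_joint)]
    dnv_only <- idx[cfg$n_cnv_risk + seq_len(cfg$n_dnv_risk - cfg$n_joint)]
    genes$is_cnv_risk <- seq_len(nrow(genes)) %in% c(joint, cnv_only)
    genes$is_dnv_risk <- seq_len(nrow(genes)) %in% c(joint, dnv_only)
    risk <- genes$is_cnv_risk | genes$is_dnv_risk
    genes$loeuf <- stats::rlnorm(nrow(genes),
                                 ifelse(risk, log(cfg$loeuf_risk),
                                        log(cfg$loeuf_null)),
                                 cfg$loeuf_sdlog)
    genes$oe_lof <- genes$loeuf * 0.6
    mu <- stats::rlnorm(nrow(genes), cfg$mu_meanlog, cfg$mu_sdlog)
    mu[genes$is_dnv_risk] <- mu[genes$is_dnv_risk] * cfg$risk_rate_scale
    genes$rate_ptv <- mu * cfg$class_shares[["PTV"]]
    genes$rate_missense <- mu * cfg$class_shares[["missense"]]
    genes$rate_silent <- mu * cfg$class_shares[["silent"]]
    genes <- genes[, c("gene_id", "chrom", "start", "end", "loeuf", "oe_lof",
                       "rate_ptv", "rate_missense", "rate_silent",
                       "is_cnv_risk", "is_dnv_risk")]
    rownames(genes) <- NULL
    class(genes) <- c("gene_models", "data.frame")
    list(genes = genes,
         masks = list(telomeres = telomeres, centromeres = centromeres,
                      segdups = segdups, probes = probes, desert = desert,
                      common_window = common_window),
         chromosomes = clen)
  })
}

# one clean random call avoiding masks and the probe desert
.clean_call <- function(cfg, clen, blocked_by_chrom) {
  repeat {
    ch <- sample(names(clen), 1)
    len <- max(cfg$min_clean_len,
               round(stats::rlnorm(1, cfg$cnv_len_meanlog, cfg$cnv_len_sdlog)))
    st <- round(stats::runif(1, 0, clen[ch] - len))
    bl <- blocked_by_chrom[[ch]]
    ov <- sum(pmax(0, pmin(bl$end, st + len) - pmax(bl$start, st)))
    if (ov == 0) return(data.frame(chrom = ch, start = st, end = st + len))
  }
}

#' Simulate the case-control deletion cohort
#'
#' Background deletions are uniform over the genome (Poisson count per
#' individual, clean of every QC gate by construction); cases additionally
#' receive planted deletions over the CNV risk genes so that their
#' carrier rate is `cnv_risk_multiplier` times the background per-gene
#' rate. A configurable number of calls violating each QC gate (too
#' small, too large, probe-poor, mask-covered, common, non-autosomal) is
#' planted and labelled in the truth column `planted_qc`.
#'
#' @param config [sim_config].
#' @param annotation output of [simulate_annotation].
#' @return list: `cnvs` (`cnv_calls` + truth columns), `samples` (roster:
#'   `sample_id`, `phenotype`, `subphenotype`, `study_id`).
#' @export
simulate_cnv_cohort <- function(config, annotation) {
  cfg <- config
  genes <- annotation$genes
  clen <- annotation$chromosomes
  masks <- annotation$masks
  blocked <- rbind(masks$telomeres[, c("chrom", "start", "end")],
                   masks$centromeres[, c("chrom", "start", "end")],
                   masks$segdups[, c("chrom", "start", "end")],
                   masks$desert[, c("chrom", "start", "end")])
  if (!is.null(masks$common_window))
    blocked <- rbind(blocked,
                     masks$common_window[, c("chrom", "start", "end")])
  blocked_by_chrom <- split(blocked[, c("start", "end")], blocked$chrom)
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_cases + cfg$n_controls
    samples <- data.frame(
      sample_id = sprintf("S%05d", seq_len(n)),
      phenotype = rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls)),
      study_id = paste0("study_", sample.int(cfg$n_studies, n, TRUE)),
      stringsAsFactors = FALSE)
    samples$subphenotype <- NA_character_
    is_case <- samples$phenotype == "case"
    samples$subphenotype[is_case] <- sample(
      c("CHD", "TAA", "LVOTO", "conotruncal"), sum(is_case), TRUE,
      prob = c(0.6, 0.1, 0.15, 0.15))
    rows <- list()
    add <- function(df) rows[[length(rows) + 1]] <<- df
    # background deletions
    n_bg <- stats::rpois(n, cfg$background_del_rate)
    for (i in which(n_bg > 0)) {
      for (j in seq_len(n_bg[i])) {
        cc <- .clean_call(cfg, clen, blocked_by_chrom)
        cc$sample_id <- samples$sample_id[i]
        cc$planted_qc <- "clean"; cc$is_risk <- FALSE
        add(cc)
      }
    }
    # planted risk-gene deletions in cases: carrier probability per case =
    # (multiplier - 1) * background per-gene carrier rate
    genome <- sum(clen)
    mean_len <- exp(cfg$cnv_len_meanlog + cfg$cnv_len_sdlog^2 / 2)
    risk_idx <- which(genes$is_cnv_risk)
    case_ids <- samples$sample_id[is_case]
    for (gi in risk_idx) {
      glen <- genes$end[gi] - genes$start[gi]
      p0 <- cfg$background_del_rate * (glen + mean_len) / genome
      p_extra <- min(0.5, (cfg$cnv_risk_multiplier - 1) * p0)
      hit <- case_ids[stats::runif(length(case_ids)) < p_extra]
      for (sid in hit) {
        margin <- round(stats::runif(2, 5e3, 2e4))
        add(data.frame(chrom = genes$chrom[gi],
                       start = max(0, genes$start[gi] - margin[1]),
                       end = min(clen[genes$chrom[gi]],
                                 genes$end[gi] + margin[2]),
                       sample_id = sid, planted_qc = "clean",
                       is_risk = TRUE))
      }
    }
    # planted QC violators, assigned to random individuals
    rnd_sample <- function(k) sample(samples$sample_id, k, replace = TRUE)
    if (cfg$n_small > 0) {
      ch <- sample(names(clen), cfg$n_small, TRUE)
      st <- round(stats::runif(cfg$n_small, 2e6, 5e6))
      add(data.frame(chrom = ch, start = st, end = st + 4e3,
                     sample_id = rnd_sample(cfg$n_small),
                     planted_qc = "size", is_risk = FALSE))
    }
    if (cfg$n_large > 0) {
      ch <- sample(names(clen), cfg$n_large, TRUE)
      add(data.frame(chrom = ch, start = 2e6, end = 2e6 + 22e6,
                     sample_id = rnd_sample(cfg$n_large),
                     planted_qc = "size", is_risk = FALSE))
    }
    if (cfg$n_lowprobe > 0) {
      ch <- sample(names(clen), cfg$n_lowprobe, TRUE)
      d0 <- masks$desert$start[match(ch, masks$desert$chrom)]
      st <- d0 + round(stats::runif(cfg$n_lowprobe, 1e5, 8e5))
      add(data.frame(chrom = ch, start = st, end = st + 4e4,
                     sample_id = rnd_sample(cfg$n_lowprobe),
                     planted_qc = "probes", is_risk = FALSE))
    }
    if (cfg$n_mask > 0) {
      sd_idx <- sample.int(nrow(masks$segdups), cfg$n_mask, TRUE)
      sd <- masks$segdups[sd_idx, ]
      # 40 kb call, 80% inside the 50 kb segdup block
      st <- sd$start + 2e3
      add(data.frame(chrom = sd$chrom, start = st, end = st + 4e4,
                     sample_id = rnd_sample(cfg$n_mask),
                     planted_qc = "mask", is_risk = FALSE))
    }
    if (cfg$n_nonauto > 0) {
      st <- round(stats::runif(cfg$n_nonauto, 1e6, 2e6))
      add(data.frame(chrom = "X", start = st, end = st + 5e4,
                     sample_id = rnd_sample(cfg$n_nonauto),
                     planted_qc = "non_autosomal", is_risk = FALSE))
    }
    # planted common deletion: carried by common_frac of controls (+ a few
    # cases), recurrent under reciprocal-overlap clustering
    ctrl_ids <- samples$sample_id[!is_case]
    n_common_ctrl <- ceiling(cfg$common_frac * length(ctrl_ids))
    carriers <- c(sample(ctrl_ids, n_common_ctrl),
                  sample(case_ids, max(2, round(n_common_ctrl / 10))))
    # 0.6 * chrom length sits clear of segdup placement ([0.05, 0.45]),
    # the centromere block (0.5) and the probe desert ([0.70, 0.70] + 1 Mb)
    base_st <- round(clen[["1"]] * 0.6)
    for (sid in carriers) {
      jit <- round(stats::runif(2, -2e3, 2e3))
      add(data.frame(chrom = "1", start = base_st + jit[1],
                     end = base_st + 1e5 + jit[2],
                     sample_id = sid, planted_qc = "maf", is_risk = FALSE))
    }
    cnvs <- do.call(rbind, rows)
    m <- match(cnvs$sample_id, samples$sample_id)
    cnvs <- data.frame(chrom = as.character(cnvs$chrom),
                       start = cnvs$start, end = cnvs$end, type = "DEL",
                       sample_id = cnvs$sample_id,
                       phenotype = samples$phenotype[m],
                       subphenotype = samples$subphenotype[m],
                       study_id = samples$study_id[m],
                       probe_count = NA_integer_, internal_maf = NA_real_,
                       qc_flag = "", planted_qc = cnvs$planted_qc,
                       is_risk = cnvs$is_risk, stringsAsFactors = FALSE)
    class(cnvs) <- c("cnv_calls", "data.frame")
    list(cnvs = cnvs, samples = samples)
  })
}

#' Simulate trio DNVs from the per-gene mutation rates
#'
#' Per gene and class, counts are Poisson with mean
#' `2 * n_trios * rate * multiplier` (multiplier applied at DNV risk genes
#' only); counts are expanded to records with consequence terms drawn from
#' the class vocabulary, population MAF 0, and a random split over two
#' cohorts.
#'
#' @param config [sim_config].
#' @param annotation output of [simulate_annotation].
#' @return `dnv_records` data.frame.
#' @export
simulate_trio_dnvs <- function(config, annotation) {
  cfg <- config
  genes <- annotation$genes
  vocab <- list(PTV = .ptv_terms, missense = .missense_terms,
                silent = .silent_terms)
  with_seed(cfg$seed + 2L, {
    mult <- ifelse(genes$is_dnv_risk, cfg$dnv_multiplier, 1)
    rows <- list()
    for (cls in c("PTV", "missense", "silent")) {
      rate <- genes[[paste0("rate_", c(PTV = "ptv", missense = "missense",
                                       silent = "silent")[[cls]])]]
      lam <- 2 * cfg$n_trios * rate *
        (if (cls == "silent") 1 else mult)   # enrichment is non-synonymous
      k <- stats::rpois(length(lam), lam)
      gi <- rep(seq_along(k), k)
      if (!length(gi)) next
      rows[[cls]] <- data.frame(
        gene_id = genes$gene_id[gi],
        consequence_term = sample(vocab[[cls]], length(gi), TRUE),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    out <- data.frame(
      sample_id = sprintf("T%05d", sample.int(cfg$n_trios, nrow(out), TRUE)),
      gene_id = out$gene_id, consequence_term = out$consequence_term,
      severity = NA_real_, population_maf = 0,
      cohort_id = sample(c("cohort_A", "cohort_B"), nrow(out), TRUE),
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("dnv_records", "data.frame")
    out
  })
}

#' Simulate the three-organ developmental expression time course
#'
#' Heart, kidney and liver are sampled at 4-20 wpc plus newborn, infant
#' and adult time points (2-3 replicates each). Baselines are shared
#' across organs; planted heart DEGs rise with developmental time in the
#' heart only; planted "high-in-heart" genes carry a constant heart
#' offset. Values are log-normal noise around the templates; the CPM and
#' RPKM matrices share the signal structure.
#'
#' @param config [sim_config].
#' @param gene_ids optional gene ids (defaults to the first
#'   `expr_n_genes` ids `G0001..`).
#' @return list: `cpm`, `rpkm` (genes x samples), `meta` (`sample`,
#'   `organ`, `days`, `replicate`), `truth` (`is_deg`, `is_high`).
#' @export
simulate_expression <- function(config, gene_ids = NULL) {
  cfg <- config
  if (is.null(gene_ids))
    gene_ids <- sprintf("G%04d", seq_len(cfg$expr_n_genes))
  ng <- length(gene_ids)
  with_seed(cfg$seed + 3L, {
    wpc_days <- c(4, 5, 6, 7, 8, 9, 12, 16, 20) * 7
    days <- c(wpc_days, 280, 500, 10000)
    organs <- c("heart", "kidney", "liver")
    reps <- 3L
    meta <- expand.grid(replicate = seq_len(reps), days = days,
                        organ = organs, stringsAsFactors = FALSE)
    meta$sample <- sprintf("%s_d%05d_r%d", meta$organ, meta$days,
                           meta$replicate)
    is_deg <- seq_len(ng) <= cfg$expr_n_deg
    is_high <- seq_len(ng) > cfg$expr_n_deg &
      seq_len(ng) <= cfg$expr_n_deg + cfg$expr_n_high
    base <- stats::rnorm(ng, 3, 1.5)
    tscale <- (log10(meta$days) - log10(28)) / (log10(10000) - log10(28))
    mu <- matrix(rep(base, each = nrow(meta)), nrow = nrow(meta))
    heart <- meta$organ == "heart"
    # planted trajectories
    mu[, is_deg] <- mu[, is_deg] + outer(ifelse(heart, 4, 0) * tscale,
                                         rep(1, sum(is_deg)))
    mu[, is_high] <- mu[, is_high] + ifelse(heart, 4, 0)
    noise <- matrix(stats::rnorm(nrow(meta) * ng, 0, cfg$expr_noise_sd),
                    nrow(meta), ng)
    logv <- mu + noise
    cpm <- t(2^logv - 1); cpm[cpm < 0] <- 0
    rpkm <- t(2^(logv + matrix(stats::rnorm(nrow(meta) * ng, 0, 0.1),
                               nrow(meta), ng)) - 1)
    rpkm[rpkm < 0] <- 0
    rownames(cpm) <- rownames(rpkm) <- gene_ids
    colnames(cpm) <- colnames(rpkm) <- meta$sample
    list(cpm = cpm, rpkm = rpkm,
         meta = meta[, c("sample", "organ", "days", "replicate")],
         truth = data.frame(gene_id = gene_ids, is_deg = is_deg,
                            is_high = is_high, stringsAsFactors = FALSE))
  })
}

#' Simulate a PPI edge list with planted modules
#'
#' Nodes are the supplied genes; planted modules (disjoint, drawn from the
#' head of the node list unless given) are densely wired at
#' `ppi_p_within`; all remaining pairs connect at `ppi_p_background`.
#' Edges are emitted deduplicated and symmetric.
#'
#' @param config [sim_config].
#' @param nodes character vector of gene ids; defaults to
#'   `sum(ppi_module_sizes) + ppi_n_extra` synthetic ids.
#' @param modules optional list of character vectors overriding the
#'   planted module memberships.
#' @return list: `edges` (two-column data.frame), `modules`.
#' @export
simulate_ppi <- function(config, nodes = NULL, modules = NULL) {
  cfg <- config
  if (is.null(nodes))
    nodes <- sprintf("P%03d", seq_len(sum(cfg$ppi_module_sizes) +
                                        cfg$ppi_n_extra))
  if (is.null(modules)) {
    off <- 0L
    modules <- lapply(cfg$ppi_module_sizes, function(k) {
      m <- nodes[off + seq_len(k)]; off <<- off + k; m
    })
  }
  with_seed(cfg$seed + 4L, {
    pairs <- t(utils::combn(nodes, 2))
    in_module <- rep(FALSE, nrow(pairs))
    for (m in modules)
      in_module <- in_module | (pairs[, 1] %in% m & pairs[, 2] %in% m)
    p <- ifelse(in_module, cfg$ppi_p_within, cfg$ppi_p_background)
    keep <- stats::runif(nrow(pairs)) < p
    list(edges = data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                            stringsAsFactors = FALSE),
         modules = modules)
  })
}
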
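#' Developmental-stage expression ranking and time-course DE
#'
#' Expression evidence enters in two forms: (i) per-gene mean expression
#' (RPKM) averaged within three stages of heart development -- early
#' development (4-8 wpc), maturation (9-20 wpc) and infant/adult (newborn
#' onward) -- with percentile ranks across genes within stage; and (ii)
#' time-course differential expression of heart versus a comparator organ
#' (kidney or liver) from CPM, fitting a degree-2 polynomial of days
#' post-conception with organ main and interaction terms, calling a gene
#' DE when the full-model R-squared exceeds 0.50 and the Bonferroni
#' corrected F-test p-value of the organ-dependent terms is below 0.01.
#'
#' @name expression-stage
NULL

#' Map days post-conception to a development stage
#'
#' Boundaries (inclusive, 7 days/week): early = 4-8 wpc (28-62 dpc),
#' maturation = 9-20 wpc (63-140 dpc), infant/adult = after 20 wpc.
#' @param days numeric vector of days post-conception.
#' @return character vector in
#'   `{"early_development","maturation","infant_adult"}`.
#' @export
stage_of_days <- function(days) {
  ifelse(days <= 62, "early_development",
         ifelse(days <= 140, "maturation", "infant_adult"))
}

#' Stage means and percentile ranks of heart expression
#'
#' Arithmetic mean per gene within each stage, then the percentile rank of
#' those means across all genes within the stage (average ranks on ties,
#' scaled to (0, 1]); the top-quartile flag marks rank >= 0.75.
#'
#' @param expr genes x samples matrix (RPKM), rownames = gene ids.
#' @param meta data.frame with one row per column of `expr`: `organ`,
#'   `days`.
#' @param organ organ to summarize (default "heart").
#' @return data.frame: `gene_id`, per-stage `mean_*` and `rank_*` columns,
#'   `top_quartile` (in both early and maturation stages).
#' @export
stage_means_and_ranks <- function(expr, meta, organ = "heart") {
  stopifnot(ncol(expr) == nrow(meta))
  sel <- meta$organ == organ
  stage <- stage_of_days(meta$days[sel])
  stages <- c("early_development", "maturation", "infant_adult")
  if (!all(stages %in% stage))
    stop("stage with zero samples: ",
         paste(setdiff(stages, stage), collapse = ", "), call. = FALSE)
  sub <- expr[, sel, drop = FALSE]
  out <- data.frame(gene_id = rownames(expr), stringsAsFactors = FALSE)
  for (s in stages) {
    mu <- rowMeans(sub[, stage == s, drop = FALSE])
    out[[paste0("mean_", s)]] <- mu
    out[[paste0("rank_", s)]] <- rank(mu, ties.method = "average") / nrow(expr)
  }
  out$top_quartile <- out$rank_early_development >= 0.75 &
    out$rank_maturation >= 0.75
  out
}

#' Time-course differential expression, heart vs a comparator organ
#'
#' Genes below the abundance gate (CPM > `min_cpm` in fewer than
#' `min_samples` samples) are excluded; time points with fewer than two
#' replicates within an organ are dropped. For the remaining genes,
#' `log2(CPM + 1)` is regressed on a shared design: degree-`degree`
#' polynomial of days post-conception, organ indicator, and organ-by-time
#' interactions. The reported p-value is the F-test of the organ-dependent
#' terms (Bonferroni corrected over tested genes); R-squared is the fit of
#' the full model. DE requires both `r2 > r2_threshold` and corrected
#' `p < alpha`.
#'
#' @param expr genes x samples CPM matrix.
#' @param meta data.frame: `organ`, `days` per sample.
#' @param comparator the non-heart organ to contrast against.
#' @param r2_threshold,alpha decision thresholds (defaults 0.50, 0.01).
#' @param min_cpm,min_samples abundance gate (defaults 0.5, 5).
#' @param degree polynomial degree of the time trend (default 2).
#' @return data.frame: `gene_id`, `r2`, `p`, `p_bonferroni`, `deg`
#'   (NA rows = excluded by the abundance gate).
#' @export
timecourse_de <- function(expr, meta, comparator = "liver",
                          r2_threshold = 0.50, alpha = 0.01,
                          min_cpm = 0.5, min_samples = 5, degree = 2) {
  stopifnot(ncol(expr) == nrow(meta))
  sel <- meta$organ %in% c("heart", comparator)
  sub <- expr[, sel, drop = FALSE]
  m <- meta[sel, , drop = FALSE]
  # drop organ/time groups without biological replication
  grp <- interaction(m$organ, m$days, drop = TRUE)
  keep_grp <- names(which(table(grp) >= 2))
  keep <- as.character(grp) %in% keep_grp
  sub <- sub[, keep, drop = FALSE]; m <- m[keep, , drop = FALSE]
  if (length(unique(m$days)) < 2)
    stop("fewer than 2 usable time points", call. = FALSE)
  tested <- rowSums(sub > min_cpm) >= min_samples
  y <- t(log2(sub[tested, , drop = FALSE] + 1))
  tt <- scale(stats::poly(m$days, degree))
  is_heart <- as.numeric(m$organ == "heart")
  x_full <- cbind(1, tt, is_heart, tt * is_heart)
  x_red <- cbind(1, tt)
  q_full <- qr(x_full); q_red <- qr(x_red)
  rss_full <- colSums(qr.resid(q_full, y)^2)
  rss_red <- colSums(qr.resid(q_red, y)^2)
  tss <- colSums(scale(y, scale = FALSE)^2)
  df1 <- q_full$rank - q_red$rank
  df2 <- nrow(y) - q_full$rank
  fstat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  p[rss_full <= .Machine$double.eps * tss] <- 0   # perfect fits
  r2 <- 1 - rss_full / tss
  r2[tss == 0] <- 0; p[tss == 0] <- 1             # flat genes
  out <- data.frame(gene_id = rownames(expr), r2 = NA_real_, p = NA_real_,
                    p_bonferroni = NA_real_, deg = NA,
                    stringsAsFactors = FALSE)
  out$r2[tested] <- r2
  out$p[tested] <- p
  out$p_bonferroni[tested] <- pmin(1, p * sum(tested))
  out$deg[tested] <- r2 > r2_threshold & out$p_bonferroni[tested] < alpha
  out
}

#' Two-sided Wilcoxon contrasts of binned values against all genes
#'
#' For each bin (e.g. genes grouped by meta-analysis p-value cut-offs),
#' compares the bin's values against the reference distribution of all
#' genes with a two-sided rank-sum test, and attaches the conventional
#' star coding.
#'
#' @param values numeric vector (e.g. LOEUF or log mean expression).
#' @param bins factor/character vector assigning each value to a bin.
#' @param reference values of the reference group (default: all `values`).
#' @return data.frame: `bin`, `n`, `p`, `stars`.
#' @export
binned_distribution_contrast <- function(values, bins, reference = values) {
  ub <- unique(as.character(bins[!is.na(bins)]))
  rows <- lapply(ub, function(b) {
    v <- values[!is.na(bins) & bins == b]
    if (length(v) < 2) {
      warning("bin '", b, "' has fewer than 2 members", call. = FALSE)
      return(data.frame(bin = b, n = length(v), p = NA_real_, stars = "ns",
                        stringsAsFactors = FALSE))
    }
    p <- stats::wilcox.test(v, reference, exact = FALSE)$p.value
    data.frame(bin = b, n = length(v), p = p, stars = p_stars(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Star coding for p-values
#' @param p numeric vector.
#' @return `"****"` below 1e-4, `"***"` below 1e-3, `"**"` below 0.01,
#'   `"*"` below 0.05, otherwise `"ns"`.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p < 1e-4, "****",
                ifelse(p < 1e-3, "***",
                       ifelse(p < 0.01, "**",
                              ifelse(p < 0.05, "*", "ns")))))
}
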
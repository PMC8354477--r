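#' Combining the CNV and DNV evidence streams
#'
#' Per gene, the CNV permutation p-value and the DNV recurrence p-value are
#' combined with Fisher's method (chi-square with 2k = 4 degrees of
#' freedom). Multiple-testing control is then applied two ways: a
#' Benjamini-Hochberg FDR (used to pick network seeds) and a
#' covariate-weighted Bonferroni in the spirit of independent hypothesis
#' weighting, with the LOEUF intolerance metric as the informative
#' covariate.
#'
#' @name integration
NULL

#' Fisher combination of two p-values
#'
#' `X = -2 (ln p1 + ln p2)` referred to the upper tail of a chi-square
#' distribution with 4 degrees of freedom. Zero inputs are clamped to the
#' smallest positive double with a warning (permutation p-values have a
#' positive floor anyway); values outside (0, 1] are an error.
#'
#' @param p_cnv,p_dnv numeric vectors of p-values (recycled).
#' @return vector of combined p-values.
#' @export
#' @examples
#' fisher_combine(6.80e-3, 2.84e-26)  # 1.25e-26
fisher_combine <- function(p_cnv, p_dnv) {
  for (p in list(p_cnv, p_dnv))
    if (any(is.na(p) | p < 0 | p > 1))
      stop("p-values must lie in (0, 1]", call. = FALSE)
  if (any(p_cnv == 0) || any(p_dnv == 0)) {
    warning("p-value of 0 clamped to smallest positive double", call. = FALSE)
    p_cnv <- pmax(p_cnv, .Machine$double.xmin)
    p_dnv <- pmax(p_dnv, .Machine$double.xmin)
  }
  stats::pchisq(-2 * (log(p_cnv) + log(p_dnv)), df = 4, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (monotone, capped at 1); thin wrapper kept
#' as the module surface for seed selection at q < 0.05.
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Configuration for the covariate-weighted Bonferroni correction
#'
#' @param n_bins number of covariate quantile bins (>= 2).
#' @param n_folds number of cross-validation folds (>= 2).
#' @param alpha rejection level the weights are tuned for.
#' @param seed RNG seed for the fold assignment.
#' @param grid_step step of the budget-allocation grid over the simplex.
#' @return list of class `ihw_config`.
#' @export
ihw_config <- function(n_bins = 5, n_folds = 5, alpha = 0.05, seed = 1,
                       grid_step = 0.2) {
  stopifnot(n_bins >= 2, n_folds >= 2, alpha > 0, alpha < 1)
  structure(list(n_bins = n_bins, n_folds = n_folds, alpha = alpha,
                 seed = seed, grid_step = grid_step), class = "ihw_config")
}

# all compositions of `total` into `k` parts (grid over the simplex)
.compositions <- function(total, k) {
  if (k == 1) return(matrix(total, ncol = 1))
  out <- list()
  for (i in 0:total) {
    sub <- .compositions(total - i, k - 1)
    out[[length(out) + 1]] <- cbind(i, sub)
  }
  do.call(rbind, out)
}

#' Covariate-weighted Bonferroni correction (simplified IHW)
#'
#' Hypotheses are binned by covariate quantiles; each cross-validation fold
#' receives bin weights learned on the complementary folds by maximizing
#' the number of rejections at level `alpha` over a grid of budget
#' allocations, subject to the weight budget `sum_b m_b w_b = m` (so the
#' procedure can only reallocate, never spend more than plain Bonferroni).
#' A gene's corrected p-value is `min(1, m * p / w_bin)` using the weights
#' of the fold that held it out, which preserves family-wise error control.
#' A constant covariate falls back to uniform weights (= plain Bonferroni)
#' with a warning.
#'
#' @param p p-values.
#' @param covariate one value per p (lower = more promising by convention;
#'   the direction is learned, not assumed).
#' @param config [ihw_config].
#' @return list: `p_ihw` (vector), `weights` (n_folds x n_bins matrix),
#'   `bins`, `folds`.
#' @export
ihw_bonferroni <- function(p, covariate, config = ihw_config()) {
  m <- length(p)
  stopifnot(length(covariate) == m)
  if (any(is.na(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  nb <- config$n_bins
  if (length(unique(covariate)) < nb) {
    warning("covariate has too few distinct values; using uniform weights",
            call. = FALSE)
    return(list(p_ihw = pmin(1, m * p),
                weights = matrix(1, config$n_folds, nb),
                bins = rep(1L, m), folds = rep(1L, m)))
  }
  bins <- as.integer(cut(rank(covariate, ties.method = "first"),
                         breaks = nb, labels = FALSE))
  m_b <- tabulate(bins, nb)
  folds <- with_seed(config$seed,
                     sample(rep_len(seq_len(config$n_folds), m)))
  steps <- round(1 / config$grid_step)
  alloc <- .compositions(steps, nb) / steps       # rows sum to 1
  # include the uniform-weight allocation (w_b = 1) as a candidate, first,
  # so ties favour plain Bonferroni
  alloc <- rbind(m_b / m, alloc)
  W <- matrix(1, config$n_folds, nb)
  thresholds <- config$alpha * t(alloc) / m_b     # nb x n_alloc, = alpha*w/m
  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    sorted_p <- lapply(seq_len(nb), function(b) sort(p[tr & bins == b]))
    rej <- rowSums(vapply(seq_len(nb), function(b)
      findInterval(thresholds[b, ], sorted_p[[b]]), numeric(nrow(alloc))))
    W[f, ] <- alloc[which.max(rej), ] * m / m_b   # sum_b m_b w_b = m exactly
  }
  w_gene <- W[cbind(folds, bins)]
  p_ihw <- ifelse(w_gene > 0, pmin(1, m * p / w_gene), 1)
  list(p_ihw = p_ihw, weights = W, bins = bins, folds = folds)
}

#' Assemble the per-gene evidence table
#'
#' Joins the CNV permutation results and the DNV recurrence results over a
#' gene universe. A gene missing from one side carries p = 1 on that side.
#' The `significant` label records which single-stream test(s) called the
#' gene (`dnv`, `cnv`, `both`, `none`); combined significance is read off
#' `p_ihw` (or `q_bh`).
#'
#' @param cnv `permutation_result` data.frame (or NULL).
#' @param dnv data.frame with `gene_id`, `n_nsdnv`, `p_dnv`,
#'   `p_bonferroni` (or NULL).
#' @param universe character vector of gene ids (no duplicates).
#' @param loeuf numeric vector aligned with `universe` (for IHW).
#' @param alpha per-stream significance level (default 0.05).
#' @param ihw [ihw_config], or NULL to skip the weighted correction.
#' @return data.frame of class `gene_results` with Table-1-style columns:
#'   gene, case/control carriers, `p_cnv_emp1`, `p_cnv_emp2`, `n_nsdnv`,
#'   `p_dnv`, `significant`, `meta_p`, `q_bh`, `p_ihw`, `loeuf`.
#' @export
assemble_results <- function(cnv, dnv, universe, loeuf = NULL, alpha = 0.05,
                             ihw = ihw_config()) {
  if (anyDuplicated(universe)) stop("duplicate gene ids", call. = FALSE)
  mcnv <- if (!is.null(cnv)) match(universe, cnv$target) else
    rep(NA_integer_, length(universe))
  mdnv <- if (!is.null(dnv)) match(universe, dnv$gene_id) else
    rep(NA_integer_, length(universe))
  p_cnv1 <- ifelse(is.na(mcnv), 1, cnv$emp1[mcnv])
  p_cnv2 <- ifelse(is.na(mcnv), 1, cnv$emp2[mcnv])
  p_dnv <- ifelse(is.na(mdnv), 1, dnv$p_dnv[mdnv])
  p_dnv_bonf <- ifelse(is.na(mdnv), 1, dnv$p_bonferroni[mdnv])
  sig_cnv <- p_cnv2 < alpha
  sig_dnv <- p_dnv_bonf < alpha
  lab <- ifelse(sig_cnv & sig_dnv, "both",
                ifelse(sig_cnv, "cnv", ifelse(sig_dnv, "dnv", "none")))
  meta <- fisher_combine(p_cnv1, p_dnv)
  out <- data.frame(
    gene_id = universe,
    n_case_cnv = ifelse(is.na(mcnv), 0L, cnv$case_carriers[mcnv]),
    n_control_cnv = ifelse(is.na(mcnv), 0L, cnv$control_carriers[mcnv]),
    p_cnv_emp1 = p_cnv1, p_cnv_emp2 = p_cnv2,
    n_nsdnv = ifelse(is.na(mdnv), 0L, dnv$n_nsdnv[mdnv]),
    p_dnv = p_dnv, significant = lab,
    meta_p = meta, q_bh = bh_adjust(meta),
    stringsAsFactors = FALSE)
  if (!is.null(loeuf) && !is.null(ihw)) {
    lo <- loeuf
    lo[is.na(lo)] <- stats::median(lo, na.rm = TRUE)
    out$p_ihw <- ihw_bonferroni(meta, lo, ihw)$p_ihw
    out$loeuf <- loeuf
  } else {
    out$p_ihw <- pmin(1, length(meta) * meta)
    out$loeuf <- if (is.null(loeuf)) NA_real_ else loeuf
  }
  class(out) <- c("gene_results", "data.frame")
  out
}
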
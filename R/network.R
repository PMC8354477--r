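#' Seed-restricted PPI network and sub-cluster enrichment
#'
#' The network is strictly seeded: only interactions between seed genes
#' (those with BH-adjusted combined p < 0.05) are retained, no neighbour
#' expansion. Overlapping sub-clusters come from k-clique percolation
#' (default k = 3); cluster significance is assessed against
#' degree-preserving rewirings of the seed network, clusters need at least
#' 5 members and permutation p < 0.05. Each cluster is then contrasted for
#' case vs control deletion load (rank-sum) and tested for gene-set
#' over-representation (hypergeometric, with an Enrichr-style combined
#' score |ln p| * z).
#'
#' @name network-stage
NULL

#' Build the seed-restricted interaction network
#'
#' @param seeds character vector of seed gene ids (non-empty).
#' @param edges data.frame with two columns of gene ids (extra columns
#'   ignored). Duplicate and reversed edges are merged; self-loops dropped;
#'   isolated seeds are kept as nodes.
#' @return an igraph graph whose vertices are exactly the seeds.
#' @export
build_seed_network <- function(seeds, edges) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) stop("empty seed list", call. = FALSE)
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  keep <- a %in% seeds & b %in% seeds & a != b
  pair <- if (any(keep))
    unique(t(apply(cbind(a[keep], b[keep]), 1, sort)))
  else matrix(character(0), ncol = 2)
  g <- igraph::make_empty_graph(n = length(seeds), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = sort(seeds))
  if (nrow(pair))
    g <- igraph::add_edges(g, as.vector(t(matrix(
      match(pair, igraph::V(g)$name), ncol = 2))))
  igraph::simplify(g)
}

# k-clique percolation: communities = unions of maximal cliques (>= k)
# chained by (k-1)-node overlaps
.k_clique_communities <- function(g, k = 3) {
  cl <- igraph::max_cliques(g, min = k)
  if (!length(cl)) return(list())
  sets <- lapply(cl, function(x) sort(as.integer(x)))
  nc <- length(sets)
  adj <- igraph::make_empty_graph(n = nc, directed = FALSE)
  if (nc > 1) {
    ed <- list()
    for (i in seq_len(nc - 1)) for (j in (i + 1):nc)
      if (length(intersect(sets[[i]], sets[[j]])) >= k - 1)
        ed[[length(ed) + 1]] <- c(i, j)
    if (length(ed)) adj <- igraph::add_edges(adj, unlist(ed))
  }
  memb <- igraph::components(adj)$membership
  lapply(split(seq_len(nc), memb), function(idx)
    sort(unique(unlist(sets[idx]))))
}

#' Overlapping sub-cluster detection with permutation significance
#'
#' Communities from k-clique percolation; for each community, significance
#' is the fraction of degree-preserving rewired networks whose best
#' same-size community has at least the observed number of internal edges
#' (`(1 + hits) / (1 + n_perm)`). Communities with fewer than
#' `min_members` members or p >= `p_threshold` are dropped.
#'
#' @param g igraph graph (from [build_seed_network]).
#' @param n_perm number of rewired networks (>= 100).
#' @param seed RNG seed.
#' @param k clique size for percolation (default 3).
#' @param min_members minimum cluster size (default 5).
#' @param p_threshold permutation significance gate (default 0.05).
#' @return list of clusters, each a list with `members` (gene ids),
#'   `n_edges` (internal edge count), `p_perm`.
#' @export
cluster_network <- function(g, n_perm = 1000, seed = NULL, k = 3,
                            min_members = 5, p_threshold = 0.05) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  comms <- .k_clique_communities(g, k)
  comms <- comms[lengths(comms) >= min_members]
  if (!length(comms)) return(list())
  obs_edges <- vapply(comms, function(v)
    igraph::ecount(igraph::induced_subgraph(g, v)), numeric(1))
  sizes <- lengths(comms)
  hits <- integer(length(comms))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(
        niter = max(100, 10 * igraph::ecount(g))))
      rc <- .k_clique_communities(gr, k)
      if (!length(rc)) next
      rs <- lengths(rc)
      re <- vapply(rc, function(v)
        igraph::ecount(igraph::induced_subgraph(gr, v)), numeric(1))
      for (i in seq_along(comms)) {
        same <- rs == sizes[i]
        if (any(same) && max(re[same]) >= obs_edges[i])
          hits[i] <- hits[i] + 1L
      }
    }
  })
  p <- (1 + hits) / (1 + n_perm)
  keep <- p < p_threshold
  mapply(function(v, e, pp) list(members = igraph::V(g)$name[v],
                                 n_edges = e, p_perm = pp),
         comms[keep], obs_edges[keep], p[keep], SIMPLIFY = FALSE)
}

#' Case vs control deletion load within a cluster
#'
#' Two-sided Wilcoxon rank-sum comparing the member genes' case-carrier
#' counts against their control-carrier counts.
#'
#' @param cluster a cluster from [cluster_network] (or a character vector
#'   of member genes).
#' @param gene_counts data.frame with `target` (gene), `case_carriers`,
#'   `control_carriers` (from the CNV association stage).
#' @param min_members size gate (default 5).
#' @return list: `p`, `n_members`, `case_total`, `control_total`.
#' @export
cluster_cnv_contrast <- function(cluster, gene_counts, min_members = 5) {
  members <- if (is.list(cluster)) cluster$members else cluster
  if (length(members) < min_members)
    stop("cluster below the minimum size gate", call. = FALSE)
  m <- match(members, gene_counts$target)
  cs <- gene_counts$case_carriers[m]; ct <- gene_counts$control_carriers[m]
  cs[is.na(cs)] <- 0L; ct[is.na(ct)] <- 0L
  if (all(cs == ct)) {
    if (all(cs == 0)) warning("all-zero carrier counts; p = 1", call. = FALSE)
    p <- 1
  } else {
    p <- stats::wilcox.test(cs, ct, exact = FALSE)$p.value
  }
  list(p = p, n_members = length(members),
       case_total = sum(cs), control_total = sum(ct))
}

#' Hypergeometric gene-set over-representation with combined score
#'
#' For each set, p is the hypergeometric upper tail of the overlap between
#' the cluster and the set within the universe; z standardizes the overlap
#' under the same hypergeometric null; the combined score is |ln p| * z
#' (Enrichr-style product form). BH tiers over the tested sets give the
#' display bands (FDR < 5%, 5-10%, > 10%).
#'
#' @param cluster_genes character vector.
#' @param gene_sets named list of character vectors (e.g. from
#'   [load_gene_sets]).
#' @param universe character vector of all network-tested genes.
#' @return data.frame: `set`, `overlap`, `expected`, `p`, `z`,
#'   `combined_score`, `fdr`, `tier`.
#' @export
overrepresentation <- function(cluster_genes, gene_sets, universe) {
  universe <- unique(universe)
  cl <- intersect(unique(cluster_genes), universe)
  n_u <- length(universe); n_c <- length(cl)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    if (length(s) == 0) {
      warning("gene set '", nm, "' disjoint from universe; skipped",
              call. = FALSE)
      return(NULL)
    }
    k <- length(intersect(cl, s)); K <- length(s)
    p <- stats::phyper(k - 1, K, n_u - K, n_c, lower.tail = FALSE)
    expd <- n_c * K / n_u
    sdv <- sqrt(n_c * (K / n_u) * (1 - K / n_u) * (n_u - n_c) / (n_u - 1))
    z <- if (sdv > 0) (k - expd) / sdv else 0
    data.frame(set = nm, overlap = k, expected = expd, p = p, z = z,
               combined_score = abs(log(p)) * z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) return(out)
  out$fdr <- bh_adjust(out$p)
  out$tier <- ifelse(out$fdr < 0.05, "FDR<5%",
                     ifelse(out$fdr < 0.10, "FDR 5-10%", "FDR>10%"))
  out[order(out$p), , drop = FALSE]
}
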
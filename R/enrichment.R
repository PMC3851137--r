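# Functional-coherence validation of CAGCs: per-cluster enrichment,
# functional indices, node-label-permuted null networks, and the
# distribution comparison between real and permuted networks.

#' One-sided over-representation test of a gene set in a cluster
#'
#' Hypergeometric upper-tail probability `P(X >= overlap)` of observing at
#' least the attained overlap between the cluster and the annotation set
#' when drawing `|cluster|` genes from the universe. The annotation set is
#' intersected with the universe before testing, as is the cluster.
#'
#' @param cluster_genes character vector of cluster member genes.
#' @param annot_genes character vector of annotated genes.
#' @param universe background gene set (the sampling frame; by convention
#'   the merged-network gene set).
#' @return list with `p_value`, `overlap`, `overlap_genes`, `cluster_size`,
#'   `set_size`, `universe_size`.
#' @export
fisher_enrichment <- function(cluster_genes, annot_genes, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  cl <- intersect(unique(as.character(cluster_genes)), universe)
  ann <- intersect(unique(as.character(annot_genes)), universe)
  ov <- intersect(cl, ann)
  p <- stats::phyper(length(ov) - 1, length(ann),
                     length(universe) - length(ann), length(cl),
                     lower.tail = FALSE)
  list(p_value = p, overlap = length(ov), overlap_genes = sort(ov),
       cluster_size = length(cl), set_size = length(ann),
       universe_size = length(universe))
}

#' Enrichment of every set in every cluster
#'
#' Vectorized over the (cluster, set) grid through 0/1 incidence matrices;
#' used by [functional_indices()] and [centre_keyword_concordance()].
#'
#' @param clusters list of [cagc] objects.
#' @param sets a [gene_set_collection].
#' @param universe background gene set.
#' @return data frame with one row per (cluster, set): columns `centre`,
#'   `set_id`, `p_value`, `overlap`, `cluster_size`, `set_size`,
#'   `universe_size`.
#' @export
enrich_clusters <- function(clusters, sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  pm <- enrichment_pvalue_matrix(clusters, sets$sets, universe)
  nr <- nrow(pm$p)
  ns <- ncol(pm$p)
  data.frame(
    centre = rep(vapply(clusters, `[[`, character(1), "centre"), ns),
    set_id = rep(names(sets$sets), each = nr),
    p_value = as.vector(pm$p),
    overlap = as.vector(pm$overlap),
    cluster_size = rep(pm$cluster_size, ns),
    set_size = rep(pm$set_size, each = nr),
    universe_size = length(universe),
    stringsAsFactors = FALSE)
}

# Internal: matrices of overlaps and hypergeometric upper-tail p-values for
# clusters x sets, restricted to the universe.
enrichment_pvalue_matrix <- function(clusters, set_list, universe) {
  n_univ <- length(universe)
  cm <- vapply(clusters, function(cl) universe %in% cl$members,
               logical(n_univ))
  sm <- vapply(set_list, function(s) universe %in% s, logical(n_univ))
  cm <- matrix(cm, nrow = n_univ)
  sm <- matrix(sm, nrow = n_univ)
  ov <- crossprod(cm * 1, sm * 1)
  csz <- colSums(cm)
  ssz <- colSums(sm)
  K <- matrix(ssz, nrow(ov), ncol(ov), byrow = TRUE)
  n <- matrix(csz, nrow(ov), ncol(ov))
  p <- stats::phyper(ov - 1, K, n_univ - K, n, lower.tail = FALSE)
  list(p = p, overlap = ov, cluster_size = csz, set_size = ssz)
}

#' Functional index of one cluster
#'
#' The functional index of a cluster is the p-value of its most
#' significantly enriched set; small indices indicate functional coherence.
#'
#' @param cluster a [cagc].
#' @param sets a [gene_set_collection].
#' @param universe background gene set.
#' @return the minimum enrichment p-value; attribute `best_sets` holds the
#'   argmin set ID(s). If no set overlaps the universe the index is 1 with
#'   a warning.
#' @export
functional_index <- function(cluster, sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(sets$sets)) stop("no sets to test")
  if (!any(unlist(sets$sets) %in% universe)) {
    warning("no annotation set overlaps the universe; index = 1")
    return(structure(1, best_sets = character(0)))
  }
  pm <- enrichment_pvalue_matrix(list(cluster), sets$sets, universe)
  p <- pm$p[1, ]
  structure(min(p), best_sets = names(sets$sets)[p == min(p)])
}

#' Functional index of every cluster
#'
#' @inheritParams functional_index
#' @param clusters list of [cagc] objects.
#' @return named numeric vector of per-cluster minimum enrichment p-values.
#' @export
functional_indices <- function(clusters, sets, universe) {
  universe <- unique(as.character(universe))
  pm <- enrichment_pvalue_matrix(clusters, sets$sets, universe)
  stats::setNames(apply(pm$p, 1, min),
                  vapply(clusters, `[[`, character(1), "centre"))
}

#' Node-label-permuted null network
#'
#' Relabels the nodes by a uniform random permutation under `seed`. The
#' topology (edge count, degree sequence) is preserved exactly; only which
#' gene carries which degree changes, which is the null model for
#' functional-coherence validation.
#'
#' @param net an [anticoex_network].
#' @param seed integer seed; the same seed always yields the same
#'   permutation.
#' @return permuted [anticoex_network].
#' @export
permuted_network <- function(net, seed) {
  stopifnot(inherits(net, "anticoex_network"))
  perm <- with_seed(seed, sample(net$nodes))
  relabel <- stats::setNames(perm, net$nodes)
  e <- net$edges
  if (nrow(e)) e <- cbind(relabel[e[, 1]], relabel[e[, 2]])
  anticoex_network(e, level = net$level, species_scope = net$species_scope,
                   provenance = net$provenance, id_space = net$id_space,
                   nodes = perm)
}

#' Compare real and permuted functional-index distributions
#'
#' Two-sample Kolmogorov-Smirnov test of the real per-cluster indices
#' against the pooled permuted indices, plus a per-replicate empirical-CDF
#' band (mean and standard deviation across permutation replicates at each
#' index threshold) mirroring the usual cumulative-distribution display.
#'
#' @param real_indices numeric vector of per-cluster indices from the real
#'   network.
#' @param permuted_indices list of numeric vectors, one per permutation
#'   replicate.
#' @return list with `statistic`, `p_value`, `n_real`, `n_permuted`,
#'   `replicate_means`, and `band` (data frame: `threshold`, `cdf_real`,
#'   `cdf_perm_mean`, `cdf_perm_sd`).
#' @export
index_distribution_test <- function(real_indices, permuted_indices) {
  if (!length(real_indices)) stop("no real indices")
  if (!length(permuted_indices) || !all(lengths(permuted_indices) > 0))
    stop("need at least one non-empty permutation replicate")
  pooled <- unlist(permuted_indices, use.names = FALSE)
  ks <- suppressWarnings(stats::ks.test(real_indices, pooled))
  grid <- sort(unique(c(real_indices, pooled)))
  cdf_real <- stats::ecdf(real_indices)(grid)
  rep_cdf <- vapply(permuted_indices,
                    function(x) stats::ecdf(x)(grid),
                    numeric(length(grid)))
  rep_cdf <- matrix(rep_cdf, nrow = length(grid))
  band <- data.frame(threshold = grid,
                     cdf_real = cdf_real,
                     cdf_perm_mean = rowMeans(rep_cdf),
                     cdf_perm_sd = apply(rep_cdf, 1, stats::sd))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       n_real = length(real_indices), n_permuted = length(pooled),
       replicate_means = vapply(permuted_indices, mean, numeric(1)),
       band = band)
}

#' Fraction of significant clusters whose centre shares a significant keyword
#'
#' Among clusters with at least one Bonferroni-significant annotation set,
#' the fraction whose centre gene is itself annotated to at least one of
#' those significant sets. The Bonferroni divisor is the number of sets
#' tested for that cluster.
#'
#' @param results data frame from [enrich_clusters()].
#' @param annot the [gene_set_collection] that was tested (for centre
#'   membership lookup).
#' @param alpha family-wise significance level (default 0.05).
#' @return list with `fraction` (NA if no cluster is significant, with
#'   `applicable = FALSE`), `n_significant_clusters`, `n_concordant`, and a
#'   per-cluster data frame `detail`.
#' @export
centre_keyword_concordance <- function(results, annot, alpha = 0.05) {
  split_res <- split(results, results$centre)
  rows <- lapply(names(split_res), function(ctr) {
    r <- split_res[[ctr]]
    m <- nrow(r)
    sig <- r$set_id[r$p_value * m <= alpha]
    if (!length(sig)) return(NULL)
    in_sig <- vapply(annot$sets[sig],
                     function(s) ctr %in% s, logical(1))
    data.frame(centre = ctr, n_significant_sets = length(sig),
               concordant = any(in_sig), stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, rows)
  if (is.null(detail))
    return(list(fraction = NA_real_, applicable = FALSE,
                n_significant_clusters = 0L, n_concordant = 0L,
                detail = data.frame()))
  list(fraction = mean(detail$concordant), applicable = TRUE,
       n_significant_clusters = nrow(detail),
       n_concordant = sum(detail$concordant), detail = detail)
}

#' Maximum phenotype similarity between a centre and its cluster members
#'
#' Scans all (centre phenotype, member phenotype) pairs in the similarity
#' matrix and reports the maximum score, flagging whether it reaches the
#' similarity threshold (a score equal to the threshold counts as
#' reaching it).
#'
#' @param centre_phenos phenotype IDs associated with the centre gene.
#' @param member_phenos phenotype IDs associated with cluster members.
#' @param sim a [phenotype_similarity] matrix.
#' @param threshold similarity threshold (default 0.4).
#' @return list with `applicable`, `max_score`, `reached_threshold`.
#' @export
centre_phenotype_similarity <- function(centre_phenos, member_phenos, sim,
                                        threshold = 0.4) {
  centre_phenos <- as.character(centre_phenos)
  member_phenos <- as.character(member_phenos)
  if (!length(centre_phenos))
    return(list(applicable = FALSE, max_score = NA_real_,
                reached_threshold = NA))
  missing <- setdiff(c(centre_phenos, member_phenos), rownames(sim))
  if (length(missing))
    stop("phenotype(s) absent from similarity matrix: ",
         paste(missing, collapse = ", "))
  if (!length(member_phenos))
    return(list(applicable = FALSE, max_score = NA_real_,
                reached_threshold = NA))
  mx <- max(sim[centre_phenos, member_phenos, drop = FALSE])
  list(applicable = TRUE, max_score = mx,
       reached_threshold = mx >= threshold)
}

#' Functional-index distributions for a network and its permuted nulls
#'
#' Convenience driver: extracts all CAGCs of `net`, computes their
#' functional indices, repeats on `n_perm` node-label permutations (seeds
#' fanned out from `seed`), and runs [index_distribution_test()].
#'
#' @param net merged [anticoex_network].
#' @param sets a [gene_set_collection].
#' @param universe background gene set (defaults to the network's nodes).
#' @param n_perm number of permutation replicates (default 100).
#' @param seed master seed for the permutations.
#' @return list with `real` (named index vector), `permuted` (list of index
#'   vectors) and `test` (result of [index_distribution_test()]).
#' @export
validate_functional_coherence <- function(net, sets, universe = net$nodes,
                                          n_perm = 100, seed = 1) {
  clusters <- extract_all_cagcs(net)
  real <- functional_indices(clusters, sets, universe)
  permuted <- lapply(seq_len(n_perm), function(i) {
    pn <- permuted_network(net, seed = derive_seed(seed, i))
    functional_indices(extract_all_cagcs(pn), sets, universe)
  })
  list(real = real, permuted = permuted,
       test = index_distribution_test(real, permuted))
}
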
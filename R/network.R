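# Anti-coexpression network construction: single-species networks (SANs)
# from reciprocal bottom-percentile correlation ranking, cross-species
# conservation, merging, and per-gene cluster (CAGC) extraction.

#' Pearson correlation matrix over probesets
#'
#' Correlates every probeset profile with every other using pairwise-complete
#' samples. Zero-variance probesets (flagged on the expression object) are
#' excluded; probeset pairs with fewer than `min_overlap` complete sample
#' pairs are recorded as undefined (`NA`) and form no edges downstream.
#'
#' @param expr an [expression_matrix].
#' @param min_overlap minimum number of complete sample pairs required for a
#'   correlation to be defined (default 4).
#' @param min_samples minimum number of samples the dataset must have for
#'   network construction to proceed at all (default 4).
#' @return symmetric numeric matrix with unit diagonal over the retained
#'   probesets; attribute `excluded` lists the zero-variance probesets and
#'   attribute `n_undefined_pairs` counts below-overlap pairs.
#' @export
correlation_matrix <- function(expr, min_overlap = 4, min_samples = 4) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr$values) < min_samples)
    stop(sprintf(
      "dataset '%s' has %d samples; network construction requires >= %d",
      expr$dataset_id, ncol(expr$values), min_samples))
  keep <- setdiff(rownames(expr$values), expr$zero_variance)
  if (length(keep) < 2)
    stop("fewer than two non-constant probesets; nothing to correlate")
  v <- expr$values[keep, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(v), use = "pairwise.complete.obs"))
  ok <- !is.na(v)
  counts <- tcrossprod(ok * 1)
  low <- counts < min_overlap
  n_undef <- (sum(low) - sum(diag(low))) / 2 + sum(is.na(cc[!low])) / 2
  cc[low] <- NA_real_
  diag(cc) <- 1
  attr(cc, "excluded") <- expr$zero_variance
  attr(cc, "n_undefined_pairs") <- n_undef
  cc
}

#' Directed anti-correlation edges by per-column bottom-percentile ranking
#'
#' A directed edge `p1 -> p2` is called when `corr(p1, p2)` is among the
#' `k` most negative values in column `p2` (diagonal excluded), with
#' `k = max(1, floor(fraction * (N - 1)))`. Only strictly negative
#' correlations are eligible, so a column without negative values receives
#' no incoming edges. Ties at the k-th value are broken by lexicographic
#' probeset ID so runs are reproducible.
#'
#' @param corr square correlation matrix (undefined pairs `NA`).
#' @param fraction percentile of the anti-correlation ranking that may form
#'   edges; the reference analysis uses the bottom 1% (`0.01`).
#' @return 2-column character matrix with columns `from`, `to`.
#' @export
directed_anticorr_edges <- function(corr, fraction = 0.01) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie strictly between 0 and 1")
  ids <- colnames(corr)
  n <- ncol(corr)
  k <- max(1L, as.integer(floor(fraction * (n - 1))))
  from <- vector("list", n)
  for (j in seq_len(n)) {
    v <- corr[, j]
    v[j] <- NA_real_
    neg <- which(!is.na(v) & v < 0)
    if (!length(neg)) next
    ord <- neg[order(v[neg], ids[neg])]
    from[[j]] <- ids[ord[seq_len(min(k, length(ord)))]]
  }
  out <- cbind(from = unlist(from),
               to = rep(ids, vapply(from, length, integer(1))))
  if (is.null(out)) out <- matrix(character(0), 0, 2,
                                  dimnames = list(NULL, c("from", "to")))
  out
}

#' Undirected network from reciprocal directed edges
#'
#' Keeps an unordered edge `{p1, p2}` only when both `p1 -> p2` and
#' `p2 -> p1` were called, i.e. each probeset lies within the other's
#' bottom-percentile anti-correlation ranking.
#'
#' @param directed 2-column character matrix of ordered pairs
#'   (from [directed_anticorr_edges()]).
#' @param species_scope,provenance labels stored on the network.
#' @return probeset-level [anticoex_network].
#' @export
reciprocal_undirected <- function(directed, species_scope = "unknown",
                                  provenance = character(0)) {
  directed <- as.matrix(directed)
  if (nrow(directed) == 0)
    return(anticoex_network(matrix(character(0), 0, 2), level = "probeset",
                            species_scope = species_scope,
                            provenance = provenance,
                            id_space = species_scope))
  fwd <- paste(directed[, 1], directed[, 2], sep = "\001")
  rev <- paste(directed[, 2], directed[, 1], sep = "\001")
  both <- directed[fwd %in% rev, , drop = FALSE]
  anticoex_network(both, level = "probeset", species_scope = species_scope,
                   provenance = provenance, id_space = species_scope)
}

#' Collapse a probeset-level network to gene level
#'
#' Genes `G1 != G2` are connected iff at least one probeset edge spans a
#' probeset of `G1` and a probeset of `G2`. Edges internal to one gene's
#' probesets are dropped; unmapped probesets contribute no gene edges.
#'
#' @param net probeset-level [anticoex_network].
#' @param map a [probeset_gene_map].
#' @return gene-level [anticoex_network].
#' @export
collapse_to_genes <- function(net, map) {
  stopifnot(inherits(net, "anticoex_network"))
  if (net$level != "probeset")
    stop("`net` must be a probeset-level network")
  mp <- map[!is.na(map$gene), c("probeset", "gene"), drop = FALSE]
  e <- as.data.frame(net$edges, stringsAsFactors = FALSE)
  if (nrow(e) == 0 || nrow(mp) == 0)
    return(anticoex_network(matrix(character(0), 0, 2), level = "gene",
                            species_scope = net$species_scope,
                            provenance = net$provenance,
                            id_space = net$id_space))
  m1 <- merge(e, mp, by.x = "from", by.y = "probeset")
  m2 <- merge(m1, mp, by.x = "to", by.y = "probeset",
              suffixes = c("_from", "_to"))
  ge <- m2[m2$gene_from != m2$gene_to, c("gene_from", "gene_to"),
           drop = FALSE]
  anticoex_network(as.matrix(ge), level = "gene",
                   species_scope = net$species_scope,
                   provenance = net$provenance, id_space = net$id_space)
}

#' Build a single-species anti-coexpression network (SAN)
#'
#' Convenience pipeline: correlation -> directed bottom-percentile edges ->
#' reciprocal filter -> gene-level collapse.
#'
#' @param expr an [expression_matrix].
#' @param map a [probeset_gene_map].
#' @param fraction bottom-percentile threshold (default 0.01).
#' @param min_overlap,min_samples see [correlation_matrix()].
#' @return gene-level [anticoex_network].
#' @export
build_san <- function(expr, map, fraction = 0.01, min_overlap = 4,
                      min_samples = 4) {
  cc <- correlation_matrix(expr, min_overlap = min_overlap,
                           min_samples = min_samples)
  d <- directed_anticorr_edges(cc, fraction = fraction)
  ps_net <- reciprocal_undirected(d, species_scope = expr$species,
                                  provenance = expr$dataset_id)
  collapse_to_genes(ps_net, map)
}

#' Build the conserved anti-coexpression gene network (CAGN)
#'
#' Two species-A genes are connected in the conserved network iff (1) they
#' are connected in the species-A network, (2) both have a one-to-one
#' ortholog, and (3) the corresponding species-B genes are connected in the
#' species-B network. The result is expressed in species-A gene IDs.
#'
#' @param net_a,net_b gene-level [anticoex_network]s for the two species.
#' @param orth an [orthology_map]; only pairs flagged one-to-one are used.
#' @return conserved [anticoex_network] over species-A IDs.
#' @export
build_conserved_network <- function(net_a, net_b, orth) {
  stopifnot(inherits(net_a, "anticoex_network"),
            inherits(net_b, "anticoex_network"))
  if (net_a$level != "gene" || net_b$level != "gene")
    stop("conservation requires gene-level networks")
  oo <- orth[orth$one_to_one, , drop = FALSE]
  b_of <- stats::setNames(oo$gene_b, oo$gene_a)
  ea <- net_a$edges
  bkeys <- edge_keys(net_b$edges)
  keep <- logical(nrow(ea))
  if (nrow(ea)) {
    b1 <- b_of[ea[, 1]]
    b2 <- b_of[ea[, 2]]
    mapped <- !is.na(b1) & !is.na(b2)
    cand <- which(mapped)
    if (length(cand)) {
      kk <- paste(pmin(b1[cand], b2[cand]), pmax(b1[cand], b2[cand]),
                  sep = "\001")
      keep[cand] <- kk %in% bkeys
    }
  }
  anticoex_network(ea[keep, , drop = FALSE], level = "gene",
                   species_scope = "conserved",
                   provenance = unique(c(net_a$provenance,
                                         net_b$provenance)),
                   id_space = net_a$id_space)
}

#' Merge conserved networks into one
#'
#' Node and edge sets are unioned and provenance concatenated. All input
#' networks must be gene-level and declare the same identifier space.
#'
#' @param nets list of gene-level [anticoex_network]s.
#' @return merged [anticoex_network].
#' @export
merge_networks <- function(nets) {
  if (!length(nets)) stop("no networks to merge")
  lvl <- unique(vapply(nets, `[[`, character(1), "level"))
  if (!identical(lvl, "gene"))
    stop("all networks must be gene-level")
  spaces <- unique(vapply(nets, `[[`, character(1), "id_space"))
  if (length(spaces) > 1)
    stop("cannot merge networks over different ID spaces: ",
         paste(spaces, collapse = " vs "))
  edges <- do.call(rbind, lapply(nets, `[[`, "edges"))
  nodes <- unique(unlist(lapply(nets, `[[`, "nodes")))
  anticoex_network(edges, level = "gene",
                   species_scope = unique(vapply(nets, `[[`, character(1),
                                                 "species_scope")),
                   provenance = unlist(lapply(nets, `[[`, "provenance")),
                   id_space = spaces, nodes = nodes)
}

#' Extract the conserved anti-coexpressed gene cluster of a gene
#'
#' The CAGC of centre gene `g` is the set of its nearest neighbours in the
#' merged conserved network; `g` itself is not a member.
#'
#' @param net merged [anticoex_network].
#' @param gene centre gene ID (must be a network node).
#' @return a [cagc].
#' @export
extract_cagc <- function(net, gene) {
  stopifnot(inherits(net, "anticoex_network"))
  gene <- as.character(gene)
  if (!gene %in% net$nodes)
    stop("gene '", gene, "' is not a node of the network")
  e <- net$edges
  nb <- c(e[e[, 1] == gene, 2], e[e[, 2] == gene, 1])
  cagc(gene, setdiff(nb, gene))
}

#' Extract the CAGC of every network gene
#'
#' @param net merged [anticoex_network].
#' @return named list of [cagc] objects, one per node with at least one
#'   neighbour.
#' @export
extract_all_cagcs <- function(net) {
  adj <- adjacency_list(net$edges, net$nodes)
  adj <- adj[lengths(adj) > 0]
  out <- mapply(function(g, nb) cagc(g, nb), names(adj), adj,
                SIMPLIFY = FALSE)
  out
}
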
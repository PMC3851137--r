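# Direction-of-effect validation against drug-perturbation rank matrices:
# probeset ranks are collapsed to gene ranks (max rule) and each
# target-centred CAGC is tested for a rank shift against the background
# with a two-sided Mann-Whitney U test under BH control.

#' Gene-level ranks for one perturbation instance
#'
#' Collapses probeset ranks to gene ranks by taking, for each gene, the
#' maximum rank among its probesets. Probesets without a gene assignment
#' are dropped (their ranks are lost), which makes the gene-rank
#' distribution non-uniform and upward-skewed even though probeset ranks
#' are uniform by construction.
#'
#' @param ranks a [perturbation_rank_matrix].
#' @param map a [probeset_gene_map].
#' @param instance instance ID (a column of the rank matrix).
#' @return named numeric vector of gene ranks.
#' @export
gene_rank <- function(ranks, map, instance) {
  stopifnot(inherits(ranks, "perturbation_rank_matrix"))
  instance <- as.character(instance)
  if (!instance %in% colnames(ranks$ranks))
    stop("instance '", instance, "' not found in rank matrix")
  gene_rank_matrix(ranks, map)[, instance]
}

# Internal: gene-by-instance matrix of max-collapsed ranks, computed once
# for all instances.
gene_rank_matrix <- function(ranks, map) {
  mp <- map[!is.na(map$gene) & map$probeset %in% rownames(ranks$ranks), ,
            drop = FALSE]
  if (!nrow(mp)) stop("no probeset of the rank matrix maps to a gene")
  groups <- split(match(mp$probeset, rownames(ranks$ranks)), mp$gene)
  out <- vapply(groups, function(ix) {
    apply(ranks$ranks[ix, , drop = FALSE], 2, max)
  }, numeric(ncol(ranks$ranks)))
  out <- matrix(out, nrow = ncol(ranks$ranks),
                dimnames = list(colnames(ranks$ranks), names(groups)))
  t(out)
}

#' Rank-shift test of a cluster against the background
#'
#' Two-sided Mann-Whitney U test of the cluster genes' ranks against all
#' other measured genes' ranks. The centre gene is excluded from both
#' groups so the target's own perturbation cannot drive the call. The
#' direction is `"up"` when the cluster median rank exceeds the background
#' median, `"down"` when it is lower, `"tie"` when equal. The p-value is
#' exact (distribution enumeration) when the smaller group has at most 8
#' genes, and uses the tie-corrected normal approximation otherwise.
#'
#' @param gene_ranks named numeric vector from [gene_rank()].
#' @param cluster a [cagc].
#' @return list with `testable`, `U`, `p_value`, `median_cluster`,
#'   `median_background`, `direction`, `n_cluster`, `n_background`.
#' @export
test_cluster_shift <- function(gene_ranks, cluster) {
  genes <- names(gene_ranks)
  cl <- intersect(cluster$members, genes)
  bg <- setdiff(genes, c(cluster$members, cluster$centre))
  if (!length(cl) || !length(bg))
    return(list(testable = FALSE, U = NA_real_, p_value = NA_real_,
                median_cluster = NA_real_, median_background = NA_real_,
                direction = NA_character_, n_cluster = length(cl),
                n_background = length(bg)))
  exact <- min(length(cl), length(bg)) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(gene_ranks[cl], gene_ranks[bg],
                       alternative = "two.sided", exact = exact))
  med_cl <- stats::median(gene_ranks[cl])
  med_bg <- stats::median(gene_ranks[bg])
  direction <- if (med_cl > med_bg) "up" else
    if (med_cl < med_bg) "down" else "tie"
  list(testable = TRUE, U = unname(wt$statistic),
       p_value = wt$p.value, median_cluster = med_cl,
       median_background = med_bg, direction = direction,
       n_cluster = length(cl), n_background = length(bg))
}

#' Validate direction of drug effect across all instances
#'
#' For each drug, performs one rank-shift test per (CAGC whose centre the
#' drug targets) x (perturbation instance of that drug) - the N x M test
#' layout - then applies Benjamini-Hochberg over the full family of tests
#' in the run and tallies significant up/down/tie calls.
#'
#' @param ranks a [perturbation_rank_matrix] (instance metadata links
#'   instances to drugs).
#' @param map a [probeset_gene_map].
#' @param clusters list of [cagc] objects.
#' @param drugs a [drug_target_table].
#' @param fdr Benjamini-Hochberg FDR level for the significance tally
#'   (default 0.05).
#' @return list with `results` (data frame: `instance`, `drug`, `centre`,
#'   `U`, `p_value`, `q_value`, `median_cluster`, `median_background`,
#'   `direction`, `significant`) and `summary` (data frame of significant
#'   up/down/tie counts and the total number of tests).
#' @export
run_validation <- function(ranks, map, clusters, drugs, fdr = 0.05) {
  stopifnot(inherits(ranks, "perturbation_rank_matrix"))
  centres <- vapply(clusters, `[[`, character(1), "centre")
  meta <- ranks$metadata
  empty <- data.frame(instance = character(0), drug = character(0),
                      centre = character(0), U = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      median_cluster = numeric(0),
                      median_background = numeric(0),
                      direction = character(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  pairs <- merge(data.frame(drug = drugs$drug, centre = drugs$target,
                            stringsAsFactors = FALSE),
                 meta[, c("instance", "drug")], by = "drug")
  pairs <- pairs[pairs$centre %in% centres, , drop = FALSE]
  if (!nrow(pairs)) {
    warning("no perturbation instance is linked to a clustered drug target")
    return(list(results = empty,
                summary = data.frame(up = 0L, down = 0L, tie = 0L,
                                     n_tests = 0L, n_significant = 0L)))
  }
  grm <- gene_rank_matrix(ranks, map)
  cluster_of <- stats::setNames(clusters, centres)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    inst <- pairs$instance[i]
    ts <- test_cluster_shift(grm[, inst], cluster_of[[pairs$centre[i]]])
    if (!ts$testable) return(NULL)
    data.frame(instance = inst, drug = pairs$drug[i],
               centre = pairs$centre[i], U = ts$U, p_value = ts$p_value,
               median_cluster = ts$median_cluster,
               median_background = ts$median_background,
               direction = ts$direction, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    warning("no testable (cluster, instance) pair")
    return(list(results = empty,
                summary = data.frame(up = 0L, down = 0L, tie = 0L,
                                     n_tests = 0L, n_significant = 0L)))
  }
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < fdr
  res <- res[, c("instance", "drug", "centre", "U", "p_value", "q_value",
                 "median_cluster", "median_background", "direction",
                 "significant")]
  rownames(res) <- NULL
  sig <- res[res$significant, , drop = FALSE]
  summary <- data.frame(up = sum(sig$direction == "up"),
                        down = sum(sig$direction == "down"),
                        tie = sum(sig$direction == "tie"),
                        n_tests = nrow(res), n_significant = nrow(sig))
  list(results = res, summary = summary)
}
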
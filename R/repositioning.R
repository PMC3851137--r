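# Drug-to-phenotype association: phenotype clusters from a similarity
# matrix, overlap testing of target-centred CAGCs against them, and the
# per-target candidate report.

#' Build phenotype clusters from a similarity matrix
#'
#' The pheno-cluster of phenotype `P` is the set of genes associated to `P`
#' itself or to any phenotype `P'` whose similarity to `P` is at least the
#' threshold (closed bound: `s = threshold` is included; `s(P, P) = 1`
#' guarantees P's own genes are always present). Phenotypes carrying gene
#' associations but absent from the similarity matrix are treated, with a
#' warning, as similar only to themselves.
#'
#' @param sim a [phenotype_similarity] matrix.
#' @param pheno_genes a [gene_set_collection] of phenotype-to-gene
#'   associations (`kind = "phenotype_association"`).
#' @param threshold similarity threshold in \[0, 1\] (default 0.4, the value
#'   below which text-mining phenotype similarity stops being biologically
#'   meaningful).
#' @return named list of `pheno_cluster` objects (fields `phenotype`,
#'   `similar_phenotypes`, `genes`), one per phenotype with a non-empty
#'   gene set.
#' @export
build_phenoclusters <- function(sim, pheno_genes, threshold = 0.4) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("`threshold` must lie in [0, 1]")
  psets <- pheno_genes$sets
  sim_ids <- rownames(sim)
  missing <- setdiff(names(psets), sim_ids)
  if (length(missing))
    warning("phenotype(s) not in similarity matrix, treated as similar ",
            "only to themselves: ", paste(missing, collapse = ", "))
  all_ids <- union(sim_ids, names(psets))
  out <- lapply(all_ids, function(p) {
    similar <- if (p %in% sim_ids)
      sim_ids[sim[p, ] >= threshold] else character(0)
    similar <- union(similar, p)
    genes <- sort(unique(unlist(psets[intersect(similar,
                                                names(psets))])))
    if (!length(genes)) return(NULL)
    structure(list(phenotype = p, similar_phenotypes = sort(similar),
                   genes = genes),
              class = "pheno_cluster")
  })
  names(out) <- all_ids
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.pheno_cluster <- function(x, ...) {
  cat(sprintf("pheno_cluster %s: %d phenotype(s), %d gene(s)\n",
              x$phenotype, length(x$similar_phenotypes), length(x$genes)))
  invisible(x)
}

#' Associate drug targets to phenotypes through CAGC overlap
#'
#' For every CAGC whose centre is a declared drug target, tests the overlap
#' of the cluster with every pheno-cluster by the one-sided Fisher
#' (hypergeometric) test over the given universe. Pairs with
#' `p < p_threshold` are retained and fanned out into one association row
#' per drug hitting that target. Benjamini-Hochberg q-values are reported
#' over the full family of tests actually performed.
#'
#' @param clusters list of [cagc] objects.
#' @param phenos list of pheno-clusters from [build_phenoclusters()].
#' @param drugs a [drug_target_table].
#' @param universe background gene set (by convention the merged-network
#'   gene set).
#' @param p_threshold significance cut on the raw p-value (default `1e-4`).
#' @return data frame of associations: `drug`, `target`, `phenotype`,
#'   `p_value`, `q_value`, `overlap`, `overlap_genes` (comma-joined);
#'   attribute `n_tests` records the test-family size.
#' @export
associate_drug_phenotypes <- function(clusters, phenos, drugs, universe,
                                      p_threshold = 1e-4) {
  empty <- data.frame(drug = character(0), target = character(0),
                      phenotype = character(0), p_value = numeric(0),
                      q_value = numeric(0), overlap = integer(0),
                      overlap_genes = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(drugs)) {
    warning("empty drug-target table; no associations possible")
    attr(empty, "n_tests") <- 0L
    return(empty)
  }
  centres <- vapply(clusters, `[[`, character(1), "centre")
  targeted <- clusters[centres %in% drugs$target]
  if (!length(targeted) || !length(phenos)) {
    attr(empty, "n_tests") <- 0L
    return(empty)
  }
  tests <- do.call(rbind, lapply(targeted, function(cl) {
    do.call(rbind, lapply(phenos, function(ph) {
      fe <- fisher_enrichment(cl$members, ph$genes, universe)
      data.frame(target = cl$centre, phenotype = ph$phenotype,
                 p_value = fe$p_value, overlap = fe$overlap,
                 overlap_genes = paste(fe$overlap_genes, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }))
  tests$q_value <- stats::p.adjust(tests$p_value, method = "BH")
  hits <- tests[tests$p_value < p_threshold, , drop = FALSE]
  if (!nrow(hits)) {
    attr(empty, "n_tests") <- nrow(tests)
    return(empty)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    dd <- drugs[drugs$target == h$target, , drop = FALSE]
    data.frame(drug = dd$drug, target = h$target,
               phenotype = h$phenotype, p_value = h$p_value,
               q_value = h$q_value, overlap = h$overlap,
               overlap_genes = h$overlap_genes, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$p_value, out$drug, out$phenotype), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(tests)
  out
}

#' Per-target association report
#'
#' Groups associations by target and sorts each group by ascending p-value,
#' mirroring the usual per-target table of candidate disorders (phenotype
#' ID, name, p-value).
#'
#' @param assocs data frame from [associate_drug_phenotypes()].
#' @param phenotype_names optional named character vector mapping phenotype
#'   IDs to display names.
#' @return data frame ordered by target then p-value with columns `target`,
#'   `phenotype`, `phenotype_name`, `p_value`, `drugs` (comma-joined drugs
#'   hitting the target for that phenotype).
#' @export
rank_report <- function(assocs, phenotype_names = NULL) {
  if (!nrow(assocs))
    return(data.frame(target = character(0), phenotype = character(0),
                      phenotype_name = character(0), p_value = numeric(0),
                      drugs = character(0), stringsAsFactors = FALSE))
  key <- paste(assocs$target, assocs$phenotype, sep = "\001")
  agg <- lapply(split(assocs, key), function(a) {
    data.frame(target = a$target[1], phenotype = a$phenotype[1],
               phenotype_name =
                 if (!is.null(phenotype_names) &&
                     a$phenotype[1] %in% names(phenotype_names))
                   phenotype_names[[a$phenotype[1]]] else NA_character_,
               p_value = a$p_value[1],
               drugs = paste(sort(unique(a$drug)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$target, out$p_value, out$phenotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}
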
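# Seeded synthetic-fixture generators. They emulate the statistical
# structure the method assumes -- planted anti-correlated conserved
# modules in two species, phenotype families aligned to those modules,
# and drug-responsive probeset sets in a perturbation rank matrix -- so
# every pipeline stage can be exercised and scored against a known truth
# record without any external database.

#' Specification of a synthetic fixture
#'
#' Collects all generator parameters with validation. The defaults define
#' the standard study conditions used throughout the test-suite: 300 genes
#' per species, 3 planted modules of 10 members, perfect anti-correlation
#' loading (`rho = -1`) with Gaussian noise `sigma = 0.2`, and 40 samples
#' per species.
#'
#' @param seed master seed; every derived generator fans its own seed out
#'   from it, so a fixture is bit-reproducible.
#' @param n_genes genes per species.
#' @param probesets_per_gene integer vector of candidate probeset counts
#'   per gene (sampled uniformly; a scalar gives every gene that count).
#' @param n_samples samples per species.
#' @param n_modules,module_size planted module layout; each module has one
#'   centre plus `module_size` members, all disjoint.
#' @param rho centre-module anti-correlation loading, in `[-1, 0)`.
#' @param sigma standard deviation of the Gaussian probe-level noise.
#' @param one_to_one_fraction fraction of genes carrying a one-to-one
#'   ortholog in the orthology table.
#' @param n_phenotypes,phenotypes_per_family phenotype family layout; the
#'   first `n_modules` families are aligned to the planted modules.
#' @param genes_per_phenotype genes associated to each phenotype.
#' @param n_decoy_drugs drugs targeting background (non-module) genes.
#' @param n_instances_per_drug perturbation instances per drug.
#' @param effect_quantile planted-effect rank quantile: probesets of a
#'   targeted module are drawn above this quantile of the background value
#'   distribution before rank transformation (0 disables planting, giving
#'   a pure-null matrix).
#' @return validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_genes = 300, probesets_per_gene = 1L,
                         n_samples = 40, n_modules = 3, module_size = 10,
                         rho = -1, sigma = 0.2, one_to_one_fraction = 1,
                         n_phenotypes = 12, phenotypes_per_family = 2,
                         genes_per_phenotype = 8, n_decoy_drugs = 2,
                         n_instances_per_drug = 4,
                         effect_quantile = 0.95) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               probesets_per_gene = as.integer(probesets_per_gene),
               n_samples = as.integer(n_samples),
               n_modules = as.integer(n_modules),
               module_size = as.integer(module_size), rho = rho,
               sigma = sigma, one_to_one_fraction = one_to_one_fraction,
               n_phenotypes = as.integer(n_phenotypes),
               phenotypes_per_family = as.integer(phenotypes_per_family),
               genes_per_phenotype = as.integer(genes_per_phenotype),
               n_decoy_drugs = as.integer(n_decoy_drugs),
               n_instances_per_drug = as.integer(n_instances_per_drug),
               effect_quantile = effect_quantile)
  counts <- c(spec$n_genes, spec$n_samples, spec$n_modules,
              spec$module_size, spec$probesets_per_gene,
              spec$n_phenotypes, spec$phenotypes_per_family,
              spec$genes_per_phenotype, spec$n_instances_per_drug)
  if (any(is.na(counts)) || any(counts < 1))
    stop("all fixture counts must be positive")
  if (!is.numeric(spec$rho) || spec$rho >= 0 || spec$rho < -1)
    stop("`rho` must lie in [-1, 0)")
  if (spec$sigma < 0) stop("`sigma` must be non-negative")
  if (spec$one_to_one_fraction < 0 || spec$one_to_one_fraction > 1)
    stop("`one_to_one_fraction` must lie in [0, 1]")
  if (spec$effect_quantile < 0 || spec$effect_quantile > 1)
    stop("`effect_quantile` must lie in [0, 1]")
  if (spec$n_modules * (spec$module_size + 1) > spec$n_genes)
    stop("modules (centre + members) exceed the gene count")
  class(spec) <- "fixture_spec"
  spec
}

#' Anti-correlation fraction matched to the planted design
#'
#' The reciprocal bottom-percentile rule caps the neighbourhood of any
#' probeset at `k = floor(fraction * (N - 1))` partners per column, so a
#' planted module is recoverable only when that capacity is at least the
#' module's probeset count. At compendium scale (tens of thousands of
#' probesets) the conventional 1% gives capacity in the hundreds, far above
#' any cluster size; at synthetic scale the fraction must be chosen by the
#' same capacity rule, `k >= module_size * max(probesets_per_gene) + 2`.
#'
#' @param n_probesets total probesets in the matrix.
#' @param module_size planted module member count.
#' @param max_probesets_per_gene largest probeset multiplicity.
#' @return a fraction in (0, 0.2].
#' @export
recommended_fraction <- function(n_probesets, module_size,
                                 max_probesets_per_gene = 1) {
  need <- module_size * max_probesets_per_gene + 2
  min(0.2, need / max(n_probesets - 1, 1))
}

# Internal: per-gene latent profiles for one species. Background genes get
# independent standard-normal latents; each module centre gets its own
# latent and members load on it with coefficient rho (< 0).
latent_profiles <- function(n_genes, n_samples, centres_i, members_i, rho) {
  z <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  for (m in seq_along(centres_i)) {
    z[members_i[[m]], ] <- matrix(rep(-abs(rho) * z[centres_i[m], ],
                                      each = length(members_i[[m]])),
                                  nrow = length(members_i[[m]]))
  }
  z
}

#' Generate a two-species expression pair with planted modules
#'
#' For each planted module, one centre gene carries a latent profile and
#' every member's profile is `-|rho|` times that latent plus Gaussian noise
#' `sigma`, independently in both species (orthologous genes carry the
#' module structure in both). Background genes are independent noise.
#' Probeset profiles replicate their gene's profile with independent probe
#' noise of the same `sigma`.
#'
#' @param spec a [fixture_spec].
#' @return list with `expr_a`, `expr_b` ([expression_matrix]), `map_a`,
#'   `map_b` ([probeset_gene_map]), `orthology` ([orthology_map]) and
#'   `truth` -- a record with the planted centres, module member sets (in
#'   both ID spaces), the background genes, and the probeset maps, from
#'   which every downstream recovery statistic can be scored.
#' @export
make_expression_pair <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    genes_a <- sprintf("gA%04d", seq_len(n))
    genes_b <- sprintf("gB%04d", seq_len(n))
    ord <- sample(n)
    centres_i <- ord[seq_len(spec$n_modules)]
    members_i <- split(
      ord[spec$n_modules + seq_len(spec$n_modules * spec$module_size)],
      rep(seq_len(spec$n_modules), each = spec$module_size))
    oo_idx <- sort(sample(n, round(spec$one_to_one_fraction * n)))
    orth <- orthology_map(genes_a[oo_idx], genes_b[oo_idx], TRUE)
    ppg <- if (length(spec$probesets_per_gene) == 1L)
      rep(spec$probesets_per_gene, n) else
        sample(spec$probesets_per_gene, n, replace = TRUE)
    build_species <- function(genes) {
      lat <- latent_profiles(n, spec$n_samples, centres_i, members_i,
                             spec$rho)
      gi <- rep(seq_len(n), ppg)
      probes <- sprintf("%s_ps%d", genes[gi],
                        unlist(lapply(ppg, seq_len)))
      vals <- lat[gi, , drop = FALSE] +
        matrix(stats::rnorm(length(gi) * spec$n_samples, sd = spec$sigma),
               nrow = length(gi))
      dimnames(vals) <- list(probes,
                             sprintf("s%02d", seq_len(spec$n_samples)))
      list(values = vals, map = probeset_gene_map(probes, genes[gi]))
    }
    sa <- build_species(genes_a)
    sb <- build_species(genes_b)
    modules <- stats::setNames(
      lapply(members_i, function(ix) sort(genes_a[ix])),
      genes_a[centres_i])
    modules_b <- stats::setNames(
      lapply(members_i, function(ix) sort(genes_b[ix])),
      genes_b[centres_i])
    planted <- c(centres_i, unlist(members_i))
    truth <- list(centres = genes_a[centres_i],
                  modules = modules,
                  centres_b = genes_b[centres_i],
                  modules_b = modules_b,
                  background = sort(genes_a[-planted]),
                  map_a = sa$map, map_b = sb$map,
                  spec = spec)
    list(expr_a = expression_matrix(sa$values, "synthetic_a", "speciesA"),
         expr_b = expression_matrix(sb$values, "synthetic_b", "speciesB"),
         map_a = sa$map, map_b = sb$map, orthology = orth,
         truth = truth)
  })
}

#' Run the network pipeline on a fixture
#'
#' Builds both single-species networks, intersects them through the
#' orthology map and merges the result; the anti-correlation fraction
#' defaults to the capacity-matched value of [recommended_fraction()].
#'
#' @param fx result of [make_expression_pair()].
#' @param fraction anti-correlation percentile passed to [build_san()].
#' @return list with `san_a`, `san_b`, `conserved`, `merged` and `cagcs`
#'   (all clusters of the merged network).
#' @export
run_fixture_pipeline <- function(fx, fraction = NULL) {
  spec <- fx$truth$spec
  if (is.null(fraction))
    fraction <- recommended_fraction(nrow(fx$expr_a$values),
                                     spec$module_size,
                                     max(spec$probesets_per_gene))
  san_a <- build_san(fx$expr_a, fx$map_a, fraction = fraction)
  san_b <- build_san(fx$expr_b, fx$map_b, fraction = fraction)
  cons <- build_conserved_network(san_a, san_b, fx$orthology)
  merged <- merge_networks(list(cons))
  list(san_a = san_a, san_b = san_b, conserved = cons, merged = merged,
       cagcs = extract_all_cagcs(merged), fraction = fraction)
}

#' Planted-member recovery of a fixture pipeline run
#'
#' Fraction of planted module members recovered by [extract_cagc()] at each
#' planted centre (centres absent from the merged network score 0).
#'
#' @param merged merged [anticoex_network].
#' @param truth truth record from [make_expression_pair()].
#' @return named numeric vector of per-module recovery fractions.
#' @export
planted_recovery <- function(merged, truth) {
  vapply(names(truth$modules), function(ctr) {
    if (!ctr %in% merged$nodes) return(0)
    got <- extract_cagc(merged, ctr)$members
    mean(truth$modules[[ctr]] %in% got)
  }, numeric(1))
}

#' Generate a phenotype world aligned to planted modules
#'
#' Phenotypes are grouped into families: similarity is drawn at or above
#' 0.4 within a family and strictly below 0.4 between families (diagonal 1,
#' symmetric). The first `n_modules` families are aligned to the planted
#' modules -- each of their phenotypes is associated to genes sampled from
#' the module's members -- while the remaining (decoy) families draw their
#' genes from the background.
#'
#' @param spec a [fixture_spec].
#' @param truth truth record from [make_expression_pair()].
#' @return list with `sim` ([phenotype_similarity]), `pheno_genes`
#'   ([gene_set_collection]) and `alignment` (data frame `phenotype`,
#'   `centre`; `NA` centre for decoys).
#' @export
make_pheno_world <- function(spec, truth) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(derive_seed(spec$seed, "pheno"), {
    np <- spec$n_phenotypes
    fam <- rep(seq_len(ceiling(np / spec$phenotypes_per_family)),
               each = spec$phenotypes_per_family)[seq_len(np)]
    if (max(fam) < spec$n_modules)
      stop("not enough phenotype families to align every module")
    ids <- sprintf("PH%04d", seq_len(np))
    sim <- matrix(0, np, np, dimnames = list(ids, ids))
    for (i in seq_len(np)) for (j in seq_len(np)) {
      if (j <= i) next
      sim[i, j] <- sim[j, i] <- if (fam[i] == fam[j])
        stats::runif(1, 0.4, 0.95) else stats::runif(1, 0, 0.395)
    }
    diag(sim) <- 1
    centre_of_fam <- c(truth$centres,
                       rep(NA_character_, max(fam) - spec$n_modules))
    gsets <- lapply(seq_len(np), function(i) {
      ctr <- centre_of_fam[fam[i]]
      pool <- if (is.na(ctr)) truth$background else truth$modules[[ctr]]
      sample(pool, min(spec$genes_per_phenotype, length(pool)))
    })
    names(gsets) <- ids
    list(sim = phenotype_similarity(sim),
         pheno_genes = gene_set_collection(gsets,
                                           kind = "phenotype_association"),
         alignment = data.frame(phenotype = ids,
                                centre = centre_of_fam[fam],
                                stringsAsFactors = FALSE))
  })
}

#' Generate a perturbation rank matrix with planted drug effects
#'
#' One inhibitor drug is planted per module (targeting its centre), plus
#' decoy drugs targeting background genes. For every instance of a planted
#' drug, the probesets of the targeted module's members are drawn above the
#' `effect_quantile` of the background value distribution before rank
#' transformation, so they occupy the top ranks; all other values are
#' uniform. Each instance column is a permutation of `1..N` by
#' construction.
#'
#' @param spec a [fixture_spec].
#' @param truth truth record from [make_expression_pair()].
#' @return list with `ranks` ([perturbation_rank_matrix]), `drugs`
#'   ([drug_target_table]) and `planted` (data frame `drug`, `target`,
#'   `instance` of the planted instances).
#' @export
make_perturbation_matrix <- function(spec, truth) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(derive_seed(spec$seed, "perturb"), {
    planted_drugs <- sprintf("drug%02d", seq_len(spec$n_modules))
    decoy_targets <- sample(truth$background,
                            min(spec$n_decoy_drugs,
                                length(truth$background)))
    decoy_drugs <- sprintf("decoy%02d", seq_along(decoy_targets))
    drugs <- drug_target_table(
      c(planted_drugs, decoy_drugs),
      c(truth$centres, decoy_targets),
      c(rep("inhibitor", length(planted_drugs)),
        rep("unknown", length(decoy_drugs))))
    probes <- truth$map_a$probeset
    n <- length(probes)
    all_drugs <- drugs$drug
    inst_drug <- rep(all_drugs, each = spec$n_instances_per_drug)
    inst_ids <- sprintf("inst%03d", seq_along(inst_drug))
    ranks <- matrix(0L, n, length(inst_ids),
                    dimnames = list(probes, inst_ids))
    module_probes <- lapply(truth$centres, function(ctr) {
      truth$map_a$probeset[truth$map_a$gene %in% truth$modules[[ctr]]]
    })
    names(module_probes) <- planted_drugs
    for (j in seq_along(inst_ids)) {
      vals <- stats::runif(n)
      d <- inst_drug[j]
      if (d %in% planted_drugs && spec$effect_quantile > 0) {
        hit <- probes %in% module_probes[[d]]
        vals[hit] <- stats::runif(sum(hit), spec$effect_quantile, 1)
      }
      ranks[, j] <- as.integer(rank(vals, ties.method = "first"))
    }
    meta <- data.frame(
      instance = inst_ids, drug = inst_drug,
      concentration = "1e-05 M",
      cell_line = sample(c("PC3", "MCF7", "HL60"), length(inst_ids),
                         replace = TRUE),
      duration = "6 h", stringsAsFactors = FALSE)
    planted <- meta[meta$drug %in% planted_drugs, c("instance", "drug")]
    planted$target <- drugs$target[match(planted$drug, drugs$drug)]
    rownames(planted) <- NULL
    list(ranks = perturbation_rank_matrix(ranks, meta), drugs = drugs,
         planted = planted[, c("drug", "target", "instance")])
  })
}

#' Annotation sets aligned to the planted modules
#'
#' One annotation set per planted module (its member genes) plus decoy sets
#' of background genes, emulating functional categories that planted
#' clusters should light up.
#'
#' @param spec a [fixture_spec].
#' @param truth truth record from [make_expression_pair()].
#' @param n_decoy_sets number of background decoy sets (default 10).
#' @return a [gene_set_collection] of kind `"annotation"`.
#' @export
make_annotation_world <- function(spec, truth, n_decoy_sets = 10) {
  with_seed(derive_seed(spec$seed, "annot"), {
    sets <- lapply(truth$centres, function(ctr) truth$modules[[ctr]])
    names(sets) <- sprintf("MOD_%s", truth$centres)
    decoys <- lapply(seq_len(n_decoy_sets), function(i)
      sample(truth$background, min(spec$module_size,
                                   length(truth$background))))
    names(decoys) <- sprintf("RND_%02d", seq_len(n_decoy_sets))
    gene_set_collection(c(sets, decoys), kind = "annotation")
  })
}

#' Random gene-level network
#'
#' Erdos-Renyi-style network used to exercise the enrichment-validation
#' machinery at scale (many clusters) without an expression matrix.
#'
#' @param n_nodes,n_edges size of the network.
#' @param seed RNG seed.
#' @param prefix node-label prefix.
#' @return gene-level [anticoex_network].
#' @export
make_random_network <- function(n_nodes, n_edges, seed = 1, prefix = "g") {
  with_seed(seed, {
    nodes <- sprintf("%s%04d", prefix, seq_len(n_nodes))
    got <- matrix(character(0), 0, 2)
    while (nrow(got) < n_edges) {
      a <- sample(nodes, 2 * n_edges, replace = TRUE)
      b <- sample(nodes, 2 * n_edges, replace = TRUE)
      got <- canonical_edges(c(got[, 1], a), c(got[, 2], b))
    }
    anticoex_network(got[seq_len(n_edges), , drop = FALSE], level = "gene",
                     species_scope = "synthetic", provenance = "random",
                     id_space = "synthetic", nodes = nodes)
  })
}

#' Annotation sets aligned to network neighbourhoods
#'
#' For each chosen centre, builds one set equal to the centre's neighbour
#' set plus a few random extra genes -- the configuration in which real
#' clusters are functionally coherent. With `scramble = TRUE` all gene
#' labels inside the sets are relabelled by one random permutation of the
#' node set, destroying the alignment while preserving set sizes (the
#' negative control).
#'
#' @param net an [anticoex_network].
#' @param n_sets number of sets (centres sampled among nodes with at least
#'   `min_degree` neighbours).
#' @param n_extra random extra genes appended to each set.
#' @param seed RNG seed.
#' @param scramble relabel genes to break the alignment.
#' @param min_degree minimum centre degree.
#' @return a [gene_set_collection] (kind `"annotation"`); attribute
#'   `centres` holds the sampled centre genes.
#' @export
make_annotation_sets <- function(net, n_sets, n_extra = 3, seed = 1,
                                 scramble = FALSE, min_degree = 1) {
  with_seed(seed, {
    adj <- adjacency_list(net$edges, net$nodes)
    eligible <- names(adj)[lengths(adj) >= min_degree]
    if (length(eligible) < n_sets)
      stop("not enough nodes of degree >= ", min_degree)
    centres <- sample(eligible, n_sets)
    sets <- lapply(centres, function(g)
      unique(c(adj[[g]], sample(net$nodes, n_extra))))
    names(sets) <- sprintf("SET_%s", centres)
    if (scramble) {
      relabel <- stats::setNames(sample(net$nodes), net$nodes)
      sets <- lapply(sets, function(s) unname(relabel[s]))
    }
    out <- gene_set_collection(sets, kind = "annotation")
    attr(out, "centres") <- centres
    out
  })
}

#' Write a complete fixture bundle to a directory
#'
#' Generates the full synthetic input world for a pipeline run and writes
#' it as the plain-text interchange formats: expression TSVs, probeset-gene
#' maps, orthology table, phenotype similarity matrix, phenotype and
#' annotation GMTs, drug-target table, perturbation rank matrix with
#' instance metadata, and a `truth.json` record.
#'
#' @param spec a [fixture_spec].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written file paths plus the
#'   in-memory objects (`fx`, `pheno`, `perturb`, `annotation`).
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_expression_pair(spec)
  pheno <- make_pheno_world(spec, fx$truth)
  perturb <- make_perturbation_matrix(spec, fx$truth)
  annotation <- make_annotation_world(spec, fx$truth)
  p <- function(f) file.path(dir, f)
  write_expr <- function(expr, path) {
    df <- data.frame(probeset = rownames(expr$values), expr$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, path)
  }
  write_expr(fx$expr_a, p("expr_a.tsv"))
  write_expr(fx$expr_b, p("expr_b.tsv"))
  write_tsv(as.data.frame(fx$map_a), p("map_a.tsv"))
  write_tsv(as.data.frame(fx$map_b), p("map_b.tsv"))
  write_tsv(as.data.frame(fx$orthology), p("orthology.tsv"))
  write_tsv(data.frame(phenotype = rownames(pheno$sim),
                       as.data.frame(unclass(pheno$sim)),
                       check.names = FALSE), p("similarity.tsv"))
  writeLines(vapply(names(pheno$pheno_genes$sets), function(id)
    paste(c(id, ".", pheno$pheno_genes$sets[[id]]), collapse = "\t"),
    character(1)), p("pheno_genes.gmt"))
  writeLines(vapply(names(annotation$sets), function(id)
    paste(c(id, ".", annotation$sets[[id]]), collapse = "\t"),
    character(1)), p("annotation.gmt"))
  write_tsv(as.data.frame(perturb$drugs), p("drug_targets.tsv"))
  write_tsv(data.frame(probeset = rownames(perturb$ranks$ranks),
                       as.data.frame(perturb$ranks$ranks),
                       check.names = FALSE), p("rank_matrix.tsv"))
  write_tsv(perturb$ranks$metadata, p("instances.tsv"))
  truth_out <- list(centres = fx$truth$centres,
                    modules = fx$truth$modules,
                    background = fx$truth$background,
                    alignment = pheno$alignment,
                    planted_perturbations = perturb$planted,
                    seed = spec$seed)
  jsonlite::write_json(truth_out, p("truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(
    paths = list(expr_a = p("expr_a.tsv"), expr_b = p("expr_b.tsv"),
                 map_a = p("map_a.tsv"), map_b = p("map_b.tsv"),
                 orthology = p("orthology.tsv"),
                 similarity = p("similarity.tsv"),
                 pheno_genes = p("pheno_genes.gmt"),
                 annotation = p("annotation.gmt"),
                 drug_targets = p("drug_targets.tsv"),
                 rank_matrix = p("rank_matrix.tsv"),
                 instances = p("instances.tsv"),
                 truth = p("truth.json")),
    fx = fx, pheno = pheno, perturb = perturb, annotation = annotation))
}
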
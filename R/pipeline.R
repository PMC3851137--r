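# Configuration-driven pipeline driver chaining all stages:
# build-san -> conserve -> merge -> clusters -> enrich -> phenoclusters ->
# associate -> validate-perturbation. Every output file carries a
# provenance header (tool version, config hash, master seed, stage), and a
# finished stage can be skipped on resume.

pipeline_defaults <- list(fraction = 0.01, sim_threshold = 0.4,
                          p_threshold = 1e-4, fdr = 0.05,
                          min_samples = 4, min_overlap = 4,
                          permutations = 100, seed = 1)

# Internal: load + validate a pipeline configuration before any
# computation. Missing inputs and out-of-range thresholds fail here.
load_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  for (k in names(pipeline_defaults))
    cfg[[k]] <- cfg[[k]] %||% pipeline_defaults[[k]]
  if (!is.numeric(cfg$fraction) || cfg$fraction <= 0 || cfg$fraction >= 1)
    stop("config error: `fraction` must lie strictly between 0 and 1")
  if (cfg$sim_threshold < 0 || cfg$sim_threshold > 1)
    stop("config error: `sim_threshold` must lie in [0, 1]")
  if (cfg$p_threshold <= 0 || cfg$p_threshold > 1)
    stop("config error: `p_threshold` must lie in (0, 1]")
  if (is.null(cfg$datasets) || !length(cfg$datasets))
    stop("config error: at least one dataset pair is required")
  if (is.null(cfg$orthology))
    stop("config error: `orthology` input is required")
  needed <- c(unlist(lapply(cfg$datasets, function(d)
    c(d$expr_a, d$map_a, d$expr_b, d$map_b))),
    cfg$orthology, cfg$annotation, cfg$phenotype_similarity,
    cfg$phenotype_genes, cfg$drug_targets, cfg$rank_matrix, cfg$instances)
  missing <- needed[!file.exists(needed)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  cfg
}

#' Run the complete repositioning pipeline from a configuration
#'
#' Executes, in order: single-species network construction for every
#' dataset pair, cross-species conservation, merging, cluster extraction,
#' functional-coherence validation (when annotation sets are supplied),
#' phenotype clustering, drug-phenotype association (when drug targets are
#' supplied) and perturbation-direction validation (when a rank matrix is
#' supplied). All randomness (network permutations) derives from the
#' configured master seed, so two runs with the same configuration produce
#' byte-identical outputs.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Required keys: `datasets` (list of `name`/`expr_a`/`map_a`/
#'   `expr_b`/`map_b`/`species_a`/`species_b`), `orthology`. Optional
#'   inputs: `annotation`, `phenotype_similarity`, `phenotype_genes`,
#'   `drug_targets`, `rank_matrix`, `instances`. Thresholds (with
#'   defaults): `fraction` 0.01, `sim_threshold` 0.4, `p_threshold` 1e-4,
#'   `fdr` 0.05, `min_samples` 4, `min_overlap` 4, `permutations` 100,
#'   `seed` 1.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @param resume skip stages whose output files already exist.
#' @return invisibly, a named list of the produced file paths.
#' @export
run_pipeline <- function(config, out_dir = NULL, resume = FALSE) {
  cfg <- load_pipeline_config(config)
  out <- out_dir %||% cfg$out_dir %||% stop("no output directory given")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- substr(digest_config(cfg), 1, 12)
  hdr <- function(stage) c(
    sprintf("tool: cagcnet %s",
            as.character(utils::packageVersion("cagcnet"))),
    sprintf("config: %s", cfg_hash),
    sprintf("seed: %d", as.integer(cfg$seed)),
    sprintf("stage: %s", stage))
  paths <- list()
  say <- function(...) message(sprintf(...))

  # -- build-san + conserve, one conserved network per dataset pair -------
  orth <- read_orthology_map(cfg$orthology)
  conserved <- list()
  for (d in cfg$datasets) {
    cons_path <- file.path(out, sprintf("conserved_%s.tsv", d$name))
    paths[[paste0("conserved_", d$name)]] <- cons_path
    if (resume && file.exists(cons_path)) {
      say("[conserve] %s: resumed from %s", d$name, cons_path)
      conserved[[d$name]] <- read_network(cons_path)
      next
    }
    ea <- read_expression_matrix(d$expr_a, d$name,
                                 d$species_a %||% "speciesA")
    eb <- read_expression_matrix(d$expr_b, d$name,
                                 d$species_b %||% "speciesB")
    san_a <- build_san(ea, read_probeset_gene_map(d$map_a),
                       fraction = cfg$fraction,
                       min_overlap = cfg$min_overlap,
                       min_samples = cfg$min_samples)
    san_b <- build_san(eb, read_probeset_gene_map(d$map_b),
                       fraction = cfg$fraction,
                       min_overlap = cfg$min_overlap,
                       min_samples = cfg$min_samples)
    for (side in list(list(n = san_a, f = "a"), list(n = san_b, f = "b"))) {
      sp <- file.path(out, sprintf("san_%s_%s.tsv", d$name, side$f))
      write_network(side$n, sp, extra_header = hdr("build-san"))
      paths[[sprintf("san_%s_%s", d$name, side$f)]] <- sp
    }
    cons <- build_conserved_network(san_a, san_b, orth)
    write_network(cons, cons_path, extra_header = hdr("conserve"))
    conserved[[d$name]] <- cons
    say("[conserve] %s: %d genes, %d conserved edges", d$name,
        length(cons$nodes), nrow(cons$edges))
  }

  # -- merge + clusters --------------------------------------------------
  merged_path <- file.path(out, "merged_network.tsv")
  merged <- merge_networks(conserved)
  write_network(merged, merged_path, extra_header = hdr("merge"))
  paths$merged <- merged_path
  clusters <- extract_all_cagcs(merged)
  cagc_path <- file.path(out, "cagcs.gmt")
  write_clusters(clusters, cagc_path, header_lines = hdr("clusters"))
  paths$cagcs <- cagc_path
  universe <- merged$nodes
  say("[merge] %d genes, %d edges; %d clusters", length(merged$nodes),
      nrow(merged$edges), length(clusters))

  # -- enrich ------------------------------------------------------------
  if (!is.null(cfg$annotation) && length(clusters)) {
    annot <- read_gene_sets(cfg$annotation, kind = "annotation")
    val <- validate_functional_coherence(
      merged, annot, universe = universe,
      n_perm = cfg$permutations, seed = derive_seed(cfg$seed, "enrich"))
    fi_path <- file.path(out, "functional_indices.tsv")
    write_tsv(data.frame(centre = names(val$real),
                         index = unname(val$real)),
              fi_path, header_lines = hdr("enrich"))
    ks_path <- file.path(out, "enrichment_summary.tsv")
    write_tsv(data.frame(ks_statistic = val$test$statistic,
                         ks_p_value = val$test$p_value,
                         n_clusters = val$test$n_real,
                         n_permutations = cfg$permutations),
              ks_path, header_lines = hdr("enrich"))
    paths$functional_indices <- fi_path
    paths$enrichment_summary <- ks_path
    say("[enrich] KS D=%.3f p=%.3g over %d clusters x %d permutations",
        val$test$statistic, val$test$p_value, val$test$n_real,
        cfg$permutations)
  }

  # -- phenoclusters + associate ----------------------------------------
  if (!is.null(cfg$phenotype_similarity) &&
      !is.null(cfg$phenotype_genes)) {
    sim <- read_similarity_matrix(cfg$phenotype_similarity)
    pheno_genes <- read_gene_sets(cfg$phenotype_genes,
                                  kind = "phenotype_association")
    phenos <- build_phenoclusters(sim, pheno_genes,
                                  threshold = cfg$sim_threshold)
    pc_path <- file.path(out, "phenoclusters.gmt")
    write_clusters(lapply(phenos, function(p)
      structure(list(centre = p$phenotype, members = p$genes),
                class = "cagc")),
      pc_path, header_lines = hdr("phenoclusters"))
    paths$phenoclusters <- pc_path
    if (!is.null(cfg$drug_targets)) {
      drugs <- read_drug_targets(cfg$drug_targets)
      assocs <- associate_drug_phenotypes(clusters, phenos, drugs,
                                          universe = universe,
                                          p_threshold = cfg$p_threshold)
      as_path <- file.path(out, "associations.tsv")
      write_tsv(assocs, as_path, header_lines = hdr("associate"))
      rp_path <- file.path(out, "rank_report.tsv")
      write_tsv(rank_report(assocs), rp_path,
                header_lines = hdr("associate"))
      paths$associations <- as_path
      paths$rank_report <- rp_path
      say("[associate] %d association(s) from %d test(s)", nrow(assocs),
          attr(assocs, "n_tests"))

      # -- validate-perturbation ----------------------------------------
      if (!is.null(cfg$rank_matrix) && !is.null(cfg$instances)) {
        prm <- read_rank_matrix(cfg$rank_matrix, cfg$instances)
        map_a <- read_probeset_gene_map(cfg$datasets[[1]]$map_a)
        vr <- run_validation(prm, map_a, clusters, drugs, fdr = cfg$fdr)
        vr_path <- file.path(out, "perturbation_results.tsv")
        write_tsv(vr$results, vr_path,
                  header_lines = hdr("validate-perturbation"))
        vs_path <- file.path(out, "perturbation_summary.tsv")
        write_tsv(vr$summary, vs_path,
                  header_lines = hdr("validate-perturbation"))
        paths$perturbation_results <- vr_path
        paths$perturbation_summary <- vs_path
        say("[validate-perturbation] %d tests, %d significant (%d up, %d down)",
            vr$summary$n_tests, vr$summary$n_significant,
            vr$summary$up, vr$summary$down)
      }
    }
  }
  invisible(paths)
}

# Internal: stable hash of the analytic configuration (inputs and
# thresholds; the output location is excluded so reruns into different
# directories share a hash), used in output provenance headers.
digest_config <- function(cfg) {
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}
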
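# S3 domain types shared by all pipeline stages.

#' Construct an expression matrix object
#'
#' Wraps a numeric probeset-by-sample matrix of normalized log-scale
#' expression values together with dataset provenance. Probesets whose
#' profile has zero variance (or fewer than two observed values) are flagged
#' at construction; they are retained in the object but excluded from
#' correlation downstream.
#'
#' @param values numeric matrix, rows = probesets, columns = samples; both
#'   dimnames required and unique. `NA` entries are permitted (correlations
#'   use pairwise-complete samples).
#' @param dataset_id text label for the dataset (e.g. a tissue name).
#' @param species text label for the species.
#' @return an object of class `expression_matrix` with elements `values`,
#'   `dataset_id`, `species` and `zero_variance` (character vector of flagged
#'   probeset IDs).
#' @export
expression_matrix <- function(values, dataset_id, species) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  ps <- rownames(values)
  sm <- colnames(values)
  if (is.null(ps) || is.null(sm))
    stop("`values` must carry probeset rownames and sample colnames")
  if (anyDuplicated(ps))
    stop("duplicate probeset ID(s): ",
         paste(unique(ps[duplicated(ps)]), collapse = ", "))
  if (anyDuplicated(sm))
    stop("duplicate sample ID(s): ",
         paste(unique(sm[duplicated(sm)]), collapse = ", "))
  v <- apply(values, 1, stats::var, na.rm = TRUE)
  nobs <- rowSums(!is.na(values))
  flagged <- ps[is.na(v) | v == 0 | nobs < 2]
  structure(
    list(values = values, dataset_id = as.character(dataset_id),
         species = as.character(species), zero_variance = flagged),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix '%s' (%s): %d probesets x %d samples",
              x$dataset_id, x$species, nrow(x$values), ncol(x$values)))
  if (length(x$zero_variance))
    cat(sprintf("; %d zero-variance probeset(s) flagged",
                length(x$zero_variance)))
  cat("\n")
  invisible(x)
}

#' Construct a probeset-to-gene mapping
#'
#' Many probesets may map to one gene; a probeset may map to zero genes
#' (gene `NA`), in which case it is retained in the map but excluded from
#' gene-level collapses.
#'
#' @param probeset,gene character vectors of equal length.
#' @return object of class `probeset_gene_map`: a data frame with columns
#'   `probeset` and `gene`, duplicate pairs removed.
#' @export
probeset_gene_map <- function(probeset, gene) {
  df <- data.frame(probeset = as.character(probeset),
                   gene = as.character(gene),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$probeset, df$gene, sep = "\001")), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("probeset_gene_map", "data.frame")
  df
}

#' Construct an orthology map with one-to-one flags
#'
#' @param gene_a,gene_b character vectors of equal length (species-A and
#'   species-B gene IDs).
#' @param one_to_one logical vector; pairs flagged `TRUE` must have their
#'   A-gene and B-gene each appearing in exactly one flagged pair.
#' @return object of class `orthology_map`.
#' @export
orthology_map <- function(gene_a, gene_b, one_to_one = TRUE) {
  df <- data.frame(gene_a = as.character(gene_a),
                   gene_b = as.character(gene_b),
                   one_to_one = as.logical(rep_len(one_to_one,
                                                   length(gene_a))),
                   stringsAsFactors = FALSE)
  oo <- df[df$one_to_one, , drop = FALSE]
  if (anyDuplicated(oo$gene_a) || anyDuplicated(oo$gene_b))
    stop("one-to-one flag violated: a flagged gene appears in more than ",
         "one flagged pair")
  rownames(df) <- NULL
  class(df) <- c("orthology_map", "data.frame")
  df
}

#' Construct an anti-coexpression network
#'
#' Undirected graph over probeset or gene IDs. Edges are stored canonically
#' (lexicographically ordered endpoints, no self-loops, no duplicates).
#'
#' @param edges 2-column character matrix or data frame of endpoints.
#' @param level `"probeset"` or `"gene"`.
#' @param species_scope single species label, or `"conserved"`.
#' @param provenance character vector of contributing dataset IDs.
#' @param id_space label declaring the identifier namespace of the nodes
#'   (used to refuse merging networks over different gene spaces).
#' @param nodes optional node set; defaults to the edge endpoints.
#' @return object of class `anticoex_network`.
#' @export
anticoex_network <- function(edges, level = c("probeset", "gene"),
                             species_scope = "unknown",
                             provenance = character(0),
                             id_space = species_scope,
                             nodes = NULL) {
  level <- match.arg(level)
  edges <- as.matrix(edges)
  if (nrow(edges) && ncol(edges) != 2)
    stop("`edges` must have two columns")
  e <- if (nrow(edges)) canonical_edges(edges[, 1], edges[, 2]) else
    matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
  nodes <- sort(unique(c(nodes, as.vector(e))))
  if (nrow(e) && !all(as.vector(e) %in% nodes))
    stop("edge endpoint outside the node set")
  structure(
    list(edges = e, nodes = nodes, level = level,
         species_scope = as.character(species_scope),
         id_space = as.character(id_space),
         provenance = as.character(provenance)),
    class = "anticoex_network")
}

#' @export
print.anticoex_network <- function(x, ...) {
  cat(sprintf("anticoex_network [%s, %s]: %d nodes, %d edges (%s)\n",
              x$level, x$species_scope, length(x$nodes), nrow(x$edges),
              if (length(x$provenance))
                paste(x$provenance, collapse = "+") else "no provenance"))
  invisible(x)
}

#' Construct a conserved anti-coexpressed gene cluster (CAGC)
#'
#' A CAGC is the neighbour set of its centre gene in the merged conserved
#' network; the centre itself is never a member.
#'
#' @param centre gene ID.
#' @param members character vector of member gene IDs.
#' @return object of class `cagc`.
#' @export
cagc <- function(centre, members) {
  centre <- as.character(centre)
  members <- sort(unique(as.character(members)))
  if (centre %in% members)
    stop("centre gene must not be a member of its own cluster")
  structure(list(centre = centre, members = members), class = "cagc")
}

#' @export
print.cagc <- function(x, ...) {
  cat(sprintf("CAGC centre %s: %d member(s)\n", x$centre, length(x$members)))
  invisible(x)
}

#' Construct a named gene-set collection
#'
#' @param sets named list of character vectors; set IDs must be unique and
#'   sets non-empty.
#' @param kind `"annotation"` (e.g. functional categories) or
#'   `"phenotype_association"` (phenotype-to-gene links).
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets,
                                kind = c("annotation",
                                         "phenotype_association")) {
  kind <- match.arg(kind)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set ID(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (any(lengths(sets) == 0))
    stop("empty set(s): ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  structure(list(sets = sets, kind = kind), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection (%s): %d sets, median size %g\n",
              x$kind, length(x$sets), stats::median(lengths(x$sets))))
  invisible(x)
}

#' Construct a phenotype similarity matrix
#'
#' Square symmetric matrix of text-mining similarity scores in \[0, 1\] over
#' phenotype IDs, with unit diagonal.
#'
#' @param mat numeric matrix with identical row and column phenotype names.
#' @return object of class `phenotype_similarity` (the validated matrix).
#' @export
phenotype_similarity <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat) || nrow(mat) != ncol(mat))
    stop("`mat` must be a square numeric matrix")
  if (is.null(rownames(mat)) || !identical(rownames(mat), colnames(mat)))
    stop("row and column phenotype IDs must be present and identical")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate phenotype ID(s)")
  if (any(is.na(mat)) || any(mat < 0) || any(mat > 1))
    stop("similarity scores must lie in [0, 1]")
  if (max(abs(mat - t(mat))) > 1e-8)
    stop("similarity matrix must be symmetric")
  if (max(abs(diag(mat) - 1)) > 1e-8)
    stop("similarity diagonal must equal 1")
  structure(mat, class = c("phenotype_similarity", "matrix"))
}

#' Construct a drug-target table
#'
#' @param drug,target character vectors; `action` an optional label per pair
#'   (e.g. `"inhibitor"`), defaulting to `"unknown"`. Duplicate
#'   (drug, target) pairs are an error.
#' @return object of class `drug_target_table`.
#' @export
drug_target_table <- function(drug, target, action = "unknown") {
  df <- data.frame(drug = as.character(drug),
                   target = as.character(target),
                   action = as.character(rep_len(action, length(drug))),
                   stringsAsFactors = FALSE)
  key <- paste(df$drug, df$target, sep = "\001")
  if (anyDuplicated(key))
    stop("duplicate (drug, target) pair(s)")
  rownames(df) <- NULL
  class(df) <- c("drug_target_table", "data.frame")
  df
}

#' Construct a perturbation rank matrix
#'
#' Probesets-by-instances table of integer ranks of case-versus-control
#' fold-changes: within each instance the ranks are a permutation of
#' `1..N` and a higher rank means a higher fold-change.
#'
#' @param ranks integer matrix, rows = probesets, columns = instance IDs.
#' @param metadata data frame with one row per instance: columns `instance`,
#'   `drug`, and optionally `concentration`, `cell_line`, `duration`.
#' @return object of class `perturbation_rank_matrix`.
#' @export
perturbation_rank_matrix <- function(ranks, metadata) {
  if (!is.matrix(ranks) || is.null(rownames(ranks)) || is.null(colnames(ranks)))
    stop("`ranks` must be a matrix with probeset rownames and instance colnames")
  n <- nrow(ranks)
  for (j in seq_len(ncol(ranks))) {
    if (!identical(sort(as.integer(ranks[, j])), seq_len(n)))
      stop(sprintf("instance '%s': ranks are not a permutation of 1..%d",
                   colnames(ranks)[j], n))
  }
  if (!all(c("instance", "drug") %in% names(metadata)))
    stop("metadata must have columns `instance` and `drug`")
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(colnames(ranks) %in% metadata$instance))
    stop("every rank-matrix instance needs a metadata row")
  structure(list(ranks = ranks,
                 metadata = metadata[match(colnames(ranks),
                                           metadata$instance), ,
                                     drop = FALSE]),
            class = "perturbation_rank_matrix")
}
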
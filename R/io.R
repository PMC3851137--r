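# Readers and writers for the tab-separated interchange formats.
# All files are UTF-8 TSV; lines starting with '#' are comments.

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of probeset IDs;
#' the body is numeric (empty cells or `NA` denote missing values).
#'
#' @param path file path.
#' @param dataset_id,species labels stored on the returned object.
#' @return an [expression_matrix] with zero-variance probesets flagged in
#'   its `zero_variance` element.
#' @export
read_expression_matrix <- function(path, dataset_id, species) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("expression TSV needs probeset + sample columns: ",
                          path)
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate probeset ID(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim(body)))
  bad <- which(is.na(num) & !is.na(body) &
                 !(trimws(body) %in% c("NA", "", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "malformed numeric cell '%s' at probeset '%s', sample '%s' in %s",
      body[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
      colnames(body)[bad[1, 2]], path))
  dimnames(num) <- list(ids, colnames(body))
  expression_matrix(num, dataset_id = dataset_id, species = species)
}

#' Read gene sets in GMT dialect
#'
#' One set per line: set ID, description, then member gene IDs, all
#' tab-separated. Sets declared with no members (only ID + description) are
#' dropped and counted in the `dropped` attribute of the result.
#'
#' @param path file path.
#' @param kind passed to [gene_set_collection()].
#' @return a [gene_set_collection]; attribute `dropped` holds the IDs of
#'   empty sets that were skipped.
#' @export
read_gene_sets <- function(path, kind = "annotation") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2)
  if (length(short))
    stop(sprintf("line %d of %s has fewer than 2 fields", short[1], path))
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate set ID(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  empty <- lengths(members) == 0
  coll <- gene_set_collection(stats::setNames(members[!empty], ids[!empty]),
                              kind = kind)
  attr(coll, "dropped") <- ids[empty]
  coll
}

#' Write CAGCs (or any gene sets) in GMT dialect
#'
#' Each cluster becomes one line `centre<TAB>.<TAB>member...`, so that the
#' output round-trips through [read_gene_sets()] with identical member sets.
#'
#' @param clusters list of [cagc] objects.
#' @param path output file path.
#' @param header_lines optional '#'-prefixed provenance comments.
#' @export
write_clusters <- function(clusters, path, header_lines = character(0)) {
  lines <- vapply(clusters, function(cl) {
    paste(c(cl$centre, ".", cl$members), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(lines, con)
  invisible(path)
}

#' Read a probeset-to-gene map from a two-column TSV
#'
#' Columns: probeset ID, gene ID. An empty gene field marks an unmapped
#' probeset (kept in the map, excluded from gene-level collapses).
#'
#' @param path file path.
#' @return a [probeset_gene_map].
#' @export
read_probeset_gene_map <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (ncol(df) < 2) stop("probeset-gene map needs 2 columns: ", path)
  gene <- df[[2]]
  gene[!nzchar(trimws(gene))] <- NA_character_
  probeset_gene_map(df[[1]], gene)
}

#' Read an orthology map from TSV
#'
#' Columns: species-A gene, species-B gene, and optionally a `one_to_one`
#' flag (TRUE/FALSE or 1/0; defaults to TRUE).
#'
#' @param path file path.
#' @return an [orthology_map].
#' @export
read_orthology_map <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (ncol(df) < 2) stop("orthology map needs >= 2 columns: ", path)
  flag <- if (ncol(df) >= 3) as.logical(toupper(df[[3]]) %in%
                                          c("TRUE", "T", "1")) else TRUE
  orthology_map(df[[1]], df[[2]], flag)
}

#' Read a phenotype similarity matrix from TSV
#'
#' Square table with a header row and first column of phenotype IDs.
#'
#' @param path file path.
#' @return a [phenotype_similarity] matrix.
#' @export
read_similarity_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  phenotype_similarity(m)
}

#' Read a drug-target table from TSV
#'
#' Columns: drug ID, target gene ID, and optionally an action label.
#'
#' @param path file path.
#' @return a [drug_target_table].
#' @export
read_drug_targets <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (ncol(df) < 2) stop("drug-target table needs >= 2 columns: ", path)
  action <- if (ncol(df) >= 3) df[[3]] else "unknown"
  drug_target_table(df[[1]], df[[2]], action)
}

#' Read a perturbation rank matrix and its instance metadata
#'
#' The rank TSV has a header row of instance IDs and a first column of
#' probeset IDs; each instance column must be a permutation of `1..N`.
#' The metadata TSV has columns `instance`, `drug`, and optionally
#' `concentration`, `cell_line`, `duration`.
#'
#' @param path rank-matrix TSV path.
#' @param metadata_path instance-metadata TSV path.
#' @return a [perturbation_rank_matrix].
#' @export
read_rank_matrix <- function(path, metadata_path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  meta <- read_tsv(metadata_path, colClasses = "character")
  perturbation_rank_matrix(m, meta)
}

#' Write a network as a two-column TSV edge list
#'
#' A '#'-prefixed header records level, scope and provenance so that
#' [read_network()] can restore them.
#'
#' @param net an [anticoex_network].
#' @param path output path.
#' @param extra_header additional comment lines.
#' @export
write_network <- function(net, path, extra_header = character(0)) {
  hdr <- c(sprintf("level: %s", net$level),
           sprintf("species_scope: %s", net$species_scope),
           sprintf("id_space: %s", net$id_space),
           sprintf("provenance: %s", paste(net$provenance, collapse = ",")),
           extra_header)
  write_tsv(as.data.frame(net$edges, stringsAsFactors = FALSE), path,
            header_lines = hdr)
}

#' Read a network written by [write_network()]
#'
#' @param path edge-list TSV path.
#' @return an [anticoex_network].
#' @export
read_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key, default) {
    hit <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[1]) else default
  }
  df <- read_tsv(path, colClasses = "character")
  prov <- field("provenance", "")
  anticoex_network(
    as.matrix(df[, 1:2, drop = FALSE]),
    level = field("level", "gene"),
    species_scope = field("species_scope", "unknown"),
    id_space = field("id_space", field("species_scope", "unknown")),
    provenance = if (nzchar(prov)) strsplit(prov, ",")[[1]] else character(0))
}
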
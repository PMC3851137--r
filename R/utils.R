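# Internal helpers shared across the pipeline stages.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Fan a master seed out to stage/replicate seeds deterministically.
# `what` may be an integer offset or a character label. Result stays inside
# the 32-bit signed range required by set.seed().
derive_seed <- function(master, what) {
  off <- if (is.character(what)) sum(utf8ToInt(what)) else as.numeric(what)
  as.integer((as.numeric(master) %% 259993L * 7919 + off) %% 2147483629)
}

# Canonical undirected edge table: lexicographically ordered endpoint pairs,
# self-loops dropped, duplicates removed. Returns a 2-column character matrix.
canonical_edges <- function(from, to) {
  from <- as.character(from)
  to <- as.character(to)
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  a <- pmin(from, to)
  b <- pmax(from, to)
  e <- cbind(a, b)[!duplicated(paste(a, b, sep = "\001")), , drop = FALSE]
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  dimnames(e) <- list(NULL, c("from", "to"))
  e
}

edge_keys <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  paste(edges[, 1], edges[, 2], sep = "\001")
}

# Adjacency list (node -> character vector of neighbours) from an undirected
# canonical edge matrix.
adjacency_list <- function(edges, nodes) {
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  out <- vector("list", length(nodes))
  names(out) <- nodes
  out[names(adj)] <- adj
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "", ...)
}

# Write a data frame as TSV with '#'-prefixed provenance header lines.
write_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
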
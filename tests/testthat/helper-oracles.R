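# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct summations, exhaustive enumerations and
# plain loops.

# Hypergeometric upper-tail P(X >= ov) by direct log-factorial summation.
hyper_tail_oracle <- function(ov, set_size, universe_size, cluster_size) {
  lfact <- function(x) lgamma(x + 1)
  lch <- function(n, k) lfact(n) - lfact(k) - lfact(n - k)
  ks <- seq(ov, min(set_size, cluster_size))
  if (!length(ks) || ov <= 0) return(1)
  sum(exp(lch(set_size, ks) +
            lch(universe_size - set_size, cluster_size - ks) -
            lch(universe_size, cluster_size)))
}

# Exhaustive two-sided Mann-Whitney p-value: enumerate every assignment of
# the pooled ranks to the two groups and count configurations at least as
# extreme (U at least as far from its null mean) as observed.
mw_enum_oracle <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n <- length(x)
  mid <- n * length(y) / 2
  obs <- abs(u_stat(x, y) - mid)
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2, function(ix)
    u_stat(pooled[ix], pooled[-ix]))
  mean(abs(us - mid) >= obs - 1e-9)
}

# Per-pair Pearson correlation from the definition, complete pairs only.
pearson_oracle <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Monolithic brute-force reimplementation of the whole network pipeline:
# full per-pair correlation -> per-column full sort -> reciprocity ->
# gene collapse -> orthology triple-condition. Returns sorted edge keys of
# the conserved network (species-A gene IDs).
brute_force_conserved <- function(values_a, values_b, map_a, map_b,
                                  orth, fraction) {
  san <- function(values, map) {
    keep <- apply(values, 1, function(r) stats::var(r, na.rm = TRUE) > 0)
    values <- values[keep, , drop = FALSE]
    ids <- rownames(values)
    n <- length(ids)
    cc <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) for (j in seq_len(n))
      cc[i, j] <- pearson_oracle(values[i, ], values[j, ])
    k <- max(1, floor(fraction * (n - 1)))
    directed <- character(0)
    for (j in seq_len(n)) {
      v <- cc[, j]; v[j] <- NA
      cand <- data.frame(id = ids, v = v)[!is.na(v) & v < 0, ]
      cand <- cand[order(cand$v, cand$id), ]
      sel <- head(cand$id, k)
      directed <- c(directed, paste(sel, ids[j], sep = ">"))
    }
    und <- character(0)
    for (d in directed) {
      pq <- strsplit(d, ">")[[1]]
      if (paste(pq[2], pq[1], sep = ">") %in% directed)
        und <- c(und, paste(sort(pq), collapse = "|"))
    }
    und <- unique(und)
    gene_of <- split(map$gene[!is.na(map$gene)],
                     map$probeset[!is.na(map$gene)])
    ge <- character(0)
    for (u in und) {
      pq <- strsplit(u, "\\|")[[1]]
      for (g1 in gene_of[[pq[1]]]) for (g2 in gene_of[[pq[2]]])
        if (!is.null(g1) && !is.null(g2) && g1 != g2)
          ge <- c(ge, paste(sort(c(g1, g2)), collapse = "|"))
    }
    unique(ge)
  }
  ge_a <- san(values_a, map_a)
  ge_b <- san(values_b, map_b)
  oo <- orth[orth$one_to_one, ]
  b_of <- stats::setNames(oo$gene_b, oo$gene_a)
  kept <- character(0)
  for (e in ge_a) {
    g <- strsplit(e, "\\|")[[1]]
    if (all(g %in% names(b_of)) &&
        paste(sort(c(b_of[[g[1]]], b_of[[g[2]]])), collapse = "|") %in% ge_b)
      kept <- c(kept, e)
  }
  sort(kept)
}

# Edge keys of a package network in the oracle's "a|b" form.
net_edge_keys <- function(net) {
  if (nrow(net$edges) == 0) return(character(0))
  sort(paste(net$edges[, 1], net$edges[, 2], sep = "|"))
}

# Small deterministic expression matrix for reader/unit tests.
tiny_expr <- function(values, dataset_id = "toy", species = "sp") {
  expression_matrix(values, dataset_id, species)
}

# Write a matrix as the expression TSV dialect.
write_expr_tsv <- function(values, path) {
  df <- data.frame(probeset = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}
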
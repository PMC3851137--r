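# Network construction: correlation, bottom-percentile directed edges,
# reciprocity, gene collapse, conservation, merging and CAGC extraction.

test_that("correlation matrix matches the per-pair Pearson definition", {
  # perfect anti-correlation and the diagonal
  x <- c(1, 2, 3, 5, 4)
  m <- rbind(p1 = x, p2 = -x)
  colnames(m) <- paste0("s", 1:5)
  cc <- correlation_matrix(tiny_expr(m))
  expect_equal(cc["p1", "p2"], -1)
  expect_equal(diag(cc), c(p1 = 1, p2 = 1))

  # seeded Gaussian block against the independent per-pair formula
  set.seed(13)
  g <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(sprintf("p%02d", 1:50), paste0("s", 1:20)))
  cc <- correlation_matrix(tiny_expr(g))
  for (pair in list(c(1, 2), c(3, 47), c(25, 26), c(10, 50))) {
    expect_equal(cc[pair[1], pair[2]],
                 pearson_oracle(g[pair[1], ], g[pair[2], ]),
                 tolerance = 1e-12)
  }
  full <- outer(rownames(g), rownames(g),
                Vectorize(function(a, b) pearson_oracle(g[a, ], g[b, ])))
  expect_equal(matrix(cc, nrow(cc)), full, tolerance = 1e-12)
})

test_that("correlation refuses degenerate inputs and records undefined pairs", {
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("p1", "p2"), paste0("s", 1:3)))
  expect_error(correlation_matrix(tiny_expr(m)), "requires >= 4")

  const <- matrix(1, 3, 5, dimnames = list(paste0("p", 1:3),
                                           paste0("s", 1:5)))
  expect_error(correlation_matrix(tiny_expr(const)), "non-constant")

  # a pair with fewer than min_overlap complete samples is undefined
  m <- matrix(rnorm(24), 3, 8,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:8)))
  m[1, 1:3] <- NA
  m[2, 6:8] <- NA
  cc <- correlation_matrix(tiny_expr(m), min_overlap = 4)
  expect_true(is.na(cc["p1", "p2"]))
  expect_false(is.na(cc["p1", "p3"]))
})

test_that("directed anti-correlation edges equal a full-sort oracle", {
  # N = 101, fraction 0.01 -> k = 1: only the single most anti-correlated
  set.seed(7)
  n <- 101
  cc <- stats::cor(matrix(rnorm(40 * n), 40, n))
  dimnames(cc) <- list(sprintf("p%03d", 1:n), sprintf("p%03d", 1:n))
  d <- directed_anticorr_edges(cc, fraction = 0.01)
  expect_equal(nrow(d), n)  # k = 1, every column has a negative value here
  for (j in sample(n, 10)) {
    v <- cc[, j]; v[j] <- NA
    expect_equal(unname(d[d[, "to"] == colnames(cc)[j], "from"]),
                 names(which.min(v)))
  }

  # a column with no negative correlation receives no incoming edges
  cc2 <- matrix(c(1, 0.2, 0.3,
                  0.2, 1, -0.5,
                  0.3, -0.5, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d2 <- directed_anticorr_edges(cc2, fraction = 0.5)
  expect_false("a" %in% d2[, "to"])
  expect_setequal(d2[d2[, "to"] == "c", "from"], "b")

  # 100 x 100 seeded table vs an oracle that fully sorts each column
  set.seed(99)
  cc3 <- stats::cor(matrix(rnorm(30 * 100), 30, 100))
  dimnames(cc3) <- list(sprintf("q%03d", 1:100), sprintf("q%03d", 1:100))
  frac <- 0.05
  d3 <- directed_anticorr_edges(cc3, fraction = frac)
  k <- max(1, floor(frac * 99))
  oracle <- do.call(rbind, lapply(seq_len(100), function(j) {
    v <- cc3[, j]; v[j] <- NA
    ord <- order(v, names(v))
    sel <- names(v)[ord][seq_len(k)]
    sel <- sel[v[sel] < 0]
    if (!length(sel)) return(NULL)
    cbind(from = sel, to = colnames(cc3)[j])
  }))
  expect_setequal(paste(d3[, 1], d3[, 2]), paste(oracle[, 1], oracle[, 2]))

  expect_error(directed_anticorr_edges(cc2, fraction = 0), "between 0 and 1")
  expect_error(directed_anticorr_edges(cc2, fraction = 1), "between 0 and 1")
})

test_that("reciprocal filter keeps exactly the mutually ranked pairs", {
  d <- rbind(c("a", "b"), c("b", "a"), c("a", "c"))
  net <- reciprocal_undirected(d)
  expect_equal(net$edges, canonical_edges("a", "b"))

  empty <- reciprocal_undirected(matrix(character(0), 0, 2))
  expect_equal(nrow(empty$edges), 0L)

  # every undirected edge has both directed parents (property over random
  # directed edge sets)
  set.seed(5)
  for (rep in 1:5) {
    ids <- sprintf("p%02d", 1:15)
    dd <- cbind(sample(ids, 60, TRUE), sample(ids, 60, TRUE))
    dd <- dd[dd[, 1] != dd[, 2], , drop = FALSE]
    net <- reciprocal_undirected(dd)
    fwd <- paste(dd[, 1], dd[, 2])
    if (nrow(net$edges)) {
      expect_true(all(paste(net$edges[, 1], net$edges[, 2]) %in% fwd))
      expect_true(all(paste(net$edges[, 2], net$edges[, 1]) %in% fwd))
    }
  }
})

test_that("a planted anti-correlated pair is recovered as a reciprocal edge", {
  set.seed(21)
  z <- rnorm(30)
  m <- rbind(matrix(rnorm(40 * 30), 40, 30), A = z, B = -z + rnorm(30, sd = 0.05))
  rownames(m)[1:40] <- sprintf("n%02d", 1:40)
  colnames(m) <- sprintf("s%02d", 1:30)
  cc <- correlation_matrix(tiny_expr(m))
  net <- reciprocal_undirected(directed_anticorr_edges(cc, fraction = 0.03))
  expect_true(paste("A", "B", sep = "\001") %in%
                paste(net$edges[, 1], net$edges[, 2], sep = "\001"))
})

test_that("gene collapse spans probeset sets and drops within-gene edges", {
  mp <- probeset_gene_map(c("p1", "p2", "p3", "p4"),
                          c("g1", "g2", "g1", NA))
  net <- anticoex_network(rbind(c("p1", "p2")), level = "probeset")
  ge <- collapse_to_genes(net, mp)
  expect_equal(ge$edges, canonical_edges("g1", "g2"))

  # both probesets on one gene -> no self-loop
  net2 <- anticoex_network(rbind(c("p1", "p3")), level = "probeset")
  expect_equal(nrow(collapse_to_genes(net2, mp)$edges), 0L)

  # unmapped probeset contributes nothing
  net3 <- anticoex_network(rbind(c("p1", "p4")), level = "probeset")
  expect_equal(nrow(collapse_to_genes(net3, mp)$edges), 0L)

  # random probeset net + random many-to-one map vs exhaustive iteration
  set.seed(31)
  probes <- sprintf("p%02d", 1:40)
  genes <- sprintf("g%02d", 1:12)
  mp2 <- probeset_gene_map(probes, sample(genes, 40, TRUE))
  e <- cbind(sample(probes, 50, TRUE), sample(probes, 50, TRUE))
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  net4 <- anticoex_network(e, level = "probeset")
  got <- collapse_to_genes(net4, mp2)
  gene_of <- stats::setNames(mp2$gene, mp2$probeset)
  want <- character(0)
  for (i in seq_len(nrow(net4$edges))) {
    g1 <- gene_of[[net4$edges[i, 1]]]
    g2 <- gene_of[[net4$edges[i, 2]]]
    if (g1 != g2) want <- c(want, paste(sort(c(g1, g2)), collapse = "|"))
  }
  expect_setequal(net_edge_keys(got), unique(want))
})

test_that("conservation requires both networks and one-to-one orthology", {
  orth <- orthology_map(c("a1", "a2", "a3"), c("b1", "b2", "b3"), TRUE)
  na <- anticoex_network(rbind(c("a1", "a2"), c("a1", "a3")),
                         level = "gene", id_space = "A")
  nb <- anticoex_network(rbind(c("b1", "b2")), level = "gene",
                         id_space = "B")
  cons <- build_conserved_network(na, nb, orth)
  expect_equal(net_edge_keys(cons), "a1|a2")

  # one endpoint lacking a one-to-one ortholog drops the edge
  orth2 <- orthology_map(c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                         c(TRUE, FALSE, TRUE))
  expect_equal(nrow(build_conserved_network(na, nb, orth2)$edges), 0L)

  # random networks + partial orthology vs the triple-condition oracle
  set.seed(17)
  ga <- sprintf("a%02d", 1:20)
  gb <- sprintf("b%02d", 1:20)
  flag <- runif(20) < 0.7
  orth3 <- orthology_map(ga, gb, flag)
  mk <- function(g, m) {
    e <- cbind(sample(g, m, TRUE), sample(g, m, TRUE))
    anticoex_network(e[e[, 1] != e[, 2], , drop = FALSE], level = "gene",
                     id_space = substr(g[1], 1, 1))
  }
  na3 <- mk(ga, 40); nb3 <- mk(gb, 40)
  got <- build_conserved_network(na3, nb3, orth3)
  b_of <- stats::setNames(gb[flag], ga[flag])
  bkeys <- net_edge_keys(nb3)
  want <- character(0)
  for (i in seq_len(nrow(na3$edges))) {
    g <- na3$edges[i, ]
    if (all(g %in% names(b_of)) &&
        paste(sort(b_of[g]), collapse = "|") %in% bkeys)
      want <- c(want, paste(sort(g), collapse = "|"))
  }
  expect_setequal(net_edge_keys(got), want)
  # conservation can only remove species-A edges
  expect_true(all(net_edge_keys(got) %in% net_edge_keys(na3)))
})

test_that("merging unions nodes, edges and provenance; refuses mixed spaces", {
  n1 <- anticoex_network(rbind(c("a", "b")), level = "gene",
                         id_space = "X", provenance = "d1")
  n2 <- anticoex_network(rbind(c("b", "c")), level = "gene",
                         id_space = "X", provenance = "d2")
  m <- merge_networks(list(n1, n2))
  expect_setequal(net_edge_keys(m), c("a|b", "b|c"))
  expect_setequal(m$provenance, c("d1", "d2"))

  expect_equal(net_edge_keys(merge_networks(list(n1))), "a|b")
  expect_equal(net_edge_keys(merge_networks(list(n1, n1))), "a|b")

  n3 <- anticoex_network(rbind(c("x", "y")), level = "gene",
                         id_space = "Y")
  expect_error(merge_networks(list(n1, n3)), "different ID spaces")
})

test_that("CAGC extraction returns the exact neighbour set, centre excluded", {
  star <- anticoex_network(rbind(c("c", "x"), c("c", "y"), c("c", "z")),
                           level = "gene")
  cl <- extract_cagc(star, "c")
  expect_equal(cl$centre, "c")
  expect_setequal(cl$members, c("x", "y", "z"))
  expect_false("c" %in% cl$members)
  expect_error(extract_cagc(star, "w"), "not a node")

  # symmetry property: b in CAGC(a) iff a in CAGC(b), over a random net
  set.seed(3)
  e <- cbind(sample(letters[1:12], 30, TRUE), sample(letters[1:12], 30, TRUE))
  net <- anticoex_network(e[e[, 1] != e[, 2], , drop = FALSE],
                          level = "gene")
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges[i, 1]; b <- net$edges[i, 2]
    expect_true(b %in% extract_cagc(net, a)$members)
    expect_true(a %in% extract_cagc(net, b)$members)
  }
})

test_that("the staged pipeline equals the monolithic brute-force oracle", {
  spec <- fixture_spec(seed = 19, n_genes = 30, probesets_per_gene = 2L,
                       n_samples = 12, n_modules = 2, module_size = 4,
                       sigma = 0.4)
  fx <- make_expression_pair(spec)
  frac <- 0.08
  pl <- run_fixture_pipeline(fx, fraction = frac)
  want <- brute_force_conserved(fx$expr_a$values, fx$expr_b$values,
                                fx$map_a, fx$map_b, fx$orthology, frac)
  expect_equal(net_edge_keys(pl$conserved), want)
})
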
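# Functional-coherence machinery: hypergeometric enrichment, functional
# indices, permuted null networks, distribution comparison, and the
# centre-concordance summaries.

test_that("fisher_enrichment equals the hypergeometric tail-summation oracle", {
  universe <- sprintf("g%03d", 1:100)

  # zero overlap: P(X >= 0) = 1
  fe <- fisher_enrichment(universe[1:10], universe[51:60], universe[1:50])
  expect_equal(fe$overlap, 0L)
  expect_equal(fe$p_value, 1)

  # the worked 100/10/20/overlap-5 table against direct summation
  cl <- universe[1:10]
  ann <- c(universe[6:10], universe[21:35])  # overlap 5, set size 20
  fe <- fisher_enrichment(cl, ann, universe)
  expect_equal(fe$overlap, 5L)
  expect_equal(fe$p_value, hyper_tail_oracle(5, 20, 100, 10),
               tolerance = 1e-12)

  # degenerate: cluster = set = universe forces the overlap, p = 1
  fe <- fisher_enrichment(universe, universe, universe)
  expect_equal(fe$p_value, 1)

  # random tables within 1e-9 relative error of the oracle
  set.seed(77)
  for (i in 1:200) {
    N <- sample(20:400, 1)
    u <- sprintf("u%04d", seq_len(N))
    cl <- sample(u, sample(1:min(40, N), 1))
    ann <- sample(u, sample(1:min(60, N), 1))
    fe <- fisher_enrichment(cl, ann, u)
    want <- hyper_tail_oracle(fe$overlap, fe$set_size, N, fe$cluster_size)
    expect_equal(fe$p_value, want, tolerance = 1e-9)
  }
})

test_that("functional index is the minimum enrichment p across sets", {
  universe <- sprintf("g%03d", 1:60)
  cl <- cagc("c1", universe[1:8])

  single <- gene_set_collection(list(S = universe[1:8]))
  fi <- functional_index(cl, single, universe)
  expect_equal(as.numeric(fi),
               fisher_enrichment(cl$members, universe[1:8],
                                 universe)$p_value)
  expect_equal(attr(fi, "best_sets"), "S")

  # cluster disjoint from every set -> index 1
  far <- gene_set_collection(list(S1 = universe[40:45],
                                  S2 = universe[50:55]))
  expect_equal(as.numeric(functional_index(cl, far, universe)), 1)

  # no set overlapping the universe at all -> 1 with warning
  alien <- gene_set_collection(list(S = c("x1", "x2")))
  expect_warning(fi <- functional_index(cl, alien, universe), "index = 1")
  expect_equal(as.numeric(fi), 1)

  # 20 seeded random sets: min over independent per-set oracle values
  set.seed(55)
  sets <- lapply(1:20, function(i) sample(universe, sample(3:20, 1)))
  names(sets) <- sprintf("S%02d", 1:20)
  coll <- gene_set_collection(sets)
  fi <- functional_index(cl, coll, universe)
  per_set <- vapply(sets, function(s) {
    ov <- length(intersect(cl$members, s))
    hyper_tail_oracle(ov, length(s), 60, length(cl$members))
  }, numeric(1))
  expect_equal(as.numeric(fi), min(per_set), tolerance = 1e-12)
  expect_true(all(functional_indices(list(cl), coll, universe) ==
                    as.numeric(fi)))
})

test_that("node-label permutation preserves topology and is seed-deterministic", {
  one <- anticoex_network(rbind(c("a", "b")), level = "gene")
  p1 <- permuted_network(one, seed = 4)
  expect_equal(nrow(p1$edges), 1L)
  expect_setequal(as.vector(p1$edges), c("a", "b"))

  set.seed(9)
  e <- cbind(sample(letters[1:15], 40, TRUE), sample(letters[1:15], 40, TRUE))
  net <- anticoex_network(e[e[, 1] != e[, 2], , drop = FALSE],
                          level = "gene")
  degree <- function(n) {
    d <- table(as.vector(n$edges))
    sort(as.integer(d))
  }
  pn <- permuted_network(net, seed = 123)
  expect_equal(nrow(pn$edges), nrow(net$edges))
  expect_equal(degree(pn), degree(net))
  expect_setequal(pn$nodes, net$nodes)

  expect_identical(permuted_network(net, seed = 123)$edges, pn$edges)
  perms <- vapply(1:10, function(s)
    paste(permuted_network(net, seed = s)$edges, collapse = ","),
    character(1))
  expect_gt(length(unique(perms)), 1)
})

test_that("index distribution test matches an empirical-CDF oracle", {
  expect_equal(index_distribution_test(1:10 / 10,
                                       list(1:10 / 10))$statistic, 0)

  disj <- index_distribution_test(rep(1e-6, 20), list(rep(1, 20)))
  expect_equal(disj$statistic, 1)

  set.seed(2)
  a <- runif(80)
  b <- list(runif(50, 0.2, 1.2), runif(50, 0.2, 1.2))
  got <- index_distribution_test(a, b)
  pooled <- unlist(b)
  grid <- sort(c(a, pooled))
  sup <- max(abs(vapply(grid, function(t) mean(a <= t) - mean(pooled <= t),
                        numeric(1))))
  expect_equal(got$statistic, sup, tolerance = 1e-12)
  expect_equal(got$band$cdf_perm_mean,
               (ecdf(b[[1]])(got$band$threshold) +
                  ecdf(b[[2]])(got$band$threshold)) / 2)
  expect_error(index_distribution_test(numeric(0), list(1)), "no real")
})

test_that("centre keyword concordance counts Bonferroni-significant clusters", {
  universe <- sprintf("g%03d", 1:200)
  mk_results <- function(centre, p) {
    data.frame(centre = centre, set_id = sprintf("S%d", seq_along(p)),
               p_value = p, stringsAsFactors = FALSE)
  }
  annot <- gene_set_collection(list(S1 = c("c1", universe[1:5]),
                                    S2 = universe[6:10]))

  # centre annotated to the sole significant set -> 1.0
  res <- mk_results("c1", c(1e-6, 0.8))
  cc <- centre_keyword_concordance(res, annot)
  expect_equal(cc$fraction, 1.0)

  # centre annotated to none of the significant sets -> 0.0
  res <- mk_results("c9", c(1e-6, 0.8))
  expect_equal(centre_keyword_concordance(res, annot)$fraction, 0.0)

  # nothing significant -> flagged empty
  res <- mk_results("c1", c(0.5, 0.9))
  cc <- centre_keyword_concordance(res, annot)
  expect_false(cc$applicable)
  expect_true(is.na(cc$fraction))

  # 10 constructed clusters, 6 with the centre inside the significant set
  centres <- sprintf("c%02d", 1:10)
  sets <- lapply(1:10, function(i) {
    if (i <= 6) c(centres[i], universe[(i * 5):(i * 5 + 3)])
    else universe[(i * 5):(i * 5 + 3)]
  })
  names(sets) <- sprintf("K%02d", 1:10)
  annot10 <- gene_set_collection(sets)
  res10 <- do.call(rbind, lapply(1:10, function(i)
    data.frame(centre = centres[i], set_id = names(sets)[i],
               p_value = 1e-8, stringsAsFactors = FALSE)))
  cc <- centre_keyword_concordance(res10, annot10)
  expect_equal(cc$n_significant_clusters, 10L)
  expect_equal(cc$fraction, 0.6)
})

test_that("centre-member phenotype similarity scans pairs with a closed bound", {
  ids <- c("P1", "P2", "P3")
  s <- matrix(c(1, 0.35, 0.2,
                0.35, 1, 0.4,
                0.2, 0.4, 1), 3, 3, dimnames = list(ids, ids))
  sim <- phenotype_similarity(s)

  got <- centre_phenotype_similarity("P1", "P2", sim)
  expect_equal(got$max_score, 0.35)
  expect_false(got$reached_threshold)

  # a score exactly at the threshold counts as reaching it
  got <- centre_phenotype_similarity("P2", "P3", sim)
  expect_equal(got$max_score, 0.4)
  expect_true(got$reached_threshold)

  expect_false(centre_phenotype_similarity(character(0), "P1",
                                           sim)$applicable)
  expect_error(centre_phenotype_similarity("P9", "P1", sim), "absent")

  # exhaustive scan oracle on a random submatrix
  set.seed(10)
  n <- 6
  m <- matrix(runif(n * n, 0, 0.9), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  dimnames(m) <- list(sprintf("Q%d", 1:n), sprintf("Q%d", 1:n))
  sim2 <- phenotype_similarity(m)
  ctr <- c("Q1", "Q2"); mem <- c("Q4", "Q5", "Q6")
  want <- max(vapply(ctr, function(a)
    max(vapply(mem, function(b) m[a, b], numeric(1))), numeric(1)))
  expect_equal(centre_phenotype_similarity(ctr, mem, sim2)$max_score, want)
})

test_that("real indices stochastically dominate permuted ones on aligned sets", {
  net <- make_random_network(120, 420, seed = 31)
  sets <- make_annotation_sets(net, n_sets = 60, seed = 32)
  val <- validate_functional_coherence(net, sets, n_perm = 5, seed = 33)
  expect_lt(val$test$p_value, 0.01)
  # left-shifted: real median index far below permuted median
  expect_lt(median(val$real), median(unlist(val$permuted)))
})
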
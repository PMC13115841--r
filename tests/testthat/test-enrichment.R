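test_that("hypergeometric upper tail matches brute-force enumeration for N <= 12", {
  expect_equal(hypergeom_pvalue(0, 3, 4, 10), 1)
  expect_equal(hypergeom_pvalue(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(5, 5, 5, 5), 1)  # degenerate certainty
  set.seed(3)
  for (i in 1:40) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_pvalue(k, K, n, N), oracle_hypergeom(k, K, n, N),
                 tolerance = 1e-12,
                 label = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
  }
  expect_error(hypergeom_pvalue(5, 4, 5, 10), "min")
  expect_error(hypergeom_pvalue(1, 11, 5, 10), "exceed")
})

test_that("BH adjustment equals the hand step-up and is idempotent-monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:15, 1))
    fdr <- bh_adjust(p)
    expect_equal(fdr, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(fdr) >= fdr - 1e-15))
    expect_true(all(fdr >= p))
  }
})

test_that("ORA applies the size filter on the universe-restricted sets", {
  universe <- sprintf("u%02d", 1:10)
  coll <- list(too_small = universe[1:2],
               too_big = universe,
               ok = universe[1:4])
  tab <- pathway_ora(universe[1:5], coll, universe, min_size = 3, max_size = 6)
  expect_equal(tab$set, "ok")
  # row carries the oracle p for (k=3, K=4, n=5, N=10)? k = |{u1..u4} ∩ {u1..u5}| = 4
  expect_equal(tab$k, 4)
  expect_equal(tab$p, hypergeom_pvalue(4, 4, 5, 10))

  # embedded toy: pathway of size 4 with overlap 3 out of a 5-gene query
  coll2 <- list(pw = universe[c(1, 2, 3, 10)])
  tab2 <- pathway_ora(universe[1:5], coll2, universe, min_size = 3)
  expect_equal(tab2$p, 66 / 252, tolerance = 1e-12)
  expect_equal(tab2$overlap, "u01,u02,u03")

  # row count depends only on size eligibility, not query content
  tab3 <- pathway_ora(universe[9], coll, universe, min_size = 3, max_size = 6)
  expect_equal(nrow(tab3), 1)
  expect_error(pathway_ora("x", coll, character()), "universe")
})

test_that("query genes outside the universe are dropped with a message", {
  universe <- sprintf("u%02d", 1:8)
  coll <- list(pw = universe[1:4])
  expect_message(tab <- pathway_ora(c(universe[1:3], "alien"), coll, universe),
                 "outside")
  expect_equal(tab$n, 3)
})

test_that("overlap coefficient and meta-pathway clustering behave on fixtures", {
  expect_equal(overlap_coefficient(letters[1:4], letters[c(1, 2, 5:8)]), 0.5)
  expect_equal(overlap_coefficient(letters[1:3], letters[1:3]), 1)
  expect_equal(overlap_coefficient(letters[1:3], letters[4:6]), 0)

  universe <- sprintf("g%02d", 1:40)
  # two tight families of pathways plus cross-family leakage
  fam1 <- lapply(1:3, function(i) universe[c(1:8, 8 + i)])
  fam2 <- lapply(1:3, function(i) universe[c(21:28, 28 + i)])
  coll <- c(fam1, fam2)
  names(coll) <- sprintf("pw%d", 1:6)
  query <- universe[c(1:8, 21:28)]
  tab <- pathway_ora(query, coll, universe)
  expect_true(all(tab$fdr < 0.05))
  meta <- meta_pathways(tab, coll, min_network_genes = 3, fdr_max = 0.05)
  cl <- meta$clusters
  expect_equal(length(unique(cl[c("pw1", "pw2", "pw3")])), 1)
  expect_equal(length(unique(cl[c("pw4", "pw5", "pw6")])), 1)
  expect_true(cl[["pw1"]] != cl[["pw4"]])
  # within-family coefficient is 8/9, across 0: any threshold below 8/9
  # separates the families; the sweep must sit in that window
  expect_lt(meta$threshold, 8 / 9)
  expect_equal(meta$Q, max(meta$objective))
})

test_that("identical sets cluster together; disjoint sets never do", {
  universe <- sprintf("g%02d", 1:30)
  coll <- list(a1 = universe[1:6], a2 = universe[1:6], b = universe[11:16])
  tab <- pathway_ora(universe[c(1:6, 11:16)], coll, universe)
  meta <- meta_pathways(tab, coll, min_network_genes = 3, fdr_max = 0.5)
  expect_equal(meta$clusters[["a1"]], meta$clusters[["a2"]])
  expect_true(meta$clusters[["b"]] != meta$clusters[["a1"]])
  # fewer than two eligible pathways: trivial cluster with a warning
  expect_warning(
    triv <- meta_pathways(tab[tab$set == "b", , drop = FALSE], coll),
    "trivial")
  expect_equal(length(unique(triv$clusters)), 1)
})

test_that("the threshold sweep returns the modularity-maximizing grid point", {
  # construct coefficients with a known best cut: two cliques at coef .6
  # joined by a single .3 bridge; cutting above .3 isolates the cliques
  sets <- list(p1 = c(sprintf("x%d", 1:10)),
               p2 = c(sprintf("x%d", 1:6), sprintf("y%d", 1:4)),
               p3 = c(sprintf("x%d", 1:6), sprintf("z%d", 1:4)),
               q1 = c(sprintf("w%d", 1:10)),
               q2 = c(sprintf("w%d", 1:6), sprintf("v%d", 1:4)),
               q3 = c(sprintf("w%d", 1:6), sprintf("u%d", 1:4), "x1", "x2", "x3"))
  universe <- unique(unlist(sets))
  tab <- pathway_ora(universe, sets, universe, max_size = 200)
  meta <- meta_pathways(tab, sets, min_network_genes = 3, fdr_max = 1.1,
                        threshold_grid = seq(0.05, 0.95, 0.05))
  # q3 shares 3/10 with p1: below 0.3 the families connect, above they split
  expect_gte(meta$threshold, 0.3)
  expect_equal(length(unique(meta$clusters)), 2)
  expect_equal(meta$Q, max(meta$objective))
  expect_equal(unname(meta$threshold),
               as.numeric(names(which.max(meta$objective))))
})
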
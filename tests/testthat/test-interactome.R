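test_that("score recombination matches hand-evaluated STRING combination", {
  # a single channel at the prior carries no evidence beyond the prior
  expect_equal(recombine_scores(c(experiments = 41), prior = 0.041), 41L)
  # two channels of 500: s' = 0.4786 each, c = 0.7281, t = 0.7393
  expect_equal(recombine_scores(c(a = 500, b = 500), prior = 0.041), 739L)
  # excluding the only informative channel leaves the bare prior
  expect_equal(recombine_scores(c(textmining = 900), "textmining", 0.041), 41L)
  expect_error(recombine_scores(c(a = 1200)), "\\[0, 1000\\]")
})

test_that("recombination is monotone in every included channel score", {
  set.seed(42)
  for (i in 1:25) {
    s <- round(runif(3, 0, 1000))
    names(s) <- c("a", "b", "c")
    base <- recombine_scores(s)
    ch <- sample(3, 1)
    s2 <- s
    s2[ch] <- min(1000, s2[ch] + round(runif(1, 0, 300)))
    expect_gte(recombine_scores(s2), base)
  }
})

test_that("vectorized link recombination agrees with the scalar form", {
  set.seed(7)
  links <- data.frame(protein1 = sprintf("p%d", 1:20),
                      protein2 = sprintf("q%d", 1:20),
                      experiments = round(runif(20, 0, 1000)),
                      database = round(runif(20, 0, 1000)),
                      textmining = round(runif(20, 0, 1000)))
  out <- recombine_links(links, excluded_channels = "textmining")
  manual <- vapply(1:20, function(i) {
    recombine_scores(c(experiments = links$experiments[i],
                       database = links$database[i]))
  }, 0L)
  expect_equal(out$score, manual)
})

test_that("edge retention keeps high-confidence edges and top-k medium per gene", {
  # g1 has four medium edges (650, 600, 550, 500) and no high edges; g5's own
  # top-3 medium edges all outrank its 500-score link to g1, so exactly g1's
  # first three survive
  ed <- data.frame(
    node_a = c("g1", "g1", "g1", "g1", "g2", "g5", "g5", "g5"),
    node_b = c("g2", "g3", "g4", "g5", "g3", "g2", "g3", "g4"),
    score = c(650, 600, 550, 500, 720, 690, 685, 680))
  net <- build_interactome(ed)
  kept <- net$edges
  g1 <- kept[kept$gene_a == "g1" | kept$gene_b == "g1", ]
  expect_equal(nrow(g1), 3)
  expect_setequal(setdiff(unlist(g1[, 1:2]), "g1"), c("g2", "g3", "g4"))
  # the high-confidence g2-g3 edge is kept regardless
  expect_true(any(kept$gene_a == "g2" & kept$gene_b == "g3"))

  # all edges >= 700 are retained no matter top_k
  ed2 <- data.frame(node_a = "a", node_b = sprintf("b%d", 1:6),
                    score = 700 + 1:6)
  expect_equal(nrow(build_interactome(ed2, top_k_medium = 0)$edges), 6)
})

test_that("an edge survives via the top-3 list of either endpoint", {
  # hub h has 5 medium partners; edge h-x5 is weakest for h but x5's only edge
  ed <- data.frame(node_a = "h", node_b = sprintf("x%d", 1:5),
                   score = c(690, 680, 670, 660, 650))
  net <- build_interactome(ed)
  expect_equal(nrow(net$edges), 5)  # every edge is a partner's top-1
})

test_that("duplicates collapse to the maximum score and self-loops vanish", {
  ed <- data.frame(node_a = c("a", "b", "a", "c"),
                   node_b = c("b", "a", "a", "d"),
                   score = c(710, 900, 950, 800))
  net <- build_interactome(ed)
  expect_equal(net$edges$score[net$edges$gene_a == "a"], 900L)
  expect_false("a" %in% net$edges$gene_b[net$edges$gene_a == "a"])
})

test_that("interactome construction is invariant to row order and orientation", {
  set.seed(11)
  ed <- data.frame(node_a = sprintf("g%d", sample(12, 40, TRUE)),
                   node_b = sprintf("g%d", sample(12, 40, TRUE)),
                   score = round(runif(40, 300, 1000)))
  ref <- build_interactome(ed)
  shuf <- ed[sample(nrow(ed)), ]
  flip <- sample(nrow(ed), 15)
  tmp <- shuf$node_a[flip]
  shuf$node_a[flip] <- shuf$node_b[flip]
  shuf$node_b[flip] <- tmp
  expect_identical(build_interactome(shuf), ref)
})

test_that("unmapped identifiers are dropped with a message; empty input is fine", {
  ed <- data.frame(node_a = c("p1", "p2"), node_b = c("p2", "p3"),
                   score = c(800, 900))
  expect_message(net <- build_interactome(ed, mapping = c(p1 = "A", p2 = "B")),
                 "1 records")
  expect_equal(net$genes, c("A", "B"))
  empty <- build_interactome(ed[0, ])
  expect_s3_class(empty, "interactome")
  expect_length(empty$genes, 0)
})

test_that("normalized adjacency matches closed forms", {
  net <- interactome_from_edges("a", "b")
  W <- normalize_adjacency(net)
  expect_equal(W["a", "b"], 1)
  expect_equal(Matrix::diag(W), c(a = 0, b = 0))

  path <- interactome_from_edges(c("a", "b"), c("b", "c"))
  Wp <- normalize_adjacency(path)
  expect_equal(Wp["a", "b"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(Wp["b", "c"], 1 / sqrt(2), tolerance = 1e-12)

  # isolated gene: zero row and column by the 0/0 = 0 convention
  iso <- socionet:::new_interactome(c("a", "b", "z"),
                                    data.frame(gene_a = "a", gene_b = "b",
                                               score = 800L))
  Wi <- normalize_adjacency(iso)
  expect_true(all(Wi["z", ] == 0) && all(Wi[, "z"] == 0))
})

test_that("W is symmetric with spectral radius at most 1 on random graphs", {
  for (s in 1:5) {
    net <- random_interactome(40, 0.1, seed = s)
    W <- normalize_adjacency(net)
    expect_lt(max(abs(W - Matrix::t(W))), 1e-12)
    ev <- eigen(as.matrix(W), symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-9)
  }
})

test_that("score weighting is supported alongside the binary default", {
  net <- interactome_from_edges(c("a", "b"), c("b", "c"), score = c(800, 400))
  Ws <- normalize_adjacency(net, weighting = "score")
  # A_ab = .8, A_bc = .4; d_a=.8, d_b=1.2, d_c=.4
  expect_equal(Ws["a", "b"], 0.8 / sqrt(0.8 * 1.2), tolerance = 1e-12)
  expect_equal(Ws["b", "c"], 0.4 / sqrt(1.2 * 0.4), tolerance = 1e-12)
})

test_that("edge TSV and STRING links round-trip through their readers", {
  net <- random_interactome(10, 0.3, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_tsv(net$edges, f)
  back <- read_edge_tsv(f)
  expect_equal(back$gene_a, net$edges$gene_a)
  expect_equal(back$score, net$edges$score)

  links <- data.frame(protein1 = c("p1", "p2"), protein2 = c("p2", "p3"),
                      experiments = c(500L, 700L), textmining = c(100L, 0L),
                      combined_score = c(520L, 700L))
  lf <- withr::local_tempfile(fileext = ".txt")
  write.table(links, lf, sep = " ", quote = FALSE, row.names = FALSE)
  rl <- read_string_links(lf)
  expect_equal(rl$node_a, c("p1", "p2"))
  expect_equal(rl$experiments, c(500L, 700L))
})
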
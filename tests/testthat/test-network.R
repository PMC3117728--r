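test_that("network topology follows minimum-spanning construction with ties", {
  # chain: d(a,b) = 1, d(b,c) = 1, d(a,c) = 2 -> path, no loop
  chain <- codon_alignment(c(a = "AAATTT", b = "AACTTT", c = "AACTTG"))
  net <- build_network(NULL, chain)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$n_loops, 0L)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("a b", "b c"))

  # square of equal distances -> all four tied edges retained, one loop
  sq <- codon_alignment(c(a = "AAAAAA", b = "AACAAA",
                          c = "AACAAC", d = "AAAAAC"))
  netsq <- build_network(NULL, sq)
  expect_equal(nrow(netsq$edges), 4L)
  expect_equal(netsq$n_loops, 1L)

  # removing one corner resolves the cycle into a path
  pruned <- prune_and_rebuild(NULL, sq, exclude = "d")
  expect_equal(nrow(pruned$edges), 2L)
  expect_equal(pruned$n_loops, 0L)

  # identical duplicate alleles merge with summed frequency
  gt <- genotype_table(paste0("i", 1:4), c("a", "a", "b", "x"),
                       c("b", "x", "x", "x"))
  dupaln <- codon_alignment(c(a = "AAATTT", b = "AAATTT", x = "AACTTT"))
  aset <- collapse_alleles(gt, dupaln)
  netd <- build_network(aset, dupaln)
  expect_equal(nrow(netd$nodes), 2L)
  merged <- netd$nodes[netd$nodes$members == "a,b", ]
  expect_equal(merged$frequency, (2 + 2) / 8)
})

test_that("tree-case networks match an independent MST oracle", {
  for (s in 1:4) {
    pool <- gen_allele_pool(sim_config(seed = 80 + s, n_alleles = 8))
    aln <- pool$alignment
    net <- build_network(NULL, aln)
    expect_gte(nrow(net$edges), nrow(net$nodes) - 1L)
    expect_true(igraph::is_connected(net$graph))
    if (net$n_loops == 0L) {
      # igraph MST on the complete distance graph as oracle
      m <- do.call(rbind, strsplit(unique(unname(aln$sequences)), ""))
      nn <- nrow(m)
      d <- matrix(0, nn, nn)
      for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
      }
      g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                               weighted = TRUE)
      mst <- igraph::mst(g)
      expect_equal(sum(net$edges$distance),
                   sum(igraph::E(mst)$weight))
    }
  }
})

test_that("edges carry amino-acid substitution labels in codon coordinates", {
  # codon 2 AAA(K) -> GAA(E): label K2E
  aln <- codon_alignment(c(a = "ATGAAA", b = "ATGGAA", c = "ATGGAG"))
  net <- build_network(NULL, aln)
  e <- net$edges[net$edges$from == "a" & net$edges$to == "b" |
                   net$edges$from == "b" & net$edges$to == "a", ]
  expect_equal(e$aa_subs, "K2E")
  # synonymous edge b-c (GAA->GAG) has an empty label
  e2 <- net$edges[net$edges$from %in% c("b", "c") & net$edges$to %in% c("b", "c"), ]
  expect_equal(e2$aa_subs, "")
})

test_that("prune_and_rebuild validates input and degenerates to one node", {
  sq <- codon_alignment(c(a = "AAAAAA", b = "AACAAA", c = "AACAAC"))
  expect_error(prune_and_rebuild(NULL, sq, exclude = "zz"), "unknown")
  expect_error(prune_and_rebuild(NULL, sq, exclude = c("a", "b", "c")),
               "every allele")
  single <- prune_and_rebuild(NULL, sq, exclude = c("a", "b"))
  expect_equal(nrow(single$nodes), 1L)
  expect_equal(nrow(single$edges), 0L)
  # empty exclusion is identical to build_network
  expect_equal(prune_and_rebuild(NULL, sq)$edges, build_network(NULL, sq)$edges)
})

test_that("network export writes edge-list, DOT and GraphML", {
  sq <- codon_alignment(c(a = "AAAAAA", b = "AACAAA", c = "AACAAC"))
  net <- build_network(NULL, sq)
  tsv <- tempfile(fileext = ".tsv"); write_network(net, tsv)
  expect_true(file.exists(tsv))
  expect_equal(nrow(read.delim(tsv)), nrow(net$edges))
  dot <- tempfile(fileext = ".dot"); write_network(net, dot, "dot")
  expect_true(any(grepl("graph", readLines(dot))))
  gml <- tempfile(fileext = ".graphml"); write_network(net, gml, "graphml")
  expect_true(file.size(gml) > 0)
})
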
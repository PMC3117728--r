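test_that("build_nj_tree yields unrooted binary trees with clamped branches", {
  pool <- gen_allele_pool(sim_config(seed = 2))
  tree <- build_nj_tree(pool$alignment)
  expect_s3_class(tree, "phylo")
  expect_equal(length(tree$tip.label), 17L)
  expect_equal(nrow(tree$edge), 2L * 17L - 3L)   # 31 branches, unrooted binary
  expect_true(all(tree$edge.length >= 0))

  # duplicate sequences produce a zero-length terminal pair
  dup <- codon_alignment(c(pool$alignment$sequences[1:3],
                           d = unname(pool$alignment$sequences[1])))
  tr2 <- build_nj_tree(dup)
  tips <- match(c(pool$alignment$allele_ids[1], "d"), tr2$tip.label)
  term_len <- tr2$edge.length[match(tips, tr2$edge[, 2])]
  expect_equal(term_len, c(0, 0))

  expect_error(build_nj_tree(codon_alignment(c(a = "AAA", b = "AAA"))),
               "insufficient-data")
})

test_that("one-codon likelihood matches direct summation over the 61 states", {
  # 3-taxon star tree rooted at the internal node: direct likelihood is
  # sum_r pi_r * prod_i P[r, x_i](t_i)
  aln <- codon_alignment(c(t1 = "ATG", t2 = "ATA", t3 = "CTG"))
  tree <- ape::read.tree(text = "(t1:0.2,t2:0.35,t3:0.1);")
  pi <- gy94_f3x4(aln)
  omega <- 0.7; kappa <- 2.5
  Q <- mhc2div:::gy94_Q(omega, kappa, pi)
  mu <- -sum(pi * diag(Q))
  ed <- mhc2div:::gy94_eigen(Q, pi)
  sense <- mhc2div:::sense_codons()
  states <- match(c("ATG", "ATA", "CTG"), sense)
  bl <- c(0.2, 0.35, 0.1) * 3 / mu    # nt units -> codons, rate-normalized
  Ps <- lapply(bl, function(t) mhc2div:::gy94_pmat(ed, t))
  direct <- sum(pi * Ps[[1]][, states[1]] * Ps[[2]][, states[2]] *
                  Ps[[3]][, states[3]])

  tree_post <- ape::reorder.phylo(tree, "postorder")
  perm <- match(tree_post$tip.label, c("t1", "t2", "t3"))
  leaf_cols <- as.list(states[perm])
  edQ <- mhc2div:::gy94_eigen(Q / mu, pi)
  ll <- mhc2div:::class_site_loglik(edQ, tree_post,
                                    tree_post$edge.length * 3, leaf_cols, pi)
  expect_equal(exp(ll), direct, tolerance = 1e-9)
})

test_that("lrt computes, clamps and validates", {
  fake <- function(label, lnl) {
    structure(list(model_label = label, log_likelihood = lnl,
                   data_key = "k"), class = "site_model_fit")
  }
  expect_equal(lrt(fake("M7", -1000), fake("M8", -1000))$statistic, 0)
  expect_equal(lrt(fake("M7", -1000), fake("M8", -1000))$p, 1)
  r <- lrt(fake("M7", -1000), fake("M8", -976.628))
  expect_equal(r$statistic, 46.744)
  expect_equal(r$df, 2L)
  expect_lt(r$p, 0.01)
  expect_warning(lrt(fake("M7", -1000), fake("M8", -1001)), "clamped")
  expect_error(lrt(fake("M8", -1), fake("M7", -1)), "expects an M7")
  m7a <- fake("M7", -10); m8b <- fake("M8", -9); m8b$data_key <- "other"
  expect_error(lrt(m7a, m8b), "different data")
})

test_that("M8 nests M7 and recovers planted positive selection", {
  # planted: 30% of codons at omega = 4 on an 8-taxon tree
  tree <- sim_tree(8, bl = 0.08)
  omega_site <- rep(c(0.2, 4), times = c(21, 9))
  aln <- simulate_gy94(tree, 30, omega_site = omega_site, kappa = 2, seed = 31)
  m7 <- fit_site_model(aln, tree, model = "M7", K = 5)
  m8 <- fit_site_model(aln, tree, model = "M8", K = 5)
  expect_gte(m8$log_likelihood, m7$log_likelihood - 1e-4)   # nesting
  expect_gt(m8$parameters$omega_s, 1)
  expect_gt(m8$parameters$p1, 0.05)
  r <- lrt(m7, m8)
  expect_gt(r$statistic, 5.99)   # planted selection clears the 5% critical value

  # posterior-based site calls: concentrated on the planted codons (22-30),
  # and invariant sites are never selected
  post <- site_posteriors(m8, threshold = 0.05)
  expect_gt(length(post$selected_sites), 0L)
  expect_gte(mean(post$selected_sites %in% 22:30), 0.8)
  m <- do.call(rbind, strsplit(unname(aln$sequences), ""))
  codon_var <- vapply(seq_len(30), function(c) {
    any(apply(m[, (3 * c - 2):(3 * c), drop = FALSE], 2,
              function(col) length(unique(col)) > 1))
  }, TRUE)
  expect_true(all(codon_var[post$selected_sites]))
  expect_length(post$posterior, 30L)
  expect_true(all(post$posterior >= 0 & post$posterior <= 1))
})

test_that("LRT stays below the critical value on M7-simulated data", {
  # boundary-aware null calibration, scaled to 3 seeded replicates for the
  # budget (sketch: 200); allow at most one exceedance of chi2(2) at 5%
  exceed <- 0L
  for (i in 1:3) {
    tree <- sim_tree(6, bl = 0.09)
    set.seed(600 + i)
    om <- rbeta(25, 2, 2)          # beta-distributed omegas: an M7 world
    aln <- simulate_gy94(tree, 25L, omega_site = om, kappa = 2, seed = 600 + i)
    m7 <- fit_site_model(aln, tree, model = "M7", K = 5)
    m8 <- fit_site_model(aln, tree, model = "M8", K = 5)
    if (lrt(m7, m8)$statistic > 5.99) exceed <- exceed + 1L
  }
  expect_lte(exceed, 1L)
})

test_that("identical sequences give equal M7/M8 likelihoods (LRT 0)", {
  aln <- codon_alignment(setNames(rep("ATGAAATTTGGACCAATGAAATTTGGACCA", 4),
                                  paste0("t", 1:4)))
  tree <- sim_tree(4, bl = 0.01)
  tree$tip.label <- paste0("t", 1:4)
  m7 <- fit_site_model(aln, tree, model = "M7", K = 5)
  m8 <- fit_site_model(aln, tree, model = "M8", K = 5)
  expect_equal(lrt(m7, m8)$statistic, 0, tolerance = 1e-3)
})

test_that("simulate_gy94 is seed-deterministic and in-frame", {
  tree <- sim_tree(5, bl = 0.1)
  a <- simulate_gy94(tree, 20, omega_site = 1, seed = 4)
  b <- simulate_gy94(tree, 20, omega_site = 1, seed = 4)
  expect_identical(a$sequences, b$sequences)
  expect_equal(a$codon_count, 20L)
  expect_silent(translate_alignment(a))   # stop-free by construction
})
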
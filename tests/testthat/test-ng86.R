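test_that("site counts follow the stops-as-nonsynonymous convention", {
  expect_equal(ng86_site_counts("TTT"), c(n = 8 / 3, s = 1 / 3))
  expect_equal(ng86_site_counts("TGG"), c(n = 3, s = 0))
  expect_error(ng86_site_counts("TAA"), "domain error")
  # identity n + s = 3 over every sense codon
  ct <- Biostrings::GENETIC_CODE
  for (cod in names(ct)[ct != "*"]) {
    cnt <- ng86_site_counts(cod)
    expect_equal(unname(cnt["n"] + cnt["s"]), 3)
  }
})

test_that("pathway averaging matches hand-derived cases and the DFS oracle", {
  expect_equal(ng86_pair("ACG", "ACG")[c("Nd", "Sd")], list(Nd = 0, Sd = 0))
  # TTT -> GTA via GTT (nonsyn, then nonsyn... ) and TTA (nonsyn syn):
  # averaged over the two orderings: Nd = 1.5, Sd = 0.5
  expect_equal(ng86_pair("TTT", "GTA")[c("Nd", "Sd")], list(Nd = 1.5, Sd = 0.5))
  expect_equal(ng86_pair("GGA", "GGG")[c("Nd", "Sd")], list(Nd = 0, Sd = 1))
  expect_error(ng86_pair("TAA", "AAA"), "domain error")

  # random sample of sense-codon pairs against the independent oracle
  # (the full 61 x 61 sweep runs in the acceptance suite)
  set.seed(5)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (rep in 1:200) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    exp <- oracle_pair(a, b)
    got <- suppressWarnings(ng86_pair(a, b))
    if (is.null(exp)) {
      expect_null(got)
    } else {
      expect_equal(c(Nd = got$Nd, Sd = got$Sd), exp)
    }
  }
})

test_that("jc_correct evaluates the closed form and flags saturation", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.01), -0.75 * log(1 - 0.04 / 3))
  expect_equal(round(jc_correct(0.01), 6), 0.010067)
  expect_error(jc_correct(0.75), "saturation")
  expect_error(jc_correct(-0.1), "domain")
})

test_that("mean_dn_ds behaves on trivial and partitioned inputs", {
  ident <- codon_alignment(c(a = "ATGAAATTT", b = "ATGAAATTT"))
  r <- mean_dn_ds(ident)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_true(is.infinite(r$ratio) || is.nan(r$ratio))

  # dS = 0 with nonsyn variation -> ratio flagged infinite, not an error
  nonsyn <- codon_alignment(c(a = "ATGAAA", b = "ATGGAA"))
  expect_true(is.infinite(mean_dn_ds(nonsyn)$ratio))

  expect_error(mean_dn_ds(toy_alignment(), partition = integer(0)), "domain")
  expect_error(mean_dn_ds(toy_alignment(), partition = 99), "domain")

  # partition bounds property: full-alignment dN and dS lie between the two
  # partition values on every fixture
  for (s in 1:5) {
    cfg <- sim_config(seed = 40 + s)
    pool <- gen_allele_pool(cfg)
    pbs <- cfg$pbs_codons
    nonpbs <- setdiff(seq_len(cfg$codon_count), pbs)
    full <- mean_dn_ds(pool$alignment)
    a <- mean_dn_ds(pool$alignment, pbs)
    b <- mean_dn_ds(pool$alignment, nonpbs)
    expect_gte(full$dN, min(a$dN, b$dN) - 1e-9)
    expect_lte(full$dN, max(a$dN, b$dN) + 1e-9)
    expect_gte(full$dS, min(a$dS, b$dS) - 1e-9)
    expect_lte(full$dS, max(a$dS, b$dS) + 1e-9)
  }
})

test_that("Z-test is one-tailed for dN > dS and degenerates sensibly", {
  # purely synonymous variation (2 syn diffs over 10 codons) -> Z < 0, p > 0.5
  syn <- codon_alignment(c(a = "GGATTACTGGGCAAACCCTTTAGAGATGAA",
                           b = "GGGTTACTAGGCAAACCCTTTAGAGATGAA"))
  zs <- z_test_positive_selection(syn, reps = 300, seed = 2)
  expect_lt(zs$z, 0)
  expect_gt(zs$p, 0.5)

  # no variation -> Z = 0, p = 1
  z0 <- z_test_positive_selection(codon_alignment(c(a = "ATGAAA", b = "ATGAAA")),
                                  reps = 100, seed = 1)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)

  expect_error(z_test_positive_selection(toy_alignment(), reps = 50), "reps")

  # seeded reproducibility
  pool <- gen_allele_pool(sim_config(seed = 9))
  a <- z_test_positive_selection(pool$alignment, reps = 150, seed = 7)
  b <- z_test_positive_selection(pool$alignment, reps = 150, seed = 7)
  expect_identical(a, b)
})

test_that("Z-test controls type-I error under neutral (omega = 1) evolution", {
  # 60 neutral GY94 alignments (scaled from the 1000-replicate sketch).
  # Empirically the bootstrap Z-test is CONSERVATIVE (rejection well below
  # the nominal 5%; see the methods vignette), so the meaningful guarantee
  # is the upper bound on the type-I error.
  rej <- 0L; n <- 60L
  for (i in seq_len(n)) {
    tree <- sim_tree(6, bl = 0.06)
    aln <- simulate_gy94(tree, 60L, omega_site = 1, kappa = 2, seed = 700 + i)
    z <- z_test_positive_selection(aln, reps = 150L, seed = i)
    if (z$p < 0.05) rej <- rej + 1L
  }
  expect_lte(rej / n, 0.07)
})

test_that("map_pbs_sites transfers catalog positions through an alignment", {
  # human reference mapped onto itself: every cataloged position transfers
  ref <- human_b1_reference()
  part <- map_pbs_sites(ref, catalog = "reche")
  expect_s3_class(part, "site_partition")
  expect_equal(part$pbs_codons, sort(pbs_catalog("reche")))
  expect_length(part$pbs_codons, 24L)
  expect_equal(3L * length(part$pbs_codons), 72L)

  brown <- map_pbs_sites(ref, catalog = "brown")
  expect_equal(brown$pbs_codons, sort(pbs_catalog("brown")))

  # empty catalog -> everything non-PBS
  none <- map_pbs_sites(ref, catalog = integer(0))
  expect_length(none$pbs_codons, 0L)
  expect_length(none$non_pbs_codons, nchar(ref))

  # an N-terminal extension shifts the mapping coherently
  shifted <- paste0("AAAA", ref)
  part2 <- map_pbs_sites(shifted, catalog = "reche")
  expect_equal(part2$pbs_codons, sort(pbs_catalog("reche")) + 4L)

  # partition invariants
  expect_equal(sort(c(part$pbs_codons, part$non_pbs_codons)),
               seq_len(nchar(ref)))

  # partition round-trips through the plain-text index-list format
  path <- tempfile(fileext = ".txt")
  write_partition(part, path)
  back <- read_partition(path)
  expect_equal(back$pbs_codons, part$pbs_codons)
  expect_equal(back$codon_count, part$codon_count)
  expect_equal(back$source_catalog, part$source_catalog)
})
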
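test_that("HWE exact test matches enumeration oracles", {
  # 2 alleles, n = 5, all heterozygotes: independent enumeration over the
  # heterozygote count h (h in {1, 3, 5} by parity of the allele counts)
  gt <- genotype_table(paste0("i", 1:5), rep("a", 5), rep("b", 5))
  res <- hwe_exact_test(gt)
  expect_equal(res$method, "enumeration")
  n <- 5; m <- c(5, 5)
  tab_p <- function(h) {
    hom <- (m - h) / 2
    exp(lgamma(n + 1) + sum(lgamma(m + 1)) + h * log(2) -
          lgamma(2 * n + 1) - sum(lgamma(c(h, hom) + 1)))
  }
  probs <- vapply(c(1, 3, 5), tab_p, 0)
  oracle_p <- sum(probs[probs <= probs[3] + 1e-12]) / sum(probs)
  expect_equal(res$p, oracle_p)

  # monomorphic -> p = 1
  expect_equal(hwe_exact_test(genotype_table(c("i1", "i2"), c("a", "a"),
                                             c("a", "a")))$p, 1)

  # Monte-Carlo agrees with enumeration on a 2-allele panel pushed past the
  # enumeration size cutoff
  set.seed(8)
  a1 <- sample(c("a", "b"), 14, TRUE, prob = c(0.6, 0.4))
  a2 <- sample(c("a", "b"), 14, TRUE, prob = c(0.6, 0.4))
  big <- genotype_table(paste0("i", 1:14), a1, a2)
  mc <- hwe_exact_test(big, mc_steps = 20000, seed = 3)
  expect_equal(mc$method, "monte-carlo")
  # oracle: enumerate heterozygote counts directly
  m2 <- table(factor(c(a1, a2), levels = c("a", "b")))
  n2 <- 14
  hs <- seq(m2[1] %% 2, min(m2), by = 2)
  probs2 <- vapply(hs, function(h) {
    hom <- (as.numeric(m2) - h) / 2
    exp(lgamma(n2 + 1) + sum(lgamma(as.numeric(m2) + 1)) + h * log(2) -
          lgamma(2 * n2 + 1) - sum(lgamma(c(h, hom) + 1)))
  }, 0)
  obs_h <- sum(a1 != a2)
  oracle2 <- sum(probs2[probs2 <= probs2[match(obs_h, hs)] + 1e-12]) / sum(probs2)
  expect_equal(mc$p, oracle2, tolerance = 0.03)
})

test_that("allelic combination test: nulls, determinism and bookkeeping", {
  # monomorphic panel: the homozygote combo is always observed = simulated
  mono <- genotype_table(paste0("i", 1:6), rep("a", 6), rep("a", 6))
  r <- allelic_combination_test(mono, reps = 200, seed = 1)
  expect_equal(nrow(r$table), 1L)
  expect_equal(r$table$p, 1)
  expect_equal(r$table$observed, 6L)

  panel <- gen_panel(gen_allele_pool(sim_config(seed = 3, n_alleles = 6))$alignment,
                     sim_config(seed = 3, n_alleles = 6, panel_size = 40))
  a <- allelic_combination_test(panel$genotypes, reps = 500, seed = 9)
  b <- allelic_combination_test(panel$genotypes, reps = 500, seed = 9)
  expect_identical(a$table, b$table)     # bit-reproducible given the seed
  # every replicate distributes exactly N individuals over combos
  expect_equal(sum(a$table$simulated_mean), 40)
  expect_equal(sum(a$table$observed), 40L)
  expect_true(all(a$table$ci_lower <= a$table$simulated_mean + 1e-9))
  expect_true(all(a$table$simulated_mean <= a$table$ci_upper + 1e-9))
  expect_true(all(a$table$p >= 0 & a$table$p <= 1))
  expect_error(allelic_combination_test(
    genotype_table(character(0), character(0), character(0)), reps = 100),
    "empty|domain")
})

test_that("sequential Bonferroni follows the Holm step-down by hand", {
  # {0.01, 0.04} with m = 2: reject 0.01 (<= 0.025), then 0.04 (<= 0.05)
  r <- sequential_bonferroni(c(0.01, 0.04))
  expect_equal(r$reject, c(TRUE, TRUE))
  # single test at 0.01 -> rejected
  expect_true(sequential_bonferroni(0.01)$reject)
  # step-down stops at the first retained hypothesis
  r2 <- sequential_bonferroni(c(0.01, 0.30, 0.04))
  expect_equal(r2$reject, c(TRUE, FALSE, FALSE))
  expect_error(sequential_bonferroni(c(0.5, 1.2)), "domain")

  # property: Holm rejects no fewer than plain Bonferroni and no more than
  # unadjusted testing
  set.seed(21)
  for (rep in 1:20) {
    p <- runif(sample(3:30, 1))^2
    holm <- sequential_bonferroni(p)$reject
    bonf <- p <= 0.05 / length(p)
    raw <- p <= 0.05
    expect_true(all(holm[bonf]))   # bonferroni-rejected => holm-rejected
    expect_true(all(raw[holm]))    # holm-rejected => raw-significant
  }
})

test_that("EM phasing resolves trivial and frequency-driven cases", {
  # one heterozygous site: unique resolution
  one <- em_phase(c(i1 = "ARG"))
  expect_setequal(c(one$individuals$hap1, one$individuals$hap2),
                  c("AAG", "AGG"))
  expect_equal(one$individuals$posterior, 1)

  # two-site toy: anchored AG/AG and GA/GA homozygotes force the double
  # heterozygote (consensus "RR") to phase as AG/GA
  deg <- c(rep("AG", 4), rep("GA", 4), "RR")
  names(deg) <- paste0("i", 1:9)
  res <- em_phase(deg, seed = 2)
  dh <- res$individuals[9, ]
  expect_setequal(c(dh$hap1, dh$hap2), c("AG", "GA"))
  expect_gt(dh$posterior, 0.5)
  expect_equal(sum(res$frequencies), 1, tolerance = 1e-9)

  # likelihood trajectory is non-decreasing on every input tried
  for (s in 1:3) {
    pool <- gen_allele_pool(sim_config(seed = 60 + s, n_alleles = 6))
    panel <- gen_panel(pool$alignment,
                       sim_config(seed = 60 + s, n_alleles = 6, panel_size = 25))
    res <- em_phase(attr(panel$genotypes, "degenerate"), seed = s)
    expect_true(all(diff(res$loglik_trajectory) > -1e-6))
  }

  # complexity guard
  too_het <- paste(rep("R", 21), collapse = "")
  expect_error(em_phase(c(i1 = too_het)), "complexity error")
})

test_that("mendel_check applies the one-allele-from-each-parent rule", {
  famA <- structure(list(family_id = "A", father = c("3", "4"),
                         mother = c("4", "15"),
                         offspring = list(c("3", "15"), c("5", "9"),
                                          c("4", "4"))),
                    class = "family_record")
  rep <- mendel_check(famA)
  expect_equal(rep$offspring$compatible, c(TRUE, FALSE, TRUE))
  expect_equal(rep$offspring$paternal[1], "3")
  expect_equal(rep$offspring$maternal[1], "15")
  # homozygote needs the allele in both parents
  expect_true(rep$offspring$compatible[3])
  hom_bad <- structure(list(family_id = "B", father = c("1", "2"),
                            mother = c("3", "4"),
                            offspring = list(c("1", "1"))),
                       class = "family_record")
  expect_false(mendel_check(hom_bad)$offspring$compatible)

  # planted corruptions are always detected, uncorrupted families are clean
  for (s in 1:4) {
    cfg <- sim_config(seed = 70 + s, n_alleles = 10)
    pool <- gen_allele_pool(cfg)
    clean <- gen_families(pool$alignment, cfg)
    mc <- mendel_check_all(clean$families)
    expect_equal(mc$total_compatible, mc$total_offspring)
    k <- 3L
    dirty <- gen_families(pool$alignment, cfg, corrupt = k)
    mcd <- mendel_check_all(dirty$families)
    expect_equal(mcd$total_offspring - mcd$total_compatible, nrow(dirty$truth))
    expect_equal(nrow(dirty$truth), k)
  }
})
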
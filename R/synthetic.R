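# Seed-deterministic generators for allele pools, genotype panels and
# nuclear families with the statistical structure the analysis assumes:
# ~90-codon stop-free alleles whose non-synonymous variation concentrates at
# designated PBS codons, optional planted single-crossover recombinants,
# panels drawn under HWE or with enriched allele combinations, and families
# with Mendelian transmission (plus a corruption mode for power tests).
#
# Defaults emulate the study design this pipeline targets: 17 alleles over
# 90 codons with a 24-codon (72-bp) PBS set, panels of 101 individuals, and
# 5 families of 8-13 offspring.

#' Simulation configuration
#'
#' @param codon_count codons per allele (default 90).
#' @param n_alleles size of the allele pool (default 17, incl. recombinants).
#' @param pbs_codons 1-based codon indices of the peptide-binding set
#'   (default: 24 codons spread over the frame, a 72-bp partition).
#' @param omega_pbs,omega_nonpbs relative non-synonymous odds inside /
#'   outside the PBS set (defaults 5 and 0.5).
#' @param n_polymorphic_sites size of the shared polymorphic-site pool from
#'   which allele substitutions are drawn (default 25, at most one site per
#'   codon); alleles of a single locus share polymorphism rather than
#'   mutating independently.
#' @param substitutions_per_allele mean substitutions separating an allele
#'   from the ancestral sequence (default 5; with the 25-site pool this
#'   yields nucleotide diversity around 0.03 on a 270-bp frame).
#' @param n_recombinants planted single-crossover alleles (default 0).
#' @param panel_size diploid individuals in a panel (default 101).
#' @param mating \code{"hwe"} or \code{"excess_pairs"}.
#' @param excess_combos character vector of combos \code{"idA/idB"} to
#'   enrich under \code{"excess_pairs"}.
#' @param excess_factor multiplicative enrichment of those combos.
#' @param dirichlet_alpha concentration of the allele-frequency draw
#'   (default 1: flat over the simplex, giving empirical-style skew).
#' @param n_families,offspring_range family count and per-family offspring
#'   range (defaults 5 and 8-13).
#' @param seed integer RNG seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(codon_count = 90L, n_alleles = 17L,
                       pbs_codons = default_pbs_codons(),
                       omega_pbs = 5, omega_nonpbs = 0.5,
                       n_polymorphic_sites = 25L,
                       substitutions_per_allele = 5,
                       n_recombinants = 0L,
                       panel_size = 101L,
                       mating = c("hwe", "excess_pairs"),
                       excess_combos = character(0),
                       excess_factor = 1,
                       dirichlet_alpha = 1,
                       n_families = 5L, offspring_range = c(8L, 13L),
                       seed = 1L) {
  mating <- match.arg(mating)
  stopifnot(codon_count > 0, n_alleles > 1, omega_pbs > 0, omega_nonpbs > 0,
            n_recombinants >= 0, panel_size > 0, excess_factor >= 0)
  if (length(pbs_codons) > 0 &&
      (min(pbs_codons) < 1 || max(pbs_codons) > codon_count)) {
    stop("domain error: pbs_codons outside 1..", codon_count)
  }
  structure(list(codon_count = as.integer(codon_count),
                 n_alleles = as.integer(n_alleles),
                 pbs_codons = as.integer(sort(unique(pbs_codons))),
                 omega_pbs = omega_pbs, omega_nonpbs = omega_nonpbs,
                 n_polymorphic_sites = as.integer(n_polymorphic_sites),
                 substitutions_per_allele = substitutions_per_allele,
                 n_recombinants = as.integer(n_recombinants),
                 panel_size = as.integer(panel_size),
                 mating = mating,
                 excess_combos = excess_combos,
                 excess_factor = excess_factor,
                 dirichlet_alpha = dirichlet_alpha,
                 n_families = as.integer(n_families),
                 offspring_range = as.integer(offspring_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default 24-codon PBS set for simulated 90-codon frames
#' @return integer vector of 24 codon indices spread over 1..90.
#' @export
default_pbs_codons <- function() {
  c(4L, 6L, 8L, 11L, 14L, 17L, 21L, 26L, 30L, 34L, 38L, 43L, 47L, 52L,
    56L, 60L, 63L, 67L, 70L, 74L, 78L, 81L, 85L, 88L)
}

# candidate single-base mutations of the ancestor, one row per (position,
# derived base), weighted by omega of the codon's partition when
# non-synonymous, 1 when synonymous, 0 (excluded) when producing a stop
.mutation_candidates <- function(anc_chars, pbs_mask, omega_pbs, omega_nonpbs) {
  ct <- codon_table()
  L <- length(anc_chars)
  out <- list()
  for (pos in seq_len(L)) {
    cidx <- (pos - 1L) %/% 3L + 1L
    off <- (cidx - 1L) * 3L
    codon <- paste0(anc_chars[(off + 1L):(off + 3L)], collapse = "")
    for (b in setdiff(.BASES, anc_chars[pos])) {
      mut <- anc_chars[(off + 1L):(off + 3L)]
      mut[pos - off] <- b
      mutc <- paste0(mut, collapse = "")
      if (ct[mutc] == "*") next
      w <- if (ct[mutc] == ct[codon]) 1 else
        if (pbs_mask[cidx]) omega_pbs else omega_nonpbs
      out[[length(out) + 1L]] <- data.frame(
        pos = pos, codon = cidx, base = b, weight = w,
        nonsyn = ct[mutc] != ct[codon], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate an allele pool with PBS-concentrated non-synonymous variation
#'
#' Draws a random stop-free ancestral sequence and a shared pool of
#' biallelic polymorphic sites (at most one per codon) whose synonymous /
#' non-synonymous character is sampled with odds scaled by the omega of the
#' containing codon's partition; each allele then carries a random subset of
#' those site mutations, so alleles share polymorphism like the alleles of a
#' single locus.  Optional recombinants are built by a single crossover
#' between two divergent alleles.  All sequences are stop-free by
#' construction (candidate mutations creating stops are resampled away).
#'
#' @param config a \code{sim_config}.
#' @return list with \code{alignment} (a \code{codon_alignment}; IDs
#'   \code{"A01"...}) and \code{truth} (ancestor, the polymorphic site pool,
#'   per-allele substitution records, recombinant parentage and breakpoints,
#'   pbs_codons, seed).
#' @export
gen_allele_pool <- function(config) {
  set.seed(config$seed)
  ct <- codon_table()
  sense <- sense_codons()
  nc <- config$codon_count
  if (config$n_recombinants > config$n_alleles - 2L) {
    stop("generation error: too many recombinants for pool size")
  }
  if (config$n_polymorphic_sites > nc) {
    stop("generation error: more polymorphic sites than codons (one per codon)")
  }
  pbs_mask <- seq_len(nc) %in% config$pbs_codons
  ancestor <- paste0(sample(sense, nc, replace = TRUE), collapse = "")
  anc_chars <- strsplit(ancestor, "")[[1]]
  cand <- .mutation_candidates(anc_chars, pbs_mask,
                               config$omega_pbs, config$omega_nonpbs)
  # shared site pool: weighted draw without replacement, one site per codon
  pool_rows <- integer(0)
  used_codons <- integer(0)
  w <- cand$weight
  while (length(pool_rows) < config$n_polymorphic_sites) {
    avail <- which(w > 0 & !(cand$codon %in% used_codons))
    if (length(avail) == 0L) stop("generation error: candidate mutations exhausted")
    pick <- avail[sample.int(length(avail), 1L, prob = w[avail])]
    pool_rows <- c(pool_rows, pick)
    used_codons <- c(used_codons, cand$codon[pick])
  }
  site_pool <- cand[pool_rows, , drop = FALSE]
  site_pool <- site_pool[order(site_pool$pos), , drop = FALSE]
  rownames(site_pool) <- NULL
  nsite <- nrow(site_pool)
  n_base <- config$n_alleles - config$n_recombinants
  seqs <- character(config$n_alleles)
  subs <- vector("list", config$n_alleles)
  seqs[1] <- ancestor
  subs[[1]] <- integer(0)
  tries <- 0L
  i <- 2L
  while (i <= n_base) {
    k <- min(nsite, max(1L, stats::rpois(1L, config$substitutions_per_allele)))
    sites <- sort(sample.int(nsite, k))
    chars <- anc_chars
    chars[site_pool$pos[sites]] <- site_pool$base[sites]
    candseq <- paste0(chars, collapse = "")
    if (candseq %in% seqs[seq_len(i - 1L)]) {
      tries <- tries + 1L
      if (tries > 500L) stop("generation error: cannot produce distinct alleles")
      next
    }
    seqs[i] <- candseq
    subs[[i]] <- sites
    i <- i + 1L
  }
  recomb_truth <- list()
  if (config$n_recombinants > 0L) {
    base_m <- do.call(rbind, strsplit(seqs[seq_len(n_base)], ""))
    for (r in seq_len(config$n_recombinants)) {
      ok <- FALSE
      for (attempt in 1:200) {
        par <- sample.int(n_base, 2L)
        p1 <- base_m[par[1], ]; p2 <- base_m[par[2], ]
        diffs <- which(p1 != p2)
        if (length(diffs) < 4L) next
        bp <- sample(diffs[-c(1, length(diffs))], 1L)  # internal crossover
        child <- c(p1[seq_len(bp - 1L)], p2[bp:length(p2)])
        childseq <- paste0(child, collapse = "")
        idx <- n_base + r
        if (childseq %in% seqs[seq_len(idx - 1L)]) next
        # crossover of stop-free parents can still create a stop at the
        # junction codon; resample if so
        if (any(ct[substring(childseq, 3 * (1:nc) - 2, 3 * (1:nc))] == "*")) next
        seqs[idx] <- childseq
        subs[[idx]] <- integer(0)
        recomb_truth[[length(recomb_truth) + 1L]] <-
          list(allele = idx, parents = par, breakpoint = bp)
        ok <- TRUE
        break
      }
      if (!ok) stop("generation error: could not place recombinant ", r)
    }
  }
  ids <- sprintf("A%02d", seq_len(config$n_alleles))
  aln <- codon_alignment(seqs, allele_ids = ids)
  for (t in seq_along(recomb_truth)) {
    recomb_truth[[t]]$allele <- ids[recomb_truth[[t]]$allele]
    recomb_truth[[t]]$parents <- ids[recomb_truth[[t]]$parents]
  }
  names(subs) <- ids
  list(alignment = aln,
       truth = list(ancestor = ancestor, site_pool = site_pool,
                    substitutions = subs, recombinants = recomb_truth,
                    pbs_codons = config$pbs_codons, seed = config$seed))
}

#' Generate a diploid genotype panel from an allele pool
#'
#' Allele frequencies are Dirichlet-drawn; under \code{"hwe"} each
#' individual's two alleles are i.i.d. draws, under \code{"excess_pairs"}
#' the probabilities of the designated combos are multiplied by the
#' enrichment factor and renormalized.  Degenerate IUPAC consensus sequences
#' are attached for phasing tests.
#'
#' @param alleles a \code{codon_alignment} (the pool).
#' @param config a \code{sim_config}.
#' @return list with \code{genotypes} (a \code{genotype_table} with a
#'   \code{degenerate} attribute) and \code{truth} (allele frequencies,
#'   true pairs).
#' @export
gen_panel <- function(alleles, config) {
  set.seed(config$seed + 1L)
  ids <- alleles$allele_ids
  k <- length(ids)
  g <- stats::rgamma(k, shape = config$dirichlet_alpha)
  freq <- g / sum(g)
  N <- config$panel_size
  if (config$mating == "hwe") {
    a <- sample.int(k, N, replace = TRUE, prob = freq)
    b <- sample.int(k, N, replace = TRUE, prob = freq)
  } else {
    pairs_idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
    pp <- ifelse(pairs_idx[, 1] == pairs_idx[, 2],
                 freq[pairs_idx[, 1]]^2,
                 2 * freq[pairs_idx[, 1]] * freq[pairs_idx[, 2]])
    labs <- paste(ids[pairs_idx[, 1]], ids[pairs_idx[, 2]], sep = "/")
    hit <- match(config$excess_combos, labs)
    if (anyNA(hit)) {
      stop("config error: unknown combo in excess_combos: ",
           paste(config$excess_combos[is.na(hit)], collapse = ", "))
    }
    pp[hit] <- pp[hit] * config$excess_factor
    pp <- pp / sum(pp)
    drawn <- sample.int(nrow(pairs_idx), N, replace = TRUE, prob = pp)
    a <- pairs_idx[drawn, 1]; b <- pairs_idx[drawn, 2]
    flip <- runif(N) < 0.5
    tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  }
  ind <- sprintf("I%03d", seq_len(N))
  deg <- vapply(seq_len(N), function(i)
    iupac_consensus(alleles$sequences[a[i]], alleles$sequences[b[i]]), "")
  names(deg) <- ind
  gt <- genotype_table(ind, ids[a], ids[b], degenerate = deg)
  list(genotypes = gt,
       truth = list(frequencies = setNames(freq, ids),
                    pairs = cbind(ids[a], ids[b])))
}

#' Generate nuclear families with Mendelian transmission
#'
#' Parents are drawn like panel individuals (HWE from Dirichlet
#' frequencies); every offspring receives one uniformly chosen allele from
#' each parent.  \code{corrupt} offspring (for power tests) get one allele
#' replaced by an allele carried by neither parent.
#'
#' @param alleles a \code{codon_alignment} (the pool).
#' @param config a \code{sim_config}.
#' @param corrupt number of offspring (across all families) to corrupt.
#' @return list with \code{families} (list of \code{family_record}s) and
#'   \code{truth} (data.frame of corrupted family/offspring indices; empty
#'   when \code{corrupt = 0}).
#' @export
gen_families <- function(alleles, config, corrupt = 0L) {
  set.seed(config$seed + 2L)
  ids <- alleles$allele_ids
  k <- length(ids)
  if (k < 2L) stop("domain error: need >= 2 alleles")
  g <- stats::rgamma(k, shape = config$dirichlet_alpha)
  freq <- g / sum(g)
  fams <- vector("list", config$n_families)
  for (f in seq_len(config$n_families)) {
    father <- ids[sample.int(k, 2L, replace = TRUE, prob = freq)]
    mother <- ids[sample.int(k, 2L, replace = TRUE, prob = freq)]
    noff <- sample(config$offspring_range[1]:config$offspring_range[2], 1L)
    offspring <- lapply(seq_len(noff), function(o) {
      c(sample(father, 1L), sample(mother, 1L))
    })
    fams[[f]] <- structure(list(family_id = sprintf("F%02d", f),
                                father = father, mother = mother,
                                offspring = offspring),
                           class = "family_record")
  }
  truth <- data.frame(family = integer(0), offspring = integer(0))
  if (corrupt > 0L) {
    slots <- do.call(rbind, lapply(seq_along(fams), function(f)
      data.frame(family = f, offspring = seq_along(fams[[f]]$offspring))))
    pick <- slots[sample.int(nrow(slots), corrupt), , drop = FALSE]
    done <- logical(nrow(pick))
    for (r in seq_len(nrow(pick))) {
      f <- pick$family[r]; o <- pick$offspring[r]
      fam <- fams[[f]]
      foreign <- setdiff(ids, c(fam$father, fam$mother))
      if (length(foreign) == 0L) next  # parents jointly carry every allele
      pair <- fam$offspring[[o]]
      pair[sample(1:2, 1L)] <- sample(foreign, 1L)
      fams[[f]]$offspring[[o]] <- pair
      done[r] <- TRUE
    }
    truth <- pick[done, , drop = FALSE]
  }
  list(families = fams, truth = truth)
}
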
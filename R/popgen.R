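# Hardy-Weinberg exact testing, the allelic-combination permutation test
# with sequential Bonferroni correction, EM haplotype phasing of degenerate
# diploid sequences, and Mendelian inheritance checking.

# log conditional probability statistic of a genotype-count configuration
# given allele counts: T = H*log(2) - sum(log g!) (constant terms dropped)
.hwe_stat <- function(pairs) {
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  g <- table(key)
  H <- sum(pairs[, 1] != pairs[, 2])
  H * log(2) - sum(lgamma(as.numeric(g) + 1))
}

# exact p by complete enumeration of genotype tables (<= 3 alleles);
# probability test: p = sum of P(table) over tables no more probable than obs
.hwe_enumerate <- function(pairs) {
  alleles <- sort(unique(c(pairs[, 1], pairs[, 2])))
  k <- length(alleles)
  m <- table(factor(c(pairs[, 1], pairs[, 2]), levels = alleles))
  m <- as.integer(m)
  n <- nrow(pairs)
  logP <- function(het, hom, H) {
    lgamma(n + 1) + sum(lgamma(m + 1)) + H * log(2) -
      lgamma(2 * n + 1) - sum(lgamma(c(het, hom) + 1))
  }
  # enumerate heterozygote counts g_ij (i < j); homozygotes follow
  pair_idx <- if (k > 1) combn(k, 2L) else matrix(0, 2, 0)
  np <- ncol(pair_idx)
  obs_stat <- .hwe_stat(pairs)
  total <- 0; below <- 0
  rec <- function(d, het) {
    if (d > np) {
      used <- rep(0L, k)
      for (q in seq_len(np)) {
        used[pair_idx[1, q]] <- used[pair_idx[1, q]] + het[q]
        used[pair_idx[2, q]] <- used[pair_idx[2, q]] + het[q]
      }
      rem <- m - used
      if (any(rem < 0L) || any(rem %% 2L != 0L)) return()
      hom <- rem %/% 2L
      H <- sum(het)
      lp <- logP(het, hom, H)
      stat <- H * log(2) - sum(lgamma(c(het, hom) + 1))
      total <<- total + exp(lp)
      if (stat <= obs_stat + 1e-9) below <<- below + exp(lp)
      return()
    }
    i <- pair_idx[1, d]; j <- pair_idx[2, d]
    for (v in 0:min(m[i], m[j])) rec(d + 1L, c(het, v))
  }
  rec(1L, integer(0))
  below / total
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact probability test: given the allele counts, genotype
#' tables under HWE are distributed as a random pairing of the 2n gametes.
#' For small problems (<= 3 alleles and <= 10 individuals) the null
#' distribution is enumerated completely; otherwise it is sampled by
#' repeatedly shuffling the gamete pool and re-pairing (the i.i.d.-sampling
#' equivalent of the Markov-chain exact test), with the +1 Monte-Carlo
#' correction.
#'
#' @param genotypes a \code{genotype_table} (>= 2 individuals).
#' @param mc_steps Monte-Carlo resamples (default 10000).
#' @param seed RNG seed.
#' @return list with \code{p}, \code{method} ("enumeration" or
#'   "monte-carlo"), \code{steps}.
#' @export
hwe_exact_test <- function(genotypes, mc_steps = 10000L, seed = 1L) {
  if (nrow(genotypes) < 2L) stop("insufficient-data error: need >= 2 individuals")
  pairs <- cbind(genotypes$allele1, genotypes$allele2)
  alleles <- unique(c(pairs))
  if (length(alleles) == 1L) {
    return(list(p = 1, method = "degenerate", steps = 0L))
  }
  if (length(alleles) <= 3L && nrow(pairs) <= 10L) {
    return(list(p = .hwe_enumerate(pairs), method = "enumeration", steps = NA_integer_))
  }
  set.seed(seed)
  pool <- c(pairs[, 1], pairs[, 2])
  n <- nrow(pairs)
  obs <- .hwe_stat(pairs)
  hits <- 0L
  for (r in seq_len(mc_steps)) {
    sh <- sample(pool)
    sim <- cbind(sh[seq_len(n)], sh[n + seq_len(n)])
    if (.hwe_stat(sim) <= obs + 1e-9) hits <- hits + 1L
  }
  list(p = (1 + hits) / (mc_steps + 1), method = "monte-carlo", steps = mc_steps)
}

#' Permutation test of allelic co-occurrence against the random-pairing null
#'
#' Each replicate draws, for every individual, two alleles i.i.d. from the
#' empirical allele frequencies; unordered combination counts across
#' replicates give the null.  One-sided excess p-values use the +1
#' correction; combinations never observed and never simulated get p = 1.
#'
#' @param genotypes a \code{genotype_table}.
#' @param reps permutation replicates (>= 1000 recommended for inference).
#' @param seed RNG seed.
#' @param alpha family-wise level for the sequential Bonferroni decisions.
#' @param two_sided also report two-sided p-values.
#' @param frequencies optional named allele frequencies for the null draw;
#'   by default the empirical frequencies of \code{genotypes} are used (the
#'   standard field practice).  Supplying the known generating frequencies
#'   removes the conditioning that otherwise makes the test conservative
#'   (useful for calibration studies).
#' @return object of class \code{combo_test_result}: data.frame \code{table}
#'   with combo, observed, simulated mean and 95% CI, one-sided p, Holm
#'   decision; plus \code{reps}, \code{seed}.
#' @export
allelic_combination_test <- function(genotypes, reps = 10000L, seed = 1L,
                                     alpha = 0.05, two_sided = FALSE,
                                     frequencies = NULL) {
  if (nrow(genotypes) == 0L) stop("domain error: empty genotype table")
  aset <- collapse_alleles(genotypes)
  if (!is.null(frequencies)) {
    miss <- setdiff(aset$allele_id, names(frequencies))
    if (length(miss)) stop("domain error: frequencies missing alleles: ",
                           paste(miss, collapse = ", "))
    aset <- data.frame(allele_id = names(frequencies),
                       frequency = as.numeric(frequencies) / sum(frequencies),
                       stringsAsFactors = FALSE)
  }
  k <- nrow(aset)
  N <- nrow(genotypes)
  ids <- aset$allele_id
  code_of <- function(a, b) {
    i <- pmin(a, b); j <- pmax(a, b)
    (i - 1L) * k + j          # unique code for unordered pair (i <= j)
  }
  all_pairs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  all_codes <- code_of(all_pairs[, 1], all_pairs[, 2])
  combo_label <- paste(ids[all_pairs[, 1]], ids[all_pairs[, 2]], sep = "/")
  obs_codes <- code_of(match(genotypes$allele1, ids), match(genotypes$allele2, ids))
  observed <- vapply(all_codes, function(cd) sum(obs_codes == cd), 0L)
  set.seed(seed)
  sim_counts <- matrix(0L, length(all_codes), reps)
  chunk <- max(1L, min(reps, as.integer(2e6 / N)))
  done <- 0L
  while (done < reps) {
    nb <- min(chunk, reps - done)
    a <- matrix(sample.int(k, N * nb, replace = TRUE, prob = aset$frequency), N, nb)
    b <- matrix(sample.int(k, N * nb, replace = TRUE, prob = aset$frequency), N, nb)
    cd <- code_of(a, b)
    f <- factor(cd, levels = all_codes)
    for (r in seq_len(nb)) {
      sim_counts[, done + r] <- tabulate(as.integer(f[((r - 1) * N + 1):(r * N)]),
                                         nbins = length(all_codes))
    }
    done <- done + nb
  }
  mean_sim <- rowMeans(sim_counts)
  ci <- t(apply(sim_counts, 1L, quantile, probs = c(0.025, 0.975)))
  p_ge <- (1 + rowSums(sim_counts >= observed)) / (reps + 1)
  p <- p_ge
  if (two_sided) {
    p_le <- (1 + rowSums(sim_counts <= observed)) / (reps + 1)
    p <- pmin(1, 2 * pmin(p_ge, p_le))
  }
  never <- observed == 0L & rowSums(sim_counts) == 0L
  p[never] <- 1
  holm <- sequential_bonferroni(p, alpha = alpha)
  tab <- data.frame(combo = combo_label,
                    observed = observed,
                    simulated_mean = mean_sim,
                    ci_lower = ci[, 1], ci_upper = ci[, 2],
                    p = p,
                    holm_adjusted_p = holm$adjusted_p,
                    holm_reject = holm$reject,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, reps = reps, seed = seed,
                 n_individuals = N, alpha = alpha,
                 two_sided = two_sided),
            class = "combo_test_result")
}

#' @export
print.combo_test_result <- function(x, ...) {
  sig <- x$table[x$table$p < x$alpha, , drop = FALSE]
  cat(sprintf("allelic-combination test: %d combos, %d individuals, %d reps\n",
              nrow(x$table), x$n_individuals, x$reps))
  cat(sprintf("%d combos at raw p < %.2f; %d significant after Holm\n",
              nrow(sig), x$alpha, sum(x$table$holm_reject)))
  invisible(x)
}

#' Write a combination-test table as TSV
#' @param result a \code{combo_test_result}.
#' @param path output file.
#' @export
write_combo_table <- function(result, path) {
  write.table(result$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sequential Bonferroni (Holm step-down) correction
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @param alpha family-wise error level.
#' @return list with \code{reject} (logical, original order),
#'   \code{adjusted_p} (Holm-adjusted), \code{alpha}.
#' @export
sequential_bonferroni <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1)) stop("domain error: p-values outside [0, 1]")
  adj <- p.adjust(pvals, method = "holm")
  list(reject = adj <= alpha, adjusted_p = adj, alpha = alpha)
}

.IUPAC2 <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))

#' IUPAC consensus of two haplotype sequences
#' @param a,b equal-length DNA strings.
#' @return degenerate consensus string.
#' @export
iupac_consensus <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  amb <- c(AG = "R", GA = "R", CT = "Y", TC = "Y", CG = "S", GC = "S",
           AT = "W", TA = "W", GT = "K", TG = "K", AC = "M", CA = "M")
  out <- x
  het <- x != y
  out[het] <- amb[paste0(x[het], y[het])]
  paste0(out, collapse = "")
}

# expand one degenerate sequence into all compatible unordered haplotype pairs
.expand_pairs <- function(dseq, max_het = 20L) {
  chars <- strsplit(dseq, "")[[1]]
  het <- which(!(chars %in% .BASES))
  h <- length(het)
  if (h > max_het) {
    stop("complexity error: ", h, " heterozygous positions (max ", max_het,
         "); prune sites before phasing")
  }
  if (h == 0L) {
    return(cbind(dseq, dseq))
  }
  opts <- lapply(chars[het], function(c) {
    o <- .IUPAC2[[c]]
    if (is.null(o)) stop("content error: unsupported IUPAC code '", c, "'")
    o
  })
  combos <- as.matrix(expand.grid(opts, stringsAsFactors = FALSE))
  # fix the first heterozygous site to break the ordered/unordered symmetry
  combos <- combos[combos[, 1] == opts[[1]][1], , drop = FALSE]
  pairs <- matrix("", nrow(combos), 2L)
  for (r in seq_len(nrow(combos))) {
    h1 <- chars; h2 <- chars
    h1[het] <- combos[r, ]
    h2[het] <- vapply(seq_len(h), function(s) setdiff(opts[[s]], combos[r, s]), "")
    pairs[r, ] <- c(paste0(h1, collapse = ""), paste0(h2, collapse = ""))
  }
  pairs
}

#' EM haplotype phasing of degenerate diploid sequences
#'
#' Excoffier-Slatkin EM over haplotype frequencies: each individual's IUPAC
#' consensus is expanded into its compatible unordered haplotype pairs and
#' the expected pair posteriors / frequency updates are iterated to
#' convergence.  Five seeded random restarts; the best-likelihood run is
#' kept.
#'
#' @param degenerate named character vector of IUPAC consensus sequences
#'   (equal length; at most 20 heterozygous positions each).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param n_starts random restarts (first start is frequency-uniform).
#' @param seed RNG seed.
#' @return object of class \code{phase_result}: \code{frequencies} (named),
#'   \code{individuals} (data.frame with best pair and posterior),
#'   \code{loglik_trajectory} of the winning start.
#' @export
em_phase <- function(degenerate, max_iter = 200L, tol = 1e-8,
                     n_starts = 5L, seed = 1L) {
  if (length(degenerate) == 0L) stop("domain error: no individuals")
  if (is.null(names(degenerate))) {
    names(degenerate) <- paste0("ind", seq_along(degenerate))
  }
  expansions <- lapply(degenerate, .expand_pairs)
  universe <- unique(unlist(expansions))
  H <- length(universe)
  # long-form (individual, pair) table
  ind_idx <- rep(seq_along(expansions), vapply(expansions, nrow, 0L))
  a_idx <- match(unlist(lapply(expansions, `[`, , 1L)), universe)
  b_idx <- match(unlist(lapply(expansions, `[`, , 2L)), universe)
  is_het <- a_idx != b_idx
  n <- length(degenerate)
  run_em <- function(f0) {
    f <- f0
    traj <- numeric(0)
    for (it in seq_len(max_iter)) {
      w <- f[a_idx] * f[b_idx] * ifelse(is_het, 2, 1)
      tot <- tapply(w, ind_idx, sum)[as.character(seq_len(n))]
      tot <- as.numeric(tot)
      ll <- sum(log(pmax(tot, 1e-300)))
      traj <- c(traj, ll)
      post <- w / tot[ind_idx]
      acc <- numeric(H)
      acc_a <- rowsum(post, a_idx)
      acc[as.integer(rownames(acc_a))] <- acc[as.integer(rownames(acc_a))] + acc_a[, 1]
      acc_b <- rowsum(post, b_idx)
      acc[as.integer(rownames(acc_b))] <- acc[as.integer(rownames(acc_b))] + acc_b[, 1]
      f <- acc / (2 * n)
      if (it > 1 && abs(traj[it] - traj[it - 1]) < tol) break
    }
    list(f = f, loglik = traj[length(traj)], traj = traj)
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    f0 <- if (s == 1L) rep(1 / H, H) else {
      x <- -log(runif(H)); x / sum(x)
    }
    fit <- run_em(f0)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  f <- best$f
  w <- f[a_idx] * f[b_idx] * ifelse(is_het, 2, 1)
  tot <- as.numeric(tapply(w, ind_idx, sum))
  post <- w / pmax(tot[ind_idx], 1e-300)
  best_rows <- vapply(seq_len(n), function(i) {
    rows <- which(ind_idx == i)
    rows[which.max(post[rows])]
  }, 0L)
  individuals <- data.frame(
    individual_id = names(degenerate),
    hap1 = universe[pmin(a_idx[best_rows], b_idx[best_rows])],
    hap2 = universe[pmax(a_idx[best_rows], b_idx[best_rows])],
    posterior = post[best_rows],
    stringsAsFactors = FALSE)
  structure(list(frequencies = setNames(f, universe),
                 individuals = individuals,
                 loglik_trajectory = best$traj),
            class = "phase_result")
}

#' Mendelian-compatibility check of one nuclear family
#'
#' An offspring's unordered pair \{x, y\} is compatible when one allele can
#' come from the father's pair and the other from the mother's.
#'
#' @param family a \code{family_record}.
#' @return object of class \code{mendel_report}: per-offspring data.frame
#'   (\code{compatible}, inferred \code{paternal}/\code{maternal} allele,
#'   NA when incompatible), \code{n_compatible}, \code{n_offspring}.
#' @export
mendel_check <- function(family) {
  F <- family$father; M <- family$mother
  rows <- lapply(seq_along(family$offspring), function(i) {
    pair <- family$offspring[[i]]
    x <- pair[1]; y <- pair[2]
    if (x %in% F && y %in% M) {
      data.frame(offspring = i, allele1 = x, allele2 = y, compatible = TRUE,
                 paternal = x, maternal = y)
    } else if (y %in% F && x %in% M) {
      data.frame(offspring = i, allele1 = x, allele2 = y, compatible = TRUE,
                 paternal = y, maternal = x)
    } else {
      data.frame(offspring = i, allele1 = x, allele2 = y, compatible = FALSE,
                 paternal = NA_character_, maternal = NA_character_)
    }
  })
  df <- do.call(rbind, rows)
  structure(list(family_id = family$family_id,
                 offspring = df,
                 n_compatible = sum(df$compatible),
                 n_offspring = nrow(df)),
            class = "mendel_report")
}

#' Mendelian check over a list of families
#' @param families list of \code{family_record}s.
#' @return list with per-family \code{reports}, \code{total_offspring},
#'   \code{total_compatible}.
#' @export
mendel_check_all <- function(families) {
  reports <- lapply(families, mendel_check)
  list(reports = reports,
       total_offspring = sum(vapply(reports, function(r) r$n_offspring, 0L)),
       total_compatible = sum(vapply(reports, function(r) r$n_compatible, 0L)))
}

#' @export
print.mendel_report <- function(x, ...) {
  cat(sprintf("family %s: %d/%d offspring Mendel-compatible\n",
              x$family_id, x$n_compatible, x$n_offspring))
  invisible(x)
}
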
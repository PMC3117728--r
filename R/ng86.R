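# Pathway-averaged Nei-Gojobori (1986) synonymous / non-synonymous counting
# with Jukes-Cantor multiple-hit correction, partition support and a
# codon-bootstrap Z-test of positive selection.
#
# Conventions (matching the MEGA behaviour this mirrors):
#  * mutations to stop codons count as non-synonymous in site counting
#    (the per-position denominator stays 3);
#  * mutational pathways passing through a stop codon are excluded and the
#    remaining pathways renormalized;
#  * distances are corrected per pair, then averaged across pairs
#    (within-group "overall mean").

.ng86_env <- new.env(parent = emptyenv())

sense_codons <- function() {
  ct <- codon_table()
  names(ct)[ct != "*"]
}

#' NG86 potential synonymous/non-synonymous site counts of one codon
#'
#' For each of the three positions the synonymous fraction is the number of
#' the 3 single-base neighbours that preserve the amino acid, divided by 3;
#' neighbours that are stop codons are non-synonymous.
#'
#' @param codon a sense codon string over A/C/G/T.
#' @return named numeric vector \code{c(n = , s = )} with \code{n + s = 3}.
#' @export
ng86_site_counts <- function(codon) {
  tab <- ng86_site_table()
  if (length(codon) != 1L || !codon %in% rownames(tab)) {
    stop("domain error: '", codon, "' is not a sense codon")
  }
  c(n = unname(tab[codon, "n"]), s = unname(tab[codon, "s"]))
}

# 61 x 2 lookup of (n, s) per sense codon, built once
ng86_site_table <- function() {
  if (!is.null(.ng86_env$site_tab)) return(.ng86_env$site_tab)
  ct <- codon_table()
  sense <- sense_codons()
  s <- vapply(sense, function(cod) {
    chars <- strsplit(cod, "")[[1]]
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(.BASES, chars[pos])) {
        mut <- chars; mut[pos] <- b
        mutc <- paste0(mut, collapse = "")
        if (ct[mutc] != "*" && ct[mutc] == ct[cod]) syn <- syn + 1
      }
    }
    syn / 3
  }, 0)
  tab <- cbind(n = 3 - s, s = s)
  rownames(tab) <- sense
  .ng86_env$site_tab <- tab
  tab
}

.PERMS <- list(list(1L),
               list(c(1L, 2L), c(2L, 1L)),
               list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

#' NG86 observed-difference contribution of one codon pair
#'
#' Averages the number of synonymous and non-synonymous steps over all
#' mutational pathways (orderings of the differing positions) between the two
#' codons; pathways whose intermediates are stop codons are excluded and the
#' average renormalized over the survivors.
#'
#' @param codonA,codonB sense codons.
#' @return list with \code{Nd}, \code{Sd}, \code{ndiff} and \code{n_pathways}
#'   (surviving pathways), or \code{NULL} (with a warning) when every pathway
#'   crosses a stop codon.
#' @export
ng86_pair <- function(codonA, codonB) {
  ct <- codon_table()
  if (is.na(ct[codonA]) || ct[codonA] == "*" || is.na(ct[codonB]) || ct[codonB] == "*") {
    stop("domain error: ng86_pair requires sense codons")
  }
  key <- paste(codonA, codonB)
  cache <- .ng86_env$pair_cache
  if (is.null(cache)) cache <- .ng86_env$pair_cache <- new.env(parent = emptyenv())
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  a <- strsplit(codonA, "")[[1]]
  b <- strsplit(codonB, "")[[1]]
  diffs <- which(a != b)
  k <- length(diffs)
  if (k == 0L) {
    res <- list(Nd = 0, Sd = 0, ndiff = 0L, n_pathways = 1L)
    cache[[key]] <- cache[[paste(codonB, codonA)]] <- res
    return(res)
  }
  nd <- sd <- 0
  surviving <- 0L
  for (ord in .PERMS[[k]]) {
    cur <- a
    path_nd <- path_sd <- 0
    ok <- TRUE
    for (step in ord) {
      nxt <- cur
      nxt[diffs[step]] <- b[diffs[step]]
      from <- paste0(cur, collapse = "")
      to <- paste0(nxt, collapse = "")
      if (ct[to] == "*") { ok <- FALSE; break }  # endpoints are sense, so a
      # stop here is an intermediate (or the step into it) -> drop pathway
      if (ct[from] == ct[to]) path_sd <- path_sd + 1 else path_nd <- path_nd + 1
      cur <- nxt
    }
    if (ok) {
      nd <- nd + path_nd; sd <- sd + path_sd
      surviving <- surviving + 1L
    }
  }
  if (surviving == 0L) {
    warning("all mutational pathways between ", codonA, " and ", codonB,
            " cross a stop codon; codon pair skipped")
    res <- NULL
  } else {
    res <- list(Nd = nd / surviving, Sd = sd / surviving, ndiff = k,
                n_pathways = surviving)
  }
  cache[[key]] <- cache[[paste(codonB, codonA)]] <- res
  res
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p proportion of sites differing, \code{0 <= p < 3/4}.
#' @return corrected distance \eqn{d = -\frac{3}{4}\ln(1 - 4p/3)}.
#' @export
jc_correct <- function(p) {
  if (any(p < 0)) stop("domain error: negative proportion")
  if (any(p >= 0.75)) stop("saturation error: p >= 3/4, JC distance undefined")
  -0.75 * log(1 - 4 * p / 3)
}

# Pair x codon decomposition of NG86 quantities for an alignment.
# Returns matrices (one row per unordered allele pair, one column per codon):
#  N, S  : potential site counts, (sites(codon_a) + sites(codon_b)) / 2
#  Nd, Sd: pathway-averaged observed differences
# Codon pairs with no stop-free pathway are excluded from that pair's counts
# (all four entries zeroed).
ng86_pair_matrices <- function(alignment) {
  cm <- codon_matrix(alignment)
  k <- nrow(cm); nc <- ncol(cm)
  if (k < 2L) stop("insufficient-data error: need >= 2 alleles")
  tab <- ng86_site_table()
  if (any(is.na(tab[cm, "n"]))) {
    stop("translation error: alignment contains stop codons")
  }
  nsites <- matrix(tab[cm, "n"], k, nc)
  ssites <- matrix(tab[cm, "s"], k, nc)
  pairs <- combn(k, 2L)
  np <- ncol(pairs)
  N <- S <- Nd <- Sd <- matrix(0, np, nc)
  labels <- character(np)
  ids <- rownames(cm)
  for (p in seq_len(np)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    labels[p] <- paste(ids[i], ids[j], sep = "|")
    N[p, ] <- (nsites[i, ] + nsites[j, ]) / 2
    S[p, ] <- (ssites[i, ] + ssites[j, ]) / 2
    diffc <- which(cm[i, ] != cm[j, ])
    for (cidx in diffc) {
      res <- ng86_pair(cm[i, cidx], cm[j, cidx])
      if (is.null(res)) {
        N[p, cidx] <- S[p, cidx] <- 0
      } else {
        Nd[p, cidx] <- res$Nd
        Sd[p, cidx] <- res$Sd
      }
    }
  }
  list(N = N, S = S, Nd = Nd, Sd = Sd, pair_labels = labels,
       allele_ids = ids, codon_count = nc)
}

# mean dN / dS over pairs from a pair x codon decomposition restricted to
# `cols`; returns c(dN, dS) (NA when a pair saturates)
.mean_dnds_from <- function(mats, cols) {
  Np <- rowSums(mats$N[, cols, drop = FALSE])
  Sp <- rowSums(mats$S[, cols, drop = FALSE])
  Ndp <- rowSums(mats$Nd[, cols, drop = FALSE])
  Sdp <- rowSums(mats$Sd[, cols, drop = FALSE])
  pN <- ifelse(Np > 0, Ndp / Np, 0)
  pS <- ifelse(Sp > 0, Sdp / Sp, 0)
  if (any(pN >= 0.75) || any(pS >= 0.75)) return(c(NA_real_, NA_real_))
  c(mean(-0.75 * log(1 - 4 * pN / 3)), mean(-0.75 * log(1 - 4 * pS / 3)))
}

#' Mean pairwise dN and dS (NG86 + Jukes-Cantor), optionally on a partition
#'
#' For every unordered allele pair, observed synonymous / non-synonymous
#' differences are accumulated by pathway averaging and divided by the
#' potential site counts; each pair's pN and pS are Jukes-Cantor corrected
#' and the corrected distances averaged over pairs.
#'
#' @param alignment a \code{codon_alignment} (>= 2 alleles, stop-free).
#' @param partition optional 1-based codon indices restricting the analysis
#'   (e.g. the PBS or non-PBS set).
#' @param partition_label text label carried into the result.
#' @return object of class \code{dnds_result}: \code{dN}, \code{dS},
#'   \code{ratio} (Inf flagged when dS = 0), counts \code{N}, \code{S},
#'   \code{Nd}, \code{Sd} (totals over pairs), \code{n_codons},
#'   \code{n_alleles}, \code{partition_label}.
#' @export
mean_dn_ds <- function(alignment, partition = NULL, partition_label = "all") {
  mats <- ng86_pair_matrices(alignment)
  cols <- if (is.null(partition)) seq_len(mats$codon_count) else as.integer(partition)
  if (length(cols) == 0L) stop("domain error: empty partition")
  if (any(cols < 1L | cols > mats$codon_count)) {
    stop("domain error: partition index outside 1..", mats$codon_count)
  }
  d <- .mean_dnds_from(mats, cols)
  if (any(is.na(d))) stop("saturation error: a pair exceeds p = 3/4")
  ratio <- if (d[2] == 0) Inf else d[1] / d[2]
  # distinct alleles within the partition (duplicated subsequences collapse)
  cm_part <- codon_matrix(alignment)[, cols, drop = FALSE]
  n_distinct <- length(unique(apply(cm_part, 1L, paste0, collapse = "")))
  structure(list(dN = d[1], dS = d[2], ratio = ratio,
                 N = sum(mats$N[, cols]) / nrow(mats$N),
                 S = sum(mats$S[, cols]) / nrow(mats$S),
                 Nd = sum(mats$Nd[, cols]) / nrow(mats$Nd),
                 Sd = sum(mats$Sd[, cols]) / nrow(mats$Sd),
                 n_codons = length(cols),
                 n_alleles = n_distinct,
                 partition_label = partition_label),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("NG86/JC [%s] %d codons, %d alleles: dN = %.3f, dS = %.3f, dN/dS = %s\n",
              x$partition_label, x$n_codons, x$n_alleles, x$dN, x$dS,
              if (is.infinite(x$ratio)) "Inf (dS = 0)" else sprintf("%.2f", x$ratio)))
  invisible(x)
}

#' Bootstrap Z-test of positive selection (dN > dS)
#'
#' Variances of the mean dN and dS are estimated by resampling codon columns
#' with replacement; \eqn{Z = (dN - dS) / \sqrt{Var(dN) + Var(dS)}} is
#' referred to the standard normal, one-tailed for the alternative dN > dS.
#'
#' @param alignment a \code{codon_alignment}.
#' @param partition optional codon index subset.
#' @param reps bootstrap replicates (>= 100).
#' @param seed integer RNG seed.
#' @return list with \code{z}, \code{p}, \code{dN}, \code{dS},
#'   \code{var_dN}, \code{var_dS}, \code{reps}.
#' @export
z_test_positive_selection <- function(alignment, partition = NULL,
                                      reps = 1000L, seed = 1L) {
  if (reps < 100L) stop("domain error: reps must be >= 100")
  mats <- ng86_pair_matrices(alignment)
  cols <- if (is.null(partition)) seq_len(mats$codon_count) else as.integer(partition)
  obs <- .mean_dnds_from(mats, cols)
  if (any(is.na(obs))) stop("saturation error in observed distances")
  if (sum(mats$Nd[, cols]) + sum(mats$Sd[, cols]) == 0) {
    return(list(z = 0, p = 1, dN = 0, dS = 0, var_dN = 0, var_dS = 0, reps = reps))
  }
  set.seed(seed)
  nb <- length(cols)
  boot <- matrix(NA_real_, reps, 2L)
  for (r in seq_len(reps)) {
    boot[r, ] <- .mean_dnds_from(mats, sample(cols, nb, replace = TRUE))
  }
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  v <- apply(boot, 2L, var)
  if (sum(v) == 0) {
    z <- 0; p <- 1
  } else {
    z <- (obs[1] - obs[2]) / sqrt(sum(v))
    p <- pnorm(z, lower.tail = FALSE)
  }
  list(z = z, p = p, dN = obs[1], dS = obs[2],
       var_dN = v[1], var_dS = v[2], reps = reps)
}

#' Write partitioned dN/dS results as a table mirroring the standard report
#'
#' @param results list of \code{dnds_result} objects.
#' @param path output TSV.
#' @param samples optional number of individuals to report per row.
#' @export
write_dnds_table <- function(results, path, samples = NA) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(Locus = r$partition_label,
               Length_bp = 3L * r$n_codons,
               Samples = samples,
               Alleles = r$n_alleles,
               dN = round(r$dN, 3), dS = round(r$dS, 3),
               dN_dS = if (is.infinite(r$ratio)) NA else round(r$ratio, 2))
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
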
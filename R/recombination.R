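# Minimal-cost mosaic detection of intralocus recombinants: each allele is
# explained from the remaining alleles by mutation (per-column mismatch cost
# 1) and recombination (source switch cost rho); the saving of the best
# mosaic over the best single source, referred to a column-permutation null,
# flags recombinant alleles.

#' Minimal mosaic explanation cost of a target sequence
#'
#' Dynamic program over columns with state = current source sequence:
#' per-column cost 1 where the source mismatches the target, plus \code{rho}
#' per switch between distinct sources.  Ties are broken toward fewer
#' switches, then lower source index.
#'
#' @param target a DNA string.
#' @param sources character vector (>= 2) of equal-length strings.
#' @param rho switch penalty in mutation-equivalents (default 1).
#' @return list with \code{cost}, \code{path} (source index per column),
#'   \code{breakpoints} (1-based columns where a new source starts),
#'   \code{single_cost} (best single-source mismatch count) and
#'   \code{savings}.
#' @export
mosaic_cost <- function(target, sources, rho = 1) {
  if (length(sources) < 2L) stop("domain error: need >= 2 source sequences")
  tg <- strsplit(target, "")[[1]]
  sm <- do.call(rbind, strsplit(sources, ""))
  if (ncol(sm) != length(tg)) stop("alignment error: unequal lengths")
  L <- length(tg)
  ns <- nrow(sm)
  M <- sweep(sm, 2L, tg, "!=") * 1
  C <- matrix(0, ns, L)
  C[, 1] <- M[, 1]
  for (l in 2:L) {
    bp <- min(C[, l - 1]) + rho
    C[, l] <- M[, l] + pmin(C[, l - 1], bp)
  }
  cost <- min(C[, L])
  # traceback, preferring to stay on the same source (fewer switches), then
  # the lowest source index
  path <- integer(L)
  path[L] <- which(C[, L] == cost)[1]
  for (l in L:2) {
    s <- path[l]
    stay <- C[s, l - 1] + M[s, l]
    if (abs(stay - C[s, l]) < 1e-9) {
      path[l - 1] <- s
    } else {
      prev_min <- min(C[, l - 1])
      path[l - 1] <- which(C[, l - 1] == prev_min)[1]
    }
  }
  breakpoints <- which(diff(path) != 0) + 1L
  single <- min(rowSums(M))
  list(cost = cost, path = path, breakpoints = breakpoints,
       single_cost = single, savings = single - cost)
}

# cost-only DP on a precomputed mismatch matrix with columns in `ord`
.mosaic_cost_fast <- function(M, ord, rho) {
  c <- M[, ord[1]]
  for (l in ord[-1]) {
    c <- M[, l] + pmin(c, min(c) + rho)
  }
  min(c)
}

#' Permutation scan for recombinant alleles
#'
#' For each allele as target (sources = all other alleles), the mosaic
#' saving is computed on the variable columns of the alignment (invariant
#' columns carry no cost).  The null distribution permutes the variable
#' column order -- the same permutation applied to every sequence, which
#' destroys mosaic structure but preserves the per-column mismatch pattern;
#' the single-source cost is permutation-invariant.
#'
#' @param alignment a \code{codon_alignment} (>= 3 alleles).
#' @param rho switch penalty (default 1).
#' @param reps permutations (>= 100).
#' @param seed RNG seed.
#' @return object of class \code{recomb_scan}: data.frame \code{table} with
#'   allele, single_cost, mosaic_cost, savings, breakpoints (nucleotide
#'   columns, comma-joined), p; plus \code{rho}, \code{reps}, \code{seed}.
#' @export
recomb_pvalues <- function(alignment, rho = 1, reps = 1000L, seed = 1L) {
  if (reps < 100L) stop("domain error: reps must be >= 100")
  m <- aln_matrix(alignment)
  k <- nrow(m)
  if (k < 3L) stop("domain error: need >= 3 alleles (>= 2 sources per target)")
  varcols <- which(apply(m, 2L, function(col) length(unique(col)) > 1L))
  ids <- rownames(m)
  if (length(varcols) < 2L) {
    tab <- data.frame(allele = ids, single_cost = 0, mosaic_cost = 0,
                      savings = 0, breakpoints = "", p = 1,
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, rho = rho, reps = reps, seed = seed,
                          variable_columns = varcols),
                     class = "recomb_scan"))
  }
  mv <- m[, varcols, drop = FALSE]
  nv <- length(varcols)
  # observed scan with traceback in variable-column space
  obs <- lapply(seq_len(k), function(i) {
    res <- mosaic_cost(paste0(mv[i, ], collapse = ""),
                       apply(mv[-i, , drop = FALSE], 1L, paste0, collapse = ""),
                       rho = rho)
    res$breakpoints_nt <- varcols[res$breakpoints]
    res
  })
  Ms <- lapply(seq_len(k), function(i) {
    sweep(mv[-i, , drop = FALSE], 2L, mv[i, ], "!=") * 1
  })
  set.seed(seed)
  exceed <- integer(k)
  obs_sav <- vapply(obs, function(o) o$savings, 0)
  single <- vapply(obs, function(o) o$single_cost, 0)
  for (r in seq_len(reps)) {
    ord <- sample.int(nv)
    for (i in seq_len(k)) {
      sav <- single[i] - .mosaic_cost_fast(Ms[[i]], ord, rho)
      if (sav >= obs_sav[i]) exceed[i] <- exceed[i] + 1L
    }
  }
  p <- (1 + exceed) / (reps + 1)
  tab <- data.frame(allele = ids,
                    single_cost = single,
                    mosaic_cost = vapply(obs, function(o) o$cost, 0),
                    savings = obs_sav,
                    breakpoints = vapply(obs, function(o)
                      paste(o$breakpoints_nt, collapse = ","), ""),
                    p = p, stringsAsFactors = FALSE)
  structure(list(table = tab, rho = rho, reps = reps, seed = seed,
                 variable_columns = varcols),
            class = "recomb_scan")
}

#' @export
print.recomb_scan <- function(x, ...) {
  sig <- x$table$allele[x$table$p < 0.05]
  cat(sprintf("recombination scan (rho = %g, %d permutations): %d alleles, %d variable columns\n",
              x$rho, x$reps, nrow(x$table), length(x$variable_columns)))
  cat("alleles at p < 0.05:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Scan over a sweep of switch penalties
#'
#' @param alignment a \code{codon_alignment}.
#' @param rhos switch penalties to try (default \code{c(0.5, 1, 2)}).
#' @param reps,seed as in \code{\link{recomb_pvalues}}.
#' @return named list of \code{recomb_scan}s, one per rho.
#' @export
recomb_rho_sweep <- function(alignment, rhos = c(0.5, 1, 2), reps = 1000L,
                             seed = 1L) {
  setNames(lapply(rhos, function(r)
    recomb_pvalues(alignment, rho = r, reps = reps, seed = seed)),
    paste0("rho=", rhos))
}

#' Write a recombination scan as TSV
#' @param scan a \code{recomb_scan}.
#' @param path output file.
#' @export
write_recomb_scan <- function(scan, path) {
  write.table(scan$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
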
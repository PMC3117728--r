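# Polymorphism and heterozygosity summaries of the exon-2 alignment and
# genotype panel.

#' Nucleotide diversity (pi)
#'
#' Mean pairwise proportion of differing sites.  Unweighted mode averages the
#' p-distance over all unordered pairs of unique alleles (the conventional
#' input when a diversity program is fed the allele FASTA).  Weighted mode
#' uses allele frequencies: \eqn{\pi = \frac{n}{n-1}\sum_{i<j} 2 w_i w_j
#' d_{ij} / L} with \eqn{n} the number of chromosomes.
#'
#' @param alignment a \code{codon_alignment} with at least 2 sequences.
#' @param weights optional numeric vector of allele frequencies (named by
#'   allele ID or in alignment order) summing to 1; switches on weighted mode.
#' @param n_chromosomes number of sampled chromosomes (2 x individuals);
#'   required for the small-sample factor in weighted mode.
#' @return pi, a number in [0, 1].
#' @export
nucleotide_diversity <- function(alignment, weights = NULL, n_chromosomes = NULL) {
  m <- aln_matrix(alignment)
  k <- nrow(m)
  if (k < 2L) stop("insufficient-data error: need >= 2 sequences")
  L <- ncol(m)
  d <- pairwise_diff_matrix(m)
  if (is.null(weights)) {
    return(mean(d[upper.tri(d)]) / L)
  }
  if (!is.null(names(weights))) weights <- weights[rownames(m)]
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  pi_w <- sum(2 * outer(weights, weights) * d * upper.tri(d)) / L
  if (!is.null(n_chromosomes)) pi_w <- pi_w * n_chromosomes / (n_chromosomes - 1)
  pi_w
}

# symmetric matrix of pairwise nucleotide difference counts
pairwise_diff_matrix <- function(m) {
  k <- nrow(m)
  d <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

#' Polymorphism summary of an in-frame alignment
#'
#' Counts segregating nucleotide columns, variable amino-acid columns, and
#' segregating columns whose variation is synonymous in every pairwise codon
#' context (each allele keeping its own state at the other two codon
#' positions).
#'
#' @param alignment a \code{codon_alignment}.
#' @return list with \code{segregating_sites}, \code{variable_nt_sites}
#'   (1-based columns), \code{variable_aa_sites} (1-based codon indices),
#'   \code{n_variable_aa_sites}, \code{synonymous_substitutions}.
#' @export
polymorphism_summary <- function(alignment) {
  m <- aln_matrix(alignment)
  seg_cols <- which(apply(m, 2L, function(col) length(unique(col)) > 1L))
  prot <- translate_alignment(alignment)
  pm <- do.call(rbind, strsplit(unname(prot), ""))
  aa_var <- which(apply(pm, 2L, function(col) length(unique(col)) > 1L))
  cm <- codon_matrix(alignment)
  ct <- codon_table()
  syn_cols <- integer(0)
  for (col in seg_cols) {
    codon_idx <- (col - 1L) %/% 3L + 1L
    codons <- cm[, codon_idx]
    aas <- ct[codons]
    # column is synonymous iff all alleles (in their own codon context)
    # encode the same amino acid at the containing codon
    if (length(unique(aas)) == 1L) syn_cols <- c(syn_cols, col)
  }
  list(segregating_sites = length(seg_cols),
       variable_nt_sites = seg_cols,
       variable_aa_sites = aa_var,
       n_variable_aa_sites = length(aa_var),
       synonymous_substitutions = length(syn_cols))
}

#' Observed heterozygosity of a genotype panel
#'
#' @param genotypes a \code{genotype_table}.
#' @return list with \code{heterozygotes}, \code{total}, \code{fraction}.
#' @export
heterozygosity <- function(genotypes) {
  if (nrow(genotypes) == 0L) stop("insufficient-data error: empty genotype table")
  het <- sum(genotypes$allele1 != genotypes$allele2)
  list(heterozygotes = het, total = nrow(genotypes),
       fraction = het / nrow(genotypes))
}

#' Full diversity summary
#'
#' Convenience wrapper assembling pi, polymorphism counts and (optionally)
#' observed heterozygosity into one record; exportable as TSV/JSON.
#'
#' @param alignment a \code{codon_alignment}.
#' @param genotypes optional \code{genotype_table}.
#' @param weights optional allele frequencies for weighted pi.
#' @return list of class \code{diversity_summary}.
#' @export
diversity_summary <- function(alignment, genotypes = NULL, weights = NULL) {
  poly <- polymorphism_summary(alignment)
  out <- c(list(pi = nucleotide_diversity(alignment, weights = weights)), poly)
  if (!is.null(genotypes)) {
    het <- heterozygosity(genotypes)
    out$observed_heterozygosity <- het$fraction
    out$heterozygotes <- het$heterozygotes
    out$n_individuals <- het$total
  }
  class(out) <- "diversity_summary"
  out
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("pi = %.4f | S = %d segregating sites | %d variable aa sites | %d synonymous\n",
              x$pi, x$segregating_sites, x$n_variable_aa_sites,
              x$synonymous_substitutions))
  if (!is.null(x$observed_heterozygosity)) {
    cat(sprintf("observed heterozygosity = %d/%d = %.3f\n",
                x$heterozygotes, x$n_individuals, x$observed_heterozygosity))
  }
  invisible(x)
}

#' Write a diversity summary as a one-row TSV or as JSON
#' @param summary a \code{diversity_summary}.
#' @param path output file.
#' @param format \code{"tsv"} (default) or \code{"json"}.
#' @export
write_diversity_summary <- function(summary, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- data.frame(pi = summary$pi,
                   segregating_sites = summary$segregating_sites,
                   variable_aa_sites = summary$n_variable_aa_sites,
                   synonymous_substitutions = summary$synonymous_substitutions,
                   observed_heterozygosity = summary$observed_heterozygosity %||% NA,
                   heterozygotes = summary$heterozygotes %||% NA,
                   n_individuals = summary$n_individuals %||% NA)
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(as.list(df), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
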
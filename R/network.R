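# Minimum-spanning haplotype network with retained ties: edges tied at the
# distance that first connects two components are all kept, producing the
# reticulation loops characteristic of recombinant alleles.

#' Build a haplotype network over alleles
#'
#' Identical sequences are merged into single nodes (frequencies summed).
#' Edges are added in increasing distance order; within one distance class
#' every pair joining two components (as they stood before the class) is
#' retained, so tied alternative connections form loops.  Each edge carries
#' the nucleotide distance and the amino-acid substitutions between its
#' endpoints (labels like \code{"S45T"}, 1-based codon numbering).
#'
#' @param alleles an \code{allele_set} (for node frequencies) or NULL for
#'   uniform frequencies.
#' @param alignment a \code{codon_alignment} (>= 2 alleles).
#' @param dist_mode \code{"nucleotide"} (default) or \code{"aa"}
#'   (non-synonymous-only distances, i.e. amino-acid differences).
#' @return object of class \code{haplotype_network}: \code{nodes}
#'   (data.frame: node, members, frequency), \code{edges} (data.frame: from,
#'   to, distance, aa_subs), \code{n_loops} (independent cycles),
#'   \code{graph} (igraph object).
#' @export
build_network <- function(alleles, alignment, dist_mode = c("nucleotide", "aa")) {
  dist_mode <- match.arg(dist_mode)
  seqs <- alignment$sequences
  if (length(seqs) < 1L) stop("domain error: empty alignment")
  freqs <- if (is.null(alleles)) {
    setNames(rep(1 / length(seqs), length(seqs)), names(seqs))
  } else setNames(alleles$frequency, alleles$allele_id)[names(seqs)]
  freqs[is.na(freqs)] <- 0
  # merge identical sequences
  grp <- match(seqs, unique(seqs))
  node_ids <- vapply(seq_len(max(grp)), function(g) names(seqs)[grp == g][1], "")
  members <- vapply(seq_len(max(grp)), function(g)
    paste(names(seqs)[grp == g], collapse = ","), "")
  node_freq <- vapply(seq_len(max(grp)), function(g) sum(freqs[grp == g]), 0)
  rep_seq <- unique(seqs)
  nn <- length(rep_seq)
  nodes <- data.frame(node = node_ids, members = members,
                      frequency = node_freq, stringsAsFactors = FALSE)
  prot <- translate_alignment(codon_alignment(rep_seq, allele_ids = node_ids))
  pm <- do.call(rbind, strsplit(unname(prot), ""))
  nt <- do.call(rbind, strsplit(rep_seq, ""))
  if (nn == 1L) {
    g <- igraph::make_empty_graph(n = 1, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = node_ids)
    g <- igraph::set_vertex_attr(g, "frequency", value = node_freq)
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(0), to = character(0),
                                             distance = numeric(0), aa_subs = character(0)),
                          n_loops = 0L, graph = g, dist_mode = dist_mode),
                     class = "haplotype_network"))
  }
  d <- matrix(0, nn, nn)
  for (i in seq_len(nn - 1L)) {
    for (j in (i + 1L):nn) {
      d[i, j] <- d[j, i] <- if (dist_mode == "nucleotide") {
        sum(nt[i, ] != nt[j, ])
      } else sum(pm[i, ] != pm[j, ])
    }
  }
  # Kruskal with retained ties: evaluate component membership before each
  # distance class, keep every within-class pair that bridges two components
  comp <- seq_len(nn)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  edges <- list()
  for (delta in sort(unique(d[upper.tri(d)]))) {
    if (delta == 0) next
    pre <- vapply(seq_len(nn), find, 0L)
    if (length(unique(pre)) == 1L) break
    cand <- which(upper.tri(d) & d == delta, arr.ind = TRUE)
    added <- FALSE
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (pre[i] != pre[j]) {
        aa_diff <- which(pm[i, ] != pm[j, ])
        label <- paste0(pm[i, aa_diff], aa_diff, pm[j, aa_diff], collapse = ",")
        edges[[length(edges) + 1L]] <- data.frame(
          from = node_ids[i], to = node_ids[j],
          distance = d[i, j],
          aa_subs = if (length(aa_diff)) label else "",
          stringsAsFactors = FALSE)
        added <- TRUE
      }
    }
    if (added) {
      for (e in edges) {
        ri <- find(match(e$from, node_ids)); rj <- find(match(e$to, node_ids))
        if (ri != rj) comp[ri] <- rj
      }
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0),
               distance = numeric(0), aa_subs = character(0))
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = nodes[, "node", drop = FALSE])
  g <- igraph::set_vertex_attr(g, "frequency", value = nodes$frequency)
  ncomp <- igraph::components(g)$no
  n_loops <- nrow(edf) - nn + ncomp
  structure(list(nodes = nodes, edges = edf, n_loops = n_loops,
                 graph = g, dist_mode = dist_mode),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype network: %d nodes, %d edges, %d loop(s) [%s distances]\n",
              nrow(x$nodes), nrow(x$edges), x$n_loops, x$dist_mode))
  invisible(x)
}

#' Rebuild the network after excluding alleles
#'
#' The network is reconstructed from scratch on the remaining alleles, so
#' topology may shift (typical when pruning recombinants).
#'
#' @param alleles an \code{allele_set} or NULL.
#' @param alignment a \code{codon_alignment}.
#' @param exclude allele IDs to drop.
#' @param dist_mode as in \code{\link{build_network}}.
#' @return a \code{haplotype_network}.
#' @export
prune_and_rebuild <- function(alleles, alignment, exclude = character(0),
                              dist_mode = c("nucleotide", "aa")) {
  dist_mode <- match.arg(dist_mode)
  bad <- setdiff(exclude, alignment$allele_ids)
  if (length(bad)) stop("domain error: unknown alleles in exclude: ",
                        paste(bad, collapse = ", "))
  keep <- setdiff(alignment$allele_ids, exclude)
  if (length(keep) == 0L) stop("domain error: cannot exclude every allele")
  sub <- codon_alignment(alignment$sequences[keep], allele_ids = keep,
                         frame_offset = alignment$frame_offset)
  asub <- if (is.null(alleles)) NULL else {
    a <- alleles[alleles$allele_id %in% keep, , drop = FALSE]
    a$frequency <- a$frequency / sum(a$frequency)
    a
  }
  build_network(asub, sub, dist_mode = dist_mode)
}

#' Export a haplotype network
#'
#' @param network a \code{haplotype_network}.
#' @param path output file.
#' @param format \code{"tsv"} (edge list), \code{"dot"} or \code{"graphml"}.
#' @export
write_network <- function(network, path, format = c("tsv", "dot", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(network$graph, path, format = format)
  }
  invisible(path)
}
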
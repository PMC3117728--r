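# Shared fixture builders: everything is generated in code, no binary data.

# independent oracle: recursive depth-first enumeration of all mutational
# pathways between two codons, excluding pathways through stop codons
# (deliberately separate from the package's iterative permutation walk)
oracle_pair <- function(a, b) {
  ct <- Biostrings::GENETIC_CODE
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  paths <- list()
  walk <- function(cur, remaining, nd, sd) {
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- c(nd, sd)
      return()
    }
    for (r in seq_along(remaining)) {
      pos <- remaining[r]
      nxt <- cur
      nxt[pos] <- bv[pos]
      to <- paste0(nxt, collapse = "")
      if (ct[[to]] == "*") next
      from <- paste0(cur, collapse = "")
      syn <- ct[[from]] == ct[[to]]
      walk(nxt, remaining[-r], nd + !syn, sd + syn)
    }
  }
  walk(av, which(av != bv), 0, 0)
  if (length(paths) == 0L) return(NULL)
  m <- do.call(rbind, paths)
  c(Nd = mean(m[, 1]), Sd = mean(m[, 2]))
}

# tiny in-frame alignment with known differences
toy_alignment <- function() {
  codon_alignment(c(a = "ATGAAATTTGGA",
                    b = "ATGAAGTTTGGA",   # codon 2 AAA->AAG (syn)
                    c = "ATGAAAGTTGGA"))  # codon 3 TTT->GTT (nonsyn)
}

# write a FASTA with given sequences, return path
write_tmp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# fixed ladder-topology tree for simulations (deterministic shape, any n)
sim_tree <- function(ntip, bl = 0.05) {
  tree <- ape::stree(ntip, type = "left")
  tree$edge.length <- rep(bl, nrow(tree$edge))
  tree$tip.label <- sprintf("t%02d", seq_len(ntip))
  tree
}

# path to the transcribed printed pedigree table
table1_path <- function() {
  system.file("extdata", "table1_families.tsv", package = "mhc2div")
}

# deposited exon-2 alleles: requires a one-time fetch impossible in an
# offline environment; tests depending on it look for a user-provided file
deposited_alignment_path <- function() {
  p <- getOption("mhc2div.deposited_fasta",
                 system.file("extdata", "deposited", "hq_exon2_alleles.fasta",
                             package = "mhc2div"))
  if (is.null(p) || !nzchar(p) || !file.exists(p)) NA_character_ else p
}
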
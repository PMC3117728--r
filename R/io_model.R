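#' @importFrom stats optim pchisq pnorm pbeta qbeta runif setNames
#'   quantile sd var p.adjust
#' @importFrom utils read.delim write.table combn head tail
"_PACKAGE"

# Standard genetic code as a named character vector, codon -> single-letter
# amino acid ("*" = stop).  Taken from Biostrings at load time so the table
# cannot drift from the reference implementation.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

.BASES <- c("A", "C", "G", "T")

#' In-frame codon alignment
#'
#' Container for an aligned set of same-length, gap-free, in-frame DNA
#' sequences (one per allele).  This is the central object consumed by the
#' diversity, selection, recombination and network stages.
#'
#' @param sequences character vector of uppercase DNA sequences over
#'   \code{A/C/G/T}, all the same length, length divisible by 3.
#' @param allele_ids unique labels, one per sequence.  Defaults to the names
#'   of \code{sequences}.
#' @param frame_offset integer vector \code{c(leading, trailing)} recording
#'   how many nucleotides were trimmed to reach the reading frame.
#' @return An object of class \code{codon_alignment} with fields
#'   \code{allele_ids}, \code{sequences} (named), \code{frame_offset} and
#'   \code{codon_count}.
#' @export
codon_alignment <- function(sequences, allele_ids = names(sequences),
                            frame_offset = c(0L, 0L)) {
  if (is.null(allele_ids)) {
    allele_ids <- paste0("allele", seq_along(sequences))
  }
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 1L) stop("alignment error: no sequences")
  if (anyDuplicated(allele_ids)) stop("alignment error: allele_ids not unique")
  len <- unique(nchar(sequences))
  if (length(len) != 1L) {
    stop("alignment error: ragged sequence lengths (", paste(len, collapse = ", "), ")")
  }
  if (len %% 3L != 0L) {
    stop("frame error: alignment length ", len, " not divisible by 3")
  }
  bad <- gregexpr("[^ACGT]", sequences)
  for (i in seq_along(sequences)) {
    pos <- bad[[i]][1]
    if (pos != -1L) {
      stop("content error: record '", allele_ids[i], "' has non-ACGT character '",
           substr(sequences[i], pos, pos), "' at column ", pos)
    }
  }
  structure(
    list(allele_ids = as.character(allele_ids),
         sequences = setNames(sequences, allele_ids),
         frame_offset = as.integer(frame_offset),
         codon_count = as.integer(len / 3L)),
    class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$sequences), "alleles x",
      x$codon_count, "codons (", 3L * x$codon_count, "bp; trimmed ",
      x$frame_offset[1], "+", x$frame_offset[2], ")\n", sep = " ")
  invisible(x)
}

#' @export
length.codon_alignment <- function(x) length(x$sequences)

# alignment as a character matrix (alleles x nucleotide columns)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$sequences), ""))
  rownames(m) <- aln$allele_ids
  m
}

# alleles x codon columns matrix of 3-mers
codon_matrix <- function(aln) {
  n <- aln$codon_count
  m <- matrix("", length(aln$sequences), n, dimnames = list(aln$allele_ids, NULL))
  for (i in seq_len(n)) {
    m[, i] <- substr(unname(aln$sequences), 3L * i - 2L, 3L * i)
  }
  m
}

#' Restrict a codon alignment to a subset of codons
#'
#' @param aln a \code{codon_alignment}.
#' @param codons 1-based codon indices to keep (order respected).
#' @return a new \code{codon_alignment} over the selected codons.
#' @export
subset_codons <- function(aln, codons) {
  codons <- as.integer(codons)
  if (length(codons) == 0L) stop("domain error: empty codon subset")
  if (any(codons < 1L | codons > aln$codon_count)) {
    stop("domain error: codon index outside 1..", aln$codon_count)
  }
  cm <- codon_matrix(aln)[, codons, drop = FALSE]
  codon_alignment(apply(cm, 1L, paste0, collapse = ""),
                  allele_ids = aln$allele_ids,
                  frame_offset = aln$frame_offset)
}

#' Read a FASTA alignment and trim to the reading frame
#'
#' Reads an aligned FASTA file, removes \code{trim_leading} nucleotides from
#' the start and \code{trim_trailing} from the end of every record (exon-
#' spanning partial codons), and validates the in-frame invariants.  The
#' defaults (2, 1) correspond to a 273-bp class II exon 2 whose complete
#' reading frame is the internal 270 bp / 90 codons.
#'
#' @param path FASTA file of equal-length aligned DNA sequences.
#' @param trim_leading,trim_trailing non-negative nucleotide counts to strip.
#' @return a \code{codon_alignment}; \code{frame_offset} records the trims.
#' @export
read_alignment <- function(path, trim_leading = 2L, trim_trailing = 1L) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) {
    stop("alignment error: ragged record lengths in ", path)
  }
  if (trim_leading + trim_trailing >= len) {
    stop("frame error: trims remove the whole sequence")
  }
  trimmed <- substr(seqs, trim_leading + 1L, len - trim_trailing)
  codon_alignment(trimmed, allele_ids = ids,
                  frame_offset = c(as.integer(trim_leading), as.integer(trim_trailing)))
}

#' Write a codon alignment as FASTA
#' @param aln a \code{codon_alignment}.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::DNAStringSet(aln$sequences)
  names(ss) <- aln$allele_ids
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Genotype table: individual -> unordered diploid allele pair
#'
#' @param individual_id character vector of individual labels.
#' @param allele1,allele2 allele IDs (unordered; homozygotes repeat the ID).
#' @param degenerate optional named character vector of IUPAC consensus
#'   sequences, one per individual.
#' @return a \code{data.frame} of class \code{genotype_table}.
#' @export
genotype_table <- function(individual_id, allele1, allele2, degenerate = NULL) {
  if (anyDuplicated(individual_id)) stop("genotype error: duplicate individual ids")
  df <- data.frame(individual_id = as.character(individual_id),
                   allele1 = as.character(allele1),
                   allele2 = as.character(allele2),
                   stringsAsFactors = FALSE)
  if (!is.null(degenerate)) attr(df, "degenerate") <- degenerate
  class(df) <- c("genotype_table", class(df))
  df
}

#' Read a two-column genotype TSV
#'
#' Dialect: tab-separated with header \code{individual<TAB>genotype}, the
#' genotype written \code{"a/b"} (homozygotes \code{"a/a"}).
#' @param path TSV file.
#' @return a \code{genotype_table}.
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("genotype error: expected 2 columns (individual, genotype)")
  parts <- strsplit(df[[2]], "/", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("genotype error: genotype not of the form 'a/b' for individual ",
         df[[1]][which(lengths(parts) != 2L)[1]])
  }
  genotype_table(df[[1]], vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

#' Write a genotype table as two-column TSV
#' @param gt a \code{genotype_table}.
#' @param path output file.
#' @export
write_genotypes <- function(gt, path) {
  out <- data.frame(individual = gt$individual_id,
                    genotype = paste0(gt$allele1, "/", gt$allele2))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse a genotype panel into an allele set with frequencies
#'
#' Each individual contributes two chromosomes; homozygotes count their
#' allele twice.  Frequencies are counts over \code{2 * n_individuals}.
#'
#' @param genotypes a \code{genotype_table}.
#' @param alignment optional \code{codon_alignment} supplying sequences; every
#'   genotype allele must be present in it.
#' @return an \code{allele_set}: data.frame with \code{allele_id},
#'   \code{sequence} (NA if no alignment given), \code{count},
#'   \code{frequency}.
#' @export
collapse_alleles <- function(genotypes, alignment = NULL) {
  alleles <- c(genotypes$allele1, genotypes$allele2)
  if (!is.null(alignment)) {
    missing <- setdiff(unique(alleles), alignment$allele_ids)
    if (length(missing) > 0L) {
      stop("reference error: genotype alleles absent from alignment: ",
           paste(missing, collapse = ", "))
    }
  }
  tab <- table(alleles)
  ids <- names(tab)
  seqs <- if (is.null(alignment)) rep(NA_character_, length(ids)) else
    unname(alignment$sequences[ids])
  out <- data.frame(allele_id = ids,
                    sequence = seqs,
                    count = as.integer(tab),
                    frequency = as.numeric(tab) / (2L * nrow(genotypes)),
                    stringsAsFactors = FALSE)
  stopifnot(abs(sum(out$frequency) - 1) < 1e-9)
  class(out) <- c("allele_set", class(out))
  out
}

#' Read nuclear-family pedigree blocks from a four-column-per-family TSV
#'
#' Layout mirrors the printed inheritance table: a header row
#' \code{individual<TAB><fam>.1 <fam>.2 <fam>.3 <fam>.4 ...} (four columns per
#' family), a \code{Father} row filling columns 1-2 of each family, a
#' \code{Mother} row filling columns 3-4, and one row per juvenile holding
#' exactly two non-empty allele cells per family in which it occurs.
#'
#' @param path TSV file.
#' @return list of \code{family_record}s, each a list with \code{family_id},
#'   \code{father} and \code{mother} (unordered allele pairs) and
#'   \code{offspring} (list of pairs).
#' @export
read_families <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  cols <- names(raw)[-1]
  fams <- unique(sub("\\.[1-4]$", "", cols))
  is_blank <- function(x) is.na(x) | trimws(x) == ""
  father_row <- which(tolower(raw[[1]]) == "father")
  mother_row <- which(tolower(raw[[1]]) == "mother")
  if (length(father_row) != 1L || length(mother_row) != 1L) {
    stop("format error: need exactly one Father and one Mother row")
  }
  off_rows <- setdiff(seq_len(nrow(raw)), c(father_row, mother_row))
  out <- lapply(fams, function(f) {
    fc <- paste0(f, ".", 1:4)
    if (!all(fc %in% names(raw))) {
      stop("format error: family ", f, " lacks four columns")
    }
    block <- as.matrix(raw[, fc, drop = FALSE])
    father <- block[father_row, 1:2]
    mother <- block[mother_row, 3:4]
    if (any(is_blank(father)) || any(is_blank(mother))) {
      stop("format error: incomplete parental genotype in family ", f)
    }
    offspring <- list()
    for (r in off_rows) {
      cells <- block[r, ]
      filled <- cells[!is_blank(cells)]
      if (length(filled) == 0L) next
      if (length(filled) != 2L) {
        stop("format error: offspring row '", raw[[1]][r], "' in family ", f,
             " has ", length(filled), " allele cells (expected 2)")
      }
      offspring[[length(offspring) + 1L]] <- unname(filled)
    }
    if (length(offspring) == 0L) {
      stop("format error: family ", f, " has no offspring rows")
    }
    structure(list(family_id = f,
                   father = unname(father),
                   mother = unname(mother),
                   offspring = offspring),
              class = "family_record")
  })
  out
}

#' Write family records back to the four-column-per-family TSV dialect
#' @param families list of \code{family_record}s.
#' @param path output file.
#' @export
write_families <- function(families, path) {
  nmax <- max(vapply(families, function(f) length(f$offspring), 0L))
  header <- unlist(lapply(families, function(f) paste0(f$family_id, ".", 1:4)))
  rows <- list()
  rows[["Father"]] <- unlist(lapply(families, function(f) c(f$father, "", "")))
  rows[["Mother"]] <- unlist(lapply(families, function(f) c("", "", f$mother)))
  for (i in seq_len(nmax)) {
    rows[[paste("Juvenile", i)]] <- unlist(lapply(families, function(f) {
      if (i > length(f$offspring)) return(c("", "", "", ""))
      pair <- f$offspring[[i]]
      # place paternal-compatible allele in columns 1-2, the other in 3-4;
      # fall back to (1,3) when assignment is ambiguous or impossible
      if (pair[1] %in% f$father && pair[2] %in% f$mother) {
        c(pair[1], "", pair[2], "")
      } else if (pair[2] %in% f$father && pair[1] %in% f$mother) {
        c(pair[2], "", pair[1], "")
      } else c(pair[1], "", pair[2], "")
    }))
  }
  m <- do.call(rbind, rows)
  df <- data.frame(individual = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("individual", header)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Translate an in-frame alignment to amino acids
#'
#' @param aln a \code{codon_alignment}.
#' @param check_stop error on internal stop codons (default TRUE).
#' @return named character vector of protein sequences.
#' @export
translate_alignment <- function(aln, check_stop = TRUE) {
  ct <- codon_table()
  cm <- codon_matrix(aln)
  aa <- matrix(ct[cm], nrow(cm), ncol(cm), dimnames = dimnames(cm))
  if (check_stop && any(aa == "*")) {
    idx <- which(aa == "*", arr.ind = TRUE)[1, ]
    stop("translation error: internal stop codon in allele '",
         rownames(aa)[idx[1]], "' at codon ", idx[2])
  }
  setNames(apply(aa, 1L, paste0, collapse = ""), rownames(aa))
}
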
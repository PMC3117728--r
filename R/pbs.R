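# Peptide-binding-site (PBS) catalogs and homology mapping.
#
# Teleost class II beta1 PBS cannot be read off a crystal structure; they are
# inferred by homology to the human DR molecule.  Two catalogs of human
# beta-chain contact residues are shipped: the classic crystallographic set
# (Brown et al. 1993) and the updated, larger-peptide-sample set (Reche &
# Reinherz 2003), the latter being the recommended default.  Position lists
# are transcribed reconstructions in mature-beta-chain numbering; see the
# methods vignette for provenance caveats.

# Human DRB1*01:01 mature beta1-domain reference (first 90 residues used for
# numbering).  Documented best-effort constant.
.HUMAN_DRB1_B1 <- paste0(
  "GDTRPRFLWQLKFECHFFNGTERVRLLERCIYNQEESVRFDSDVGEYRAV",
  "TELGRPDAEYWNSQKDLLEQRRAAVDTYCRHNYGVGESFT")

.PBS_CATALOGS <- list(
  brown = c(9, 11, 13, 26, 28, 30, 32, 37, 38, 47, 56, 57, 60, 61, 65, 68,
            70, 71, 74, 78, 81, 82, 85, 86),
  reche = c(9, 11, 13, 26, 28, 30, 32, 37, 38, 47, 56, 57, 60, 61, 64, 65,
            67, 68, 70, 71, 74, 78, 81, 85))

#' Shipped human beta1-domain PBS catalogs
#'
#' @param catalog \code{"brown"} or \code{"reche"} (default: reche, the
#'   recommended, more comprehensive model).
#' @return integer vector of human mature-beta-chain residue positions.
#' @export
pbs_catalog <- function(catalog = c("reche", "brown")) {
  catalog <- match.arg(catalog)
  .PBS_CATALOGS[[catalog]]
}

#' Human beta1-domain reference sequence used for PBS numbering
#' @return single amino-acid string (mature DRB numbering starts at 1).
#' @export
human_b1_reference <- function() .HUMAN_DRB1_B1

#' Reference lengths of the two deposited full-gene sequences
#'
#' Metadata only: total gene lengths (bp) of the two full MHIIbeta gDNA
#' haplotypes deposited alongside the exon-2 alleles; intron length
#' variation accounts for the difference.
#' @return named integer vector.
#' @export
full_gene_lengths <- function() {
  c(HQ902181 = 3508L, HQ902182 = 3523L)
}

#' Disjoint PBS / non-PBS codon partition
#'
#' @param pbs_codons sorted 1-based codon indices.
#' @param codon_count total codons in the frame.
#' @param source_catalog label recording the catalog used.
#' @return object of class \code{site_partition} with \code{pbs_codons},
#'   \code{non_pbs_codons}, \code{source_catalog}.
#' @export
site_partition <- function(pbs_codons, codon_count, source_catalog = "custom") {
  pbs_codons <- sort(unique(as.integer(pbs_codons)))
  if (length(pbs_codons) > 0 && (min(pbs_codons) < 1L || max(pbs_codons) > codon_count)) {
    stop("domain error: PBS codon outside 1..", codon_count)
  }
  structure(list(pbs_codons = pbs_codons,
                 non_pbs_codons = setdiff(seq_len(codon_count), pbs_codons),
                 codon_count = as.integer(codon_count),
                 source_catalog = source_catalog),
            class = "site_partition")
}

#' @export
print.site_partition <- function(x, ...) {
  cat(sprintf("site_partition [%s]: %d PBS codons (%d bp) / %d non-PBS of %d\n",
              x$source_catalog, length(x$pbs_codons), 3 * length(x$pbs_codons),
              length(x$non_pbs_codons), x$codon_count))
  invisible(x)
}

#' Write / read a site partition as a plain-text codon index list
#'
#' One 1-based PBS codon index per line; a header comment records the frame
#' size and catalog.
#' @param partition a \code{site_partition}.
#' @param path text file.
#' @export
write_partition <- function(partition, path) {
  writeLines(c(sprintf("# codon_count=%d catalog=%s", partition$codon_count,
                       partition$source_catalog),
               as.character(partition$pbs_codons)), path)
  invisible(path)
}

#' @rdname write_partition
#' @param codon_count frame size; required if the file lacks the header.
#' @export
read_partition <- function(path, codon_count = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  catalog <- "custom"
  if (length(hdr) > 0) {
    m <- regmatches(hdr[1], regexec("codon_count=(\\d+) catalog=(\\S+)", hdr[1]))[[1]]
    if (length(m) == 3) {
      if (is.null(codon_count)) codon_count <- as.integer(m[2])
      catalog <- m[3]
    }
  }
  if (is.null(codon_count)) stop("domain error: codon_count unknown (no header)")
  idx <- as.integer(lines[!grepl("^#", lines) & nzchar(lines)])
  site_partition(idx, codon_count, catalog)
}

#' Map human PBS positions onto a query beta1 frame by pairwise alignment
#'
#' Globally aligns the query protein (first sequence of the translated codon
#' alignment unless given explicitly) to the human beta1 reference and
#' transfers the cataloged human contact positions to query codon indices.
#' Cataloged positions falling in gaps or beyond the alignment are dropped
#' with a warning.
#'
#' @param alignment a \code{codon_alignment} (translated internally), or a
#'   single protein string.
#' @param catalog \code{"reche"} (default) or \code{"brown"}, or an integer
#'   vector of custom human positions.
#' @param human_ref reference protein string (default shipped DRB beta1).
#' @return a \code{site_partition} over the query codon frame.
#' @export
map_pbs_sites <- function(alignment, catalog = "reche",
                          human_ref = human_b1_reference()) {
  if (inherits(alignment, "codon_alignment")) {
    query <- translate_alignment(alignment)[1]
    codon_count <- alignment$codon_count
  } else {
    query <- as.character(alignment)[1]
    codon_count <- nchar(query)
  }
  if (is.character(catalog) && length(catalog) == 1L) {
    positions <- pbs_catalog(catalog)
    label <- catalog
  } else {
    positions <- as.integer(catalog)
    label <- "custom"
  }
  if (length(positions) == 0L) {
    return(site_partition(integer(0), codon_count, label))
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = human_ref, type = "global",
    substitutionMatrix = get("BLOSUM62"), gapOpening = 10, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ha <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qpos <- hpos <- 0L
  human_to_query <- rep(NA_integer_, nchar(human_ref))
  for (k in seq_along(qa)) {
    if (qa[k] != "-") qpos <- qpos + 1L
    if (ha[k] != "-") {
      hpos <- hpos + 1L
      if (qa[k] != "-") human_to_query[hpos] <- qpos
    }
  }
  mapped <- human_to_query[positions]
  dropped <- positions[is.na(mapped)]
  if (length(dropped) > 0L) {
    warning("catalog positions not covered by the alignment, dropped: ",
            paste(dropped, collapse = ", "))
  }
  site_partition(mapped[!is.na(mapped)], codon_count, label)
}
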
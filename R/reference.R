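#' Simulate a reference genome with germline SNPs and assembly gaps
#'
#' Builds a small multi-contig reference with a controlled GC fraction,
#' heterozygous and homozygous germline SNP sites at a given per-base density,
#' and optional assembly-gap intervals (used by the read-depth gap-exclusion
#' filter). Deterministic for a fixed seed.
#'
#' @param seed integer RNG seed.
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bp (recycled).
#' @param gc_fraction target G+C fraction in (0, 1).
#' @param snp_density per-base probability of a germline SNP site (split
#'   evenly between heterozygous and homozygous sites); must be <= 0.1.
#' @param gap_spec optional data.frame with columns contig, start, end
#'   (1-based inclusive) marking assembly gaps; SNPs are never placed inside.
#' @return an object of class \code{ReferenceGenome}: a list with
#'   \code{contigs} (named character vector of sequences), \code{gaps},
#'   \code{het_snps} and \code{hom_snps} (data.frames with columns
#'   contig, pos, ref, alt).
#' @examples
#' ref <- build_reference(seed = 1, n_contigs = 2, contig_length = 20000)
#' nchar(ref$contigs[[1]])
#' @export
build_reference <- function(seed, n_contigs = 2L, contig_length = 100000L,
                            gc_fraction = 0.41, snp_density = 0.001,
                            gap_spec = NULL) {
  if (any(contig_length <= 0)) stop("contig_length must be positive")
  if (snp_density < 0 || snp_density > 0.1) stop("snp_density must be in [0, 0.1]")
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0, 1)")
  set.seed(seed)
  lens <- rep_len(as.integer(contig_length), n_contigs)
  names(lens) <- paste0("contig", seq_len(n_contigs))
  w <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  contigs <- vapply(lens, function(L) {
    paste0(sample(BASES, L, replace = TRUE, prob = w[BASES]), collapse = "")
  }, "")

  gaps <- if (is.null(gap_spec)) {
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("contig", "start", "end") %in% names(gap_spec)))
    if (any(gap_spec$end < gap_spec$start)) stop("gap intervals must have end >= start")
    gap_spec[, c("contig", "start", "end")]
  }

  het <- hom <- data.frame(contig = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           stringsAsFactors = FALSE)
  if (snp_density > 0) {
    for (cn in names(contigs)) {
      L <- lens[[cn]]
      n_sites <- rbinom(1L, L, snp_density)
      if (n_sites == 0L) next
      pos <- sort(sample.int(L, n_sites))
      g <- gaps[gaps$contig == cn, , drop = FALSE]
      if (nrow(g)) {
        in_gap <- vapply(pos, function(p) any(p >= g$start & p <= g$end), TRUE)
        pos <- pos[!in_gap]
      }
      if (!length(pos)) next
      refb <- str_at(contigs[[cn]], pos)
      altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L), "")
      is_het <- runif(length(pos)) < 0.5
      het <- rbind(het, data.frame(contig = cn, pos = pos[is_het],
                                   ref = refb[is_het], alt = altb[is_het],
                                   stringsAsFactors = FALSE))
      hom <- rbind(hom, data.frame(contig = cn, pos = pos[!is_het],
                                   ref = refb[!is_het], alt = altb[!is_het],
                                   stringsAsFactors = FALSE))
    }
  }
  structure(list(contigs = contigs, gaps = gaps,
                 het_snps = het, hom_snps = hom),
            class = "ReferenceGenome")
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome:", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp;",
      nrow(x$het_snps), "het /", nrow(x$hom_snps), "hom SNP sites;",
      nrow(x$gaps), "gap interval(s)\n")
  invisible(x)
}

#' Write a reference genome to FASTA
#'
#' @param ref a \code{ReferenceGenome}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  dss <- Biostrings::DNAStringSet(ref$contigs)
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}

#' Read contigs from a FASTA file into a bare ReferenceGenome
#'
#' SNP and gap annotations are not stored in FASTA and come back empty.
#' @param path FASTA path.
#' @return a \code{ReferenceGenome} with empty annotation tables.
#' @export
read_reference_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  contigs <- as.character(dss)
  names(contigs) <- sub("\\s.*$", "", names(dss))
  structure(list(contigs = contigs,
                 gaps = data.frame(contig = character(0), start = integer(0),
                                   end = integer(0), stringsAsFactors = FALSE),
                 het_snps = data.frame(contig = character(0), pos = integer(0),
                                       ref = character(0), alt = character(0),
                                       stringsAsFactors = FALSE),
                 hom_snps = data.frame(contig = character(0), pos = integer(0),
                                       ref = character(0), alt = character(0),
                                       stringsAsFactors = FALSE)),
            class = "ReferenceGenome")
}

genome_length <- function(ref) sum(nchar(ref$contigs))
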
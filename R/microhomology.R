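#' Measure junction microhomology
#'
#' Microhomology at a rearrangement junction is a short identical sequence
#' shared by the two sides of the junction, a signature of replication-based
#' (template-switch) mechanisms. Junctions are left-aligned, and since either
#' homology convention may apply, the reported length is the maximum of the
#' two: the left-side homology (the m bases ending at the donor breakpoint
#' equal the m bases ending at the acceptor breakpoint, i.e. the acceptor
#' alignment could extend m bases back) and the right-side homology (the m
#' bases after the donor breakpoint equal the acceptor's first m bases, i.e.
#' the donor alignment could extend m bases forward).
#'
#' @param ref a \code{ReferenceGenome}.
#' @param donor list(contig, pos, strand): oriented reference position of the
#'   last base emitted before the junction.
#' @param acceptor list(contig, pos, strand): oriented reference position of
#'   the first base emitted after the junction.
#' @param max_mh search limit in bases; truncated flanks reduce it.
#' @return integer microhomology length.
#' @examples
#' ref <- build_reference(seed = 3, n_contigs = 1, contig_length = 5000,
#'                        snp_density = 0)
#' detect_microhomology(ref, donor = list(contig = "contig1", pos = 1000,
#'                      strand = "+"),
#'                      acceptor = list(contig = "contig1", pos = 3000,
#'                      strand = "+"))
#' @export
detect_microhomology <- function(ref, donor, acceptor, max_mh = 20L) {
  don_len <- nchar(ref$contigs[[donor$contig]])
  acc_len <- nchar(ref$contigs[[acceptor$contig]])

  ## left-side homology: donor bases at distances 0..m-1 back from its end
  ## vs acceptor upstream flank at distances 1..m
  m_left <- 0L
  for (i in seq_len(max_mh)) {
    dp <- if (donor$strand == "+") donor$pos - i + 1L else donor$pos + i - 1L
    ap <- if (acceptor$strand == "+") acceptor$pos - i else acceptor$pos + i
    if (dp < 1L || dp > don_len || ap < 1L || ap > acc_len) break
    db <- oriented_base(ref, donor$contig, dp, donor$strand)
    ab <- oriented_base(ref, acceptor$contig, ap, acceptor$strand)
    if (db != ab) break
    m_left <- i
  }
  ## right-side homology: donor downstream flank vs acceptor's first bases
  m_right <- 0L
  for (i in seq_len(max_mh)) {
    dp <- if (donor$strand == "+") donor$pos + i else donor$pos - i
    ap <- if (acceptor$strand == "+") acceptor$pos + i - 1L else acceptor$pos - i + 1L
    if (dp < 1L || dp > don_len || ap < 1L || ap > acc_len) break
    db <- oriented_base(ref, donor$contig, dp, donor$strand)
    ab <- oriented_base(ref, acceptor$contig, ap, acceptor$strand)
    if (db != ab) break
    m_right <- i
  }
  max(m_left, m_right)
}
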
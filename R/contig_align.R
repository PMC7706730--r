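# Contig-to-reference alignment: exact k-mer seeding on both strands,
# same-diagonal run merging, exact-match extension. The simulator's error
# model is substitution-only, so ungapped alignment with a small per-run
# mismatch budget (from merged seed gaps) is exact for data in scope.

#' Prepare a reference for k-mer seeding
#'
#' @param ref a \code{ReferenceGenome}.
#' @param k seed k-mer length.
#' @return a seeding handle (reference \code{DNAStringSet} plus k).
#' @export
kmer_index <- function(ref, k = 15L) {
  structure(list(dss = Biostrings::DNAStringSet(ref$contigs), k = k),
            class = "clonesv_seed_index")
}

## seed hits of query against the reference: data.frame(qpos, contig, rpos);
## exact k-mer matches found with matchPDict (C speed)
seed_hits <- function(query, index) {
  k <- index$k
  L <- nchar(query)
  if (L < k) return(data.frame(qpos = integer(0), contig = character(0),
                               rpos = integer(0), stringsAsFactors = FALSE))
  starts <- seq_len(L - k + 1L)
  kmers <- Biostrings::DNAStringSet(substring(query, starts, starts + k - 1L))
  pd <- Biostrings::PDict(kmers)
  out <- list()
  for (ci in seq_along(index$dss)) {
    m <- Biostrings::matchPDict(pd, index$dss[[ci]])
    cnt <- S4Vectors::elementNROWS(m)
    if (sum(cnt) == 0L) next
    rpos <- IRanges::start(unlist(m))
    out[[length(out) + 1L]] <- data.frame(
      qpos = rep(starts, cnt), contig = names(index$dss)[ci], rpos = rpos,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(qpos = integer(0), contig = character(0),
                                      rpos = integer(0),
                                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## exact-match extension of an ungapped alignment in one strand-space
extend_exact <- function(qseq, rseq, qs, qe, rs, re) {
  while (qs > 1L && rs > 1L &&
         substr(qseq, qs - 1L, qs - 1L) == substr(rseq, rs - 1L, rs - 1L)) {
    qs <- qs - 1L; rs <- rs - 1L
  }
  lq <- nchar(qseq); lr <- nchar(rseq)
  while (qe < lq && re < lr &&
         substr(qseq, qe + 1L, qe + 1L) == substr(rseq, re + 1L, re + 1L)) {
    qe <- qe + 1L; re <- re + 1L
  }
  c(qs, qe, rs, re)
}

#' Align a contig to the reference as local oriented segments
#'
#' Seeds exact k-mers on both strands, merges same-diagonal seed runs (gaps
#' up to ~2 mismatches), extends each run by exact matching, and reports all
#' local ungapped alignments passing the identity and length floors.
#'
#' @param contig_seq contig sequence.
#' @param ref a \code{ReferenceGenome}.
#' @param config a \code{\link{pipeline_config}} (seed_k, min_identity,
#'   min_align_len).
#' @param index optional prebuilt \code{\link{kmer_index}} (rebuilt per call
#'   otherwise).
#' @return SegmentAlignment data.frame: cstart, cend (contig, 1-based),
#'   contig (reference contig), rstart, rend, strand, identity, score.
#' @export
align_contig <- function(contig_seq, ref, config = pipeline_config(),
                         index = NULL) {
  k <- config$seed_k
  if (nchar(contig_seq) < k) return(empty_alignments())
  if (is.null(index)) index <- kmer_index(ref, k)
  clen <- nchar(contig_seq)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") contig_seq else rc(contig_seq)
    hits <- seed_hits(q, index)
    if (!nrow(hits)) next
    hits$diag <- hits$rpos - hits$qpos
    key <- paste(hits$contig, hits$diag)
    for (grp in split(hits, key)) {
      grp <- grp[order(grp$qpos), , drop = FALSE]
      run_id <- c(0L, cumsum(diff(grp$qpos) > 2L * (k + 2L)))
      for (run in split(grp, run_id)) {
        qs <- run$qpos[1]; qe <- run$qpos[nrow(run)] + k - 1L
        rs <- run$rpos[1]; re <- run$rpos[nrow(run)] + k - 1L
        rseq <- ref$contigs[[run$contig[1]]]
        ext <- extend_exact(q, rseq, qs, qe, rs, re)
        len <- ext[2] - ext[1] + 1L
        if (len < config$min_align_len) next
        idy <- str_identity(substr(q, ext[1], ext[2]),
                            substr(rseq, ext[3], ext[4]))
        if (idy < config$min_identity) next
        if (strand == "+") {
          cs <- ext[1]; ce <- ext[2]
        } else {
          cs <- clen - ext[2] + 1L; ce <- clen - ext[1] + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          cstart = cs, cend = ce, contig = run$contig[1],
          rstart = ext[3], rend = ext[4], strand = strand,
          identity = idy, score = len * idy, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_alignments())
  res <- unique(do.call(rbind, out))
  res <- res[order(res$cstart, res$cend, -res$score), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## project a contig position through an ungapped alignment row to its
## (oriented) reference coordinate
aln_project <- function(aln, cpos) {
  if (aln$strand == "+") aln$rstart + (cpos - aln$cstart)
  else aln$rend - (cpos - aln$cstart)
}

## reference base (in alignment orientation) projected at a contig position,
## or NA outside the reference
aln_ref_base <- function(aln, ref, cpos) {
  rp <- aln_project(aln, cpos)
  L <- nchar(ref$contigs[[aln$contig]])
  if (rp < 1L || rp > L) return(NA_character_)
  b <- substr(ref$contigs[[aln$contig]], rp, rp)
  if (aln$strand == "-") chartr("ACGT", "TGCA", b) else b
}

## choose the junction split point between two adjacent alignments: the cut
## minimizing mismatches of the contig against the donor projection (left of
## the cut) plus the acceptor projection (right of it); leftmost on ties.
refine_junction_cut <- function(contig_seq, ref, don, acc, slack = 4L,
                                win = 30L) {
  lo <- min(don$cend, acc$cstart - 1L) - slack
  hi <- max(don$cend, acc$cstart - 1L) + slack
  lo <- max(lo, don$cstart)
  hi <- min(hi, acc$cend - 1L)
  if (lo > hi) return(NULL)
  wl <- max(don$cstart, lo - win)
  wr <- min(acc$cend, hi + win)
  cpos <- wl:wr
  obs <- strsplit(substr(contig_seq, wl, wr), "")[[1]]
  don_b <- vapply(cpos, function(p) aln_ref_base(don, ref, p), "")
  acc_b <- vapply(cpos, function(p) aln_ref_base(acc, ref, p), "")
  don_mm <- cumsum(is.na(don_b) | obs != don_b)
  acc_mm_rev <- rev(cumsum(rev(is.na(acc_b) | obs != acc_b)))
  score <- function(cut) {
    i <- cut - wl + 1L
    left <- if (i >= 1L) don_mm[i] else 0L
    right <- if (i + 1L <= length(cpos)) acc_mm_rev[i + 1L] else 0L
    left + right
  }
  cuts <- lo:hi
  sc <- vapply(cuts, score, 0L)
  tied <- cuts[sc == min(sc)]
  if (length(tied) == 1L) return(tied)
  ## canonical placement among equal-mismatch cuts: the one whose implied
  ## junction carries the most microhomology, leftmost thereafter
  mh <- vapply(tied, function(cut) {
    detect_microhomology(ref,
      donor = list(contig = don$contig, pos = aln_project(don, cut),
                   strand = don$strand),
      acceptor = list(contig = acc$contig, pos = aln_project(acc, cut + 1L),
                      strand = acc$strand))
  }, 0L)
  tied[which.max(mh)]
}

empty_alignments <- function() {
  data.frame(cstart = integer(0), cend = integer(0), contig = character(0),
             rstart = integer(0), rend = integer(0), strand = character(0),
             identity = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Select the segment chain tiling a contig
#'
#' Weighted interval scheduling over contig intervals (weight = aligned
#' length x identity): the maximum-weight ordered subset of alignments that
#' do not overlap on the contig by more than the microhomology allowance.
#' Adjacent chain overlaps (junction microhomology) are split at the
#' midpoint for the tiling; raw alignment ends are kept for exact junction
#' coordinates.
#'
#' @param alignments data.frame from \code{\link{align_contig}}.
#' @param contig_length contig length in bp.
#' @param config a \code{\link{pipeline_config}} (max_mh = permitted
#'   overlap; chain_min_cover = coverage floor).
#' @param contig_seq optional contig sequence; with \code{ref} also given,
#'   each junction is refined to the minimum-mismatch split point between
#'   the two alignment diagonals (leftmost on ties, i.e. left-aligned
#'   junctions), which keeps junction coordinates exact even when an
#'   isolated variant or consensus error sits next to the junction.
#' @param ref optional \code{ReferenceGenome} for junction refinement.
#' @return list with \code{chain} (selected alignments, in contig order,
#'   with tile_start/tile_end midpoint-split columns), \code{junctions}
#'   (donor/acceptor oriented reference coordinates per adjacency, with the
#'   contig-overlap length), \code{coverage} (fraction of the contig
#'   covered) and \code{low_confidence}.
#' @export
chain_segments <- function(alignments, contig_length,
                           config = pipeline_config(), contig_seq = NULL,
                           ref = NULL) {
  if (!nrow(alignments)) stop("no alignments to chain")
  a <- alignments[order(alignments$cend, alignments$cstart), , drop = FALSE]
  n <- nrow(a)
  allowed <- config$max_mh
  dp <- a$score; prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      compatible <- a$cend[j] <= a$cstart[i] - 1L + allowed &&
        a$cstart[j] < a$cstart[i] && a$cend[j] < a$cend[i]
      if (compatible && dp[j] + a$score[i] > dp[i]) {
        dp[i] <- dp[j] + a$score[i]
        prev[i] <- j
      }
    }
  }
  best <- which.max(dp)
  sel <- integer(0); cur <- best
  while (cur != 0L) { sel <- c(cur, sel); cur <- prev[cur] }
  chain <- a[sel, , drop = FALSE]
  rownames(chain) <- NULL
  m <- nrow(chain)
  ## midpoint split of contig overlaps; exact junction reference coordinates
  chain$tile_start <- chain$cstart
  chain$tile_end <- chain$cend
  juncs <- NULL
  if (m >= 2L) {
    juncs <- data.frame(donor_contig = character(m - 1L),
                        donor_pos = integer(m - 1L),
                        donor_strand = character(m - 1L),
                        acc_contig = character(m - 1L),
                        acc_pos = integer(m - 1L),
                        acc_strand = character(m - 1L),
                        overlap = integer(m - 1L), stringsAsFactors = FALSE)
    refine <- !is.null(contig_seq) && !is.null(ref)
    for (i in seq_len(m - 1L)) {
      ov <- max(0L, chain$cend[i] - chain$cstart[i + 1L] + 1L)
      don_plus <- chain$strand[i] == "+"
      acc_plus <- chain$strand[i + 1L] == "+"
      juncs$donor_contig[i] <- chain$contig[i]
      juncs$donor_strand[i] <- chain$strand[i]
      juncs$acc_contig[i] <- chain$contig[i + 1L]
      juncs$acc_strand[i] <- chain$strand[i + 1L]
      juncs$overlap[i] <- ov
      cutpos <- NULL
      if (refine)
        cutpos <- refine_junction_cut(contig_seq, ref, chain[i, ],
                                      chain[i + 1L, ])
      if (!is.null(cutpos)) {
        chain$tile_end[i] <- cutpos
        chain$tile_start[i + 1L] <- cutpos + 1L
        juncs$donor_pos[i] <- aln_project(chain[i, ], cutpos)
        juncs$acc_pos[i] <- aln_project(chain[i + 1L, ], cutpos + 1L)
      } else {
        cut <- ov %/% 2L
        chain$tile_end[i] <- chain$cend[i] - cut
        chain$tile_start[i + 1L] <- chain$cend[i] - cut + 1L
        juncs$donor_pos[i] <- if (don_plus) chain$rend[i] else chain$rstart[i]
        ## the acceptor alignment extends `ov` bases back through the
        ## microhomology; its true start is ov bases downstream
        juncs$acc_pos[i] <- if (acc_plus) chain$rstart[i + 1L] + ov
                            else chain$rend[i + 1L] - ov
      }
    }
  } else {
    juncs <- data.frame(donor_contig = character(0), donor_pos = integer(0),
                        donor_strand = character(0), acc_contig = character(0),
                        acc_pos = integer(0), acc_strand = character(0),
                        overlap = integer(0), stringsAsFactors = FALSE)
  }
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(chain$cstart, chain$cend)))) / contig_length
  list(chain = chain, junctions = juncs, coverage = covered,
       low_confidence = covered < config$chain_min_cover)
}
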
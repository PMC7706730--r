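# Greedy overlap-layout-consensus assembly of abnormal reads.
#
# Read counts per locus are small (tens), so greedy OLC is simpler than a
# de Bruijn graph and fully deterministic: repeatedly merge the pair with
# the longest suffix/prefix overlap, ties broken by the lexicographically
# smallest merged sequence; the consensus is a per-column majority vote
# over the layout.

## longest suffix(a)/prefix(b) overlap >= min_overlap with <= max_mismatch
## mismatches. Anchored on the terminal 12-mer of a for speed.
best_overlap <- function(a, b, min_overlap, max_mismatch, anchor_k = 12L) {
  anchor_k <- min(anchor_k, min_overlap)
  la <- nchar(a); lb <- nchar(b)
  if (la < anchor_k || lb < min_overlap) return(0L)
  anchor <- substring(a, la - anchor_k + 1L)
  hits <- gregexpr(anchor, b, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(0L)
  best <- 0L
  for (p in rev(hits)) {   # largest overlap first
    o <- p + anchor_k - 1L
    if (o > min(la, lb) || o < min_overlap || o <= best) next
    mm <- str_mismatches(substring(a, la - o + 1L), substr(b, 1L, o))
    if (mm <= max_mismatch) { best <- o; break }
  }
  best
}

#' Assemble abnormal reads into contigs
#'
#' @param seqs character vector of read sequences (reference orientation, as
#'   stored in the alignment records).
#' @param min_overlap minimum suffix/prefix overlap to merge.
#' @param max_mismatch mismatches tolerated inside an overlap.
#' @param max_reads deterministic cap on the number of reads assembled
#'   (evenly subsampled after sorting when exceeded).
#' @return list of contigs, each a list with \code{sequence}, \code{n_reads},
#'   and \code{depth} (per-base read support). Reads without any overlap
#'   remain singleton contigs.
#' @export
assemble_contigs <- function(seqs, min_overlap = 20L, max_mismatch = 2L,
                             max_reads = 100L) {
  seqs <- unique(seqs[nchar(seqs) >= min_overlap])
  seqs <- sort(seqs)                 # deterministic layout order
  if (length(seqs) > max_reads)
    seqs <- seqs[round(seq(1L, length(seqs), length.out = max_reads))]
  n <- length(seqs)
  if (n == 0L) return(list())
  ## each node: sequence + layout of member reads (read, offset)
  nodes <- lapply(seqs, function(s)
    list(sequence = s, members = data.frame(seq = s, offset = 0L,
                                            stringsAsFactors = FALSE)))
  alive <- rep(TRUE, n)
  ov <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    ov[i, j] <- best_overlap(nodes[[i]]$sequence, nodes[[j]]$sequence,
                             min_overlap, max_mismatch)
  repeat {
    mx <- max(ov)
    if (mx < min_overlap) break
    hits <- which(ov == mx, arr.ind = TRUE)
    ## tie-break: lexicographically smallest merged sequence
    merged <- vapply(seq_len(nrow(hits)), function(h) {
      a <- nodes[[hits[h, 1]]]$sequence; b <- nodes[[hits[h, 2]]]$sequence
      paste0(a, substring(b, mx + 1L))
    }, "")
    pick <- which(merged == min(merged))[1]
    i <- hits[pick, 1]; j <- hits[pick, 2]
    shift <- nchar(nodes[[i]]$sequence) - mx
    mem_j <- nodes[[j]]$members
    mem_j$offset <- mem_j$offset + shift
    nodes[[i]]$sequence <- merged[pick]
    nodes[[i]]$members <- rbind(nodes[[i]]$members, mem_j)
    alive[j] <- FALSE
    ov[j, ] <- 0L; ov[, j] <- 0L
    for (k in which(alive)) {
      if (k == i) next
      ov[i, k] <- best_overlap(nodes[[i]]$sequence, nodes[[k]]$sequence,
                               min_overlap, max_mismatch)
      ov[k, i] <- best_overlap(nodes[[k]]$sequence, nodes[[i]]$sequence,
                               min_overlap, max_mismatch)
    }
  }
  out <- lapply(which(alive), function(i) contig_consensus(nodes[[i]]))
  out[order(-vapply(out, function(x) nchar(x$sequence), 0))]
}

## per-column majority consensus over a layout (ties -> alphabetical)
contig_consensus <- function(node) {
  len <- nchar(node$sequence)
  mem <- node$members
  counts <- matrix(0L, 4L, len, dimnames = list(BASES, NULL))
  for (i in seq_len(nrow(mem))) {
    r <- charToRaw(mem$seq[i])
    pos <- mem$offset[i] + seq_along(r)
    b <- match(rawToChar(r, multiple = TRUE), BASES)
    okb <- !is.na(b)
    idx <- cbind(b[okb], pos[okb])
    counts[idx] <- counts[idx] + 1L
  }
  cons <- BASES[apply(counts, 2L, which.max)]
  list(sequence = paste0(cons, collapse = ""),
       n_reads = nrow(mem),
       depth = as.integer(colSums(counts)))
}
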
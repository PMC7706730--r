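# Binned read-depth simulation and normalized copy-number profiles.

#' Simulate per-bin read-depth counts
#'
#' Poisson counts around the expected per-bin read count, scaled by the local
#' copy number implied by the truth records each sample carries: a deletion
#' carried at cell fraction f scales affected bins by (2 - f)/2 (0.5 for a
#' heterozygous clonal loss), a duplication by (2 + f)/2.
#'
#' @param ref a \code{ReferenceGenome}.
#' @param clones list of \code{CloneSpec}.
#' @param truths named list of \code{TruthRecord}.
#' @param bin_size bin width in bp (>= 50).
#' @param seed integer seed.
#' @return data.frame with columns sample, contig, bin_start, bin_end, count.
#' @export
simulate_read_depth <- function(ref, clones, truths = list(), bin_size = 200L,
                                seed = 1L) {
  if (bin_size < 50L) stop("bin_size must be >= 50")
  set.seed(seed)
  out <- list()
  for (cl in clones) {
    my <- truths[cl$harbored_svs$label]
    for (cn in names(ref$contigs)) {
      L <- nchar(ref$contigs[[cn]])
      starts <- seq(1L, L, by = bin_size)
      ends <- pmin(starts + bin_size - 1L, L)
      lambda0 <- cl$coverage * (ends - starts + 1L) / cl$read_length
      scale <- rep(1, length(starts))
      for (k in seq_along(my)) {
        tr <- my[[k]]
        f <- cl$harbored_svs$cell_fraction[match(tr$label, cl$harbored_svs$label)]
        ev <- tr$events
        ev <- ev[ev$type %in% c("DEL", "DUP") & ev$contig == cn, , drop = FALSE]
        for (i in seq_len(nrow(ev))) {
          hit <- starts <= ev$end[i] & ends >= ev$start[i]
          fac <- if (ev$type[i] == "DEL") (2 - f) / 2 else (2 + f) / 2
          scale[hit] <- scale[hit] * fac
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        sample = cl$clone_id, contig = cn, bin_start = starts, bin_end = ends,
        count = rpois(length(starts), lambda0 * scale),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalized copy-number profiles from binned counts
#'
#' Per-sample normalization: each bin's count is divided by the sample's
#' genome-wide mean over non-gap bins and multiplied by 2, the standard
#' normalized-copy-number convention (diploid background has mean 2.0).
#'
#' @param depth data.frame from \code{simulate_read_depth} (or equivalent).
#' @param gaps data.frame contig/start/end of assembly gaps (may be empty).
#' @return data.frame with columns sample, contig, bin_start, bin_end, cn,
#'   gap (logical mask of bins overlapping a gap interval).
#' @export
depth_profile <- function(depth, gaps = NULL) {
  depth$gap <- FALSE
  if (!is.null(gaps) && nrow(gaps)) {
    for (i in seq_len(nrow(gaps))) {
      hit <- depth$contig == gaps$contig[i] &
        depth$bin_start <= gaps$end[i] & depth$bin_end >= gaps$start[i]
      depth$gap[hit] <- TRUE
    }
  }
  out <- lapply(split(depth, depth$sample), function(d) {
    m <- mean(d$count[!d$gap])
    d$cn <- 2 * d$count / m
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
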
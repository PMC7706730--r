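# Breakpoint discovery from split and discordant reads.

#' Estimate the insert-size distribution from proper pairs
#'
#' @param records alignment record data.frame.
#' @param min_pairs minimum proper pairs required.
#' @return list(mean, sd, n).
#' @export
estimate_insert_stats <- function(records, min_pairs = 100L) {
  pp <- records[records$proper & records$mate == 1L & !is.na(records$isize), ]
  if (nrow(pp) < min_pairs)
    stop("too few proper pairs (", nrow(pp), ") to estimate the insert-size ",
         "distribution; supply insert_stats explicitly")
  list(mean = mean(abs(pp$isize)), sd = sd(abs(pp$isize)), n = nrow(pp))
}

#' Extract abnormal reads
#'
#' A record is abnormal iff more than \code{soft_clip_min} bases are
#' soft-clipped, or its insert size exceeds the proper-pair mean by more than
#' \code{discordance_sds} standard deviations, or its mate maps to a
#' different contig. With a locus, extraction is restricted to a
#' \code{window} on either end of the event.
#'
#' @param records alignment record data.frame.
#' @param config a \code{\link{pipeline_config}}.
#' @param locus optional list(contig, start, end) to restrict to.
#' @param insert_stats optional list(mean, sd); estimated from proper pairs
#'   when NULL.
#' @param include_mates also return the mates of abnormal reads (useful for
#'   assembly; mates are marked in column \code{rescued}).
#' @return subset of \code{records} (with logical column \code{rescued}).
#' @export
extract_abnormal_reads <- function(records, config = pipeline_config(),
                                   locus = NULL, insert_stats = NULL,
                                   include_mates = FALSE) {
  if (is.null(insert_stats)) insert_stats <- estimate_insert_stats(records)
  cut <- insert_stats$mean + config$discordance_sds * insert_stats$sd
  ab <- records$clip_left > config$soft_clip_min |
    records$clip_right > config$soft_clip_min |
    (!is.na(records$isize) & abs(records$isize) > cut) |
    records$mate_contig != records$contig
  keep <- ab
  if (include_mates) keep <- keep | records$read_id %in% records$read_id[ab]
  out <- records[keep, , drop = FALSE]
  out$rescued <- !ab[keep]
  if (!is.null(locus)) {
    w <- config$window
    hit <- out$contig == locus$contig &
      out$pos <= locus$end + w & (out$pos + out$mlen - 1L) >= locus$start - w
    out <- out[hit, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Cluster soft-clip breakpoints into candidates
#'
#' Soft-clip junction positions on the same contig and side within
#' \code{cluster_tolerance} are merged (single linkage); the candidate
#' position is the median clip position (lower coordinate on ties).
#' Discordant pairs are attached to the nearest candidate within the window.
#' Candidates with fewer than \code{min_split_support} split reads are
#' dropped.
#'
#' @param abn abnormal-read data.frame from \code{extract_abnormal_reads}.
#' @param config a \code{\link{pipeline_config}}.
#' @param insert_stats list(mean, sd) used to recognize discordant pairs.
#' @return BreakpointCandidate data.frame: sample, contig, pos, side ("R" =
#'   reads continue elsewhere after pos; "L" = before pos), split_support,
#'   discordant_support, clip_seq (longest observed clipped sequence).
#' @export
cluster_breakpoints <- function(abn, config = pipeline_config(),
                                insert_stats = NULL) {
  empty <- data.frame(sample = character(0), contig = character(0),
                      pos = integer(0), side = character(0),
                      split_support = integer(0),
                      discordant_support = integer(0),
                      clip_seq = character(0), stringsAsFactors = FALSE)
  if (!nrow(abn)) return(empty)
  min_clip <- config$soft_clip_min
  evs <- list()
  r <- abn[abn$clip_right > min_clip, , drop = FALSE]
  if (nrow(r)) evs[[1]] <- data.frame(
    sample = r$sample, contig = r$contig, pos = r$pos + r$mlen - 1L,
    side = "R", clip = substring(r$seq, nchar(r$seq) - r$clip_right + 1L),
    stringsAsFactors = FALSE)
  l <- abn[abn$clip_left > min_clip, , drop = FALSE]
  if (nrow(l)) evs[[length(evs) + 1L]] <- data.frame(
    sample = l$sample, contig = l$contig, pos = l$pos, side = "L",
    clip = substr(l$seq, 1L, l$clip_left), stringsAsFactors = FALSE)
  if (!length(evs)) return(empty)
  ev <- do.call(rbind, evs)

  out <- list()
  for (key in unique(paste(ev$sample, ev$contig, ev$side))) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    e <- ev[ev$sample == parts[1] & ev$contig == parts[2] & ev$side == parts[3], ]
    e <- e[order(e$pos), , drop = FALSE]
    brk <- c(0L, cumsum(diff(e$pos) > config$cluster_tolerance))
    for (g in split(e, brk)) {
      med <- sort(g$pos)[ceiling(nrow(g) / 2)]  # lower median on ties
      out[[length(out) + 1L]] <- data.frame(
        sample = parts[1], contig = parts[2], pos = med, side = parts[3],
        split_support = nrow(g),
        discordant_support = 0L,
        clip_seq = g$clip[which.max(nchar(g$clip))],
        stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, out)
  cand <- cand[cand$split_support >= config$min_split_support, , drop = FALSE]
  if (!nrow(cand)) return(empty)

  ## attach discordant pairs to the nearest compatible candidate
  if (is.null(insert_stats)) {
    disc <- abn$mate_contig != abn$contig
  } else {
    cut <- insert_stats$mean + config$discordance_sds * insert_stats$sd
    disc <- abn$mate_contig != abn$contig |
      (!is.na(abn$isize) & abs(abn$isize) > cut)
  }
  d <- abn[disc & abn$clip_left == 0L & abn$clip_right == 0L, , drop = FALSE]
  if (nrow(d)) {
    for (i in seq_len(nrow(cand))) {
      near <- d$sample == cand$sample[i] & d$contig == cand$contig[i] &
        abs(d$pos + d$mlen / 2 - cand$pos[i]) <= config$window
      cand$discordant_support[i] <- sum(near)
    }
  }
  rownames(cand) <- NULL
  cand
}

## expected clipped sequence (in the anchored read's stored orientation) for
## a junction hypothesis donor (c1,p1,s1) -> acceptor (c2,p2,s2)
expected_donor_clip <- function(ref, acc, len) {
  L <- nchar(ref$contigs[[acc$contig]])
  if (acc$strand == "+") {
    end <- min(acc$pos + len - 1L, L)
    if (end < acc$pos) return("")
    ref_fetch(ref, acc$contig, acc$pos, end, "+")
  } else {
    start <- max(acc$pos - len + 1L, 1L)
    if (start > acc$pos) return("")
    ref_fetch(ref, acc$contig, start, acc$pos, "-")
  }
}

expected_acceptor_clip <- function(ref, don, len) {
  L <- nchar(ref$contigs[[don$contig]])
  if (don$strand == "+") {
    start <- max(don$pos - len + 1L, 1L)
    ref_fetch(ref, don$contig, start, don$pos, "+")
  } else {
    end <- min(don$pos + len - 1L, L)
    ref_fetch(ref, don$contig, don$pos, end, "-")
  }
}

## score one junction hypothesis: X is the donor-anchored candidate, Y the
## acceptor-anchored one. Returns identity in [0,1] (minimum of both clips).
junction_hypothesis_identity <- function(ref, X, Y) {
  s1 <- if (X$side == "R") "+" else "-"
  s2 <- if (Y$side == "L") "+" else "-"
  don <- list(contig = X$contig, pos = X$pos, strand = s1)
  acc <- list(contig = Y$contig, pos = Y$pos, strand = s2)
  ## donor-anchored clip: acceptor prefix; stored rc'ed when donor on "-"
  exp_x <- expected_donor_clip(ref, acc, nchar(X$clip_seq))
  if (s1 == "-") exp_x <- rc(exp_x)
  id_x <- if (X$side == "R") str_identity(X$clip_seq, exp_x)
          else str_identity_right(X$clip_seq, exp_x)
  ## acceptor-anchored clip: donor suffix; stored rc'ed when acceptor on "-"
  exp_y <- expected_acceptor_clip(ref, don, nchar(Y$clip_seq))
  if (s2 == "-") exp_y <- rc(exp_y)
  id_y <- if (Y$side == "L") str_identity_right(Y$clip_seq, exp_y)
          else str_identity(Y$clip_seq, exp_y)
  min(id_x, id_y)
}

## identity aligning the *ends* of the strings (left-clip content abuts the
## junction at its right end)
str_identity_right <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0)
  str_identity(substring(a, nchar(a) - n + 1L),
               substring(b, nchar(b) - n + 1L))
}

## locate a clipped sequence in the reference. For a side-R (donor-anchored)
## candidate the clip is the acceptor's oriented prefix; for side L it is
## the donor's oriented suffix. Returns list(contig, pos, strand) of the
## partner breakend, or NULL.
find_clip_locus <- function(clip, side, ref, min_identity = 0.9,
                            anchor_k = 18L) {
  l <- nchar(clip)
  if (l < anchor_k + 2L) return(NULL)
  best <- NULL; best_id <- min_identity - 1e-9
  try_seq <- function(query, strand) {
    anchors <- unique(pmin(c(1L, l - anchor_k + 1L), l - anchor_k + 1L))
    for (astart in anchors) {
      a <- substr(query, astart, astart + anchor_k - 1L)
      for (cn in names(ref$contigs)) {
        hits <- gregexpr(a, ref$contigs[[cn]], fixed = TRUE)[[1]]
        if (hits[1] == -1L) next
        for (p in hits) {
          s <- p - astart + 1L
          if (s < 1L || s + l - 1L > nchar(ref$contigs[[cn]])) next
          idy <- str_identity(query, substr(ref$contigs[[cn]], s, s + l - 1L))
          if (idy > best_id) {
            best_id <<- idy
            ## convert the hit to the partner breakend position
            if (side == "R") {
              best <<- if (strand == "+") list(contig = cn, pos = s,
                                               strand = "+")
                       else list(contig = cn, pos = s + l - 1L, strand = "-")
            } else {
              best <<- if (strand == "+") list(contig = cn, pos = s + l - 1L,
                                               strand = "+")
                       else list(contig = cn, pos = s, strand = "-")
            }
          }
        }
      }
    }
  }
  try_seq(clip, "+")
  try_seq(rc(clip), "-")
  best
}

#' Pair breakpoint candidates and type the junctions
#'
#' Two candidates with reciprocal orientations are joined when each clipped
#' sequence matches the partner locus at \code{clip_match_identity} or
#' better: a right-clip at a joined to a left-clip at b > a on the same
#' contig is a deletion junction; left-at-a with right-at-b a tandem
#' duplication; same-side pairs are inversion junctions; inter-contig pairs
#' and unpaired candidates become breakends (BND).
#'
#' @param candidates data.frame from \code{\link{cluster_breakpoints}}.
#' @param ref the \code{ReferenceGenome} candidates were called against.
#' @param config a \code{\link{pipeline_config}}.
#' @param max_pair_span largest same-contig junction span considered.
#' @return SvCall data.frame: sample, type (DEL/DUP/INV/BND), contig, start,
#'   end, contig2, pos2, orient ("RL"/"LR"/"RR"/"LL" or one-sided "R-"/"L-"),
#'   split_support, discordant_support, bp1, bp2, strand1, strand2.
#' @export
pair_and_type <- function(candidates, ref, config = pipeline_config(),
                          max_pair_span = 100000L) {
  cand <- candidates
  n <- nrow(cand)
  used <- rep(FALSE, n)
  calls <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (used[i] || used[j]) next
        if (cand$sample[i] != cand$sample[j]) next
        same_ctg <- cand$contig[i] == cand$contig[j]
        if (same_ctg && abs(cand$pos[i] - cand$pos[j]) > max_pair_span) next
        ## try both role assignments, keep the better
        id_ij <- junction_hypothesis_identity(ref, as.list(cand[i, ]),
                                              as.list(cand[j, ]))
        id_ji <- junction_hypothesis_identity(ref, as.list(cand[j, ]),
                                              as.list(cand[i, ]))
        if (max(id_ij, id_ji) < config$clip_match_identity) next
        if (id_ij >= id_ji) { d <- i; a <- j } else { d <- j; a <- i }
        s1 <- if (cand$side[d] == "R") "+" else "-"
        s2 <- if (cand$side[a] == "L") "+" else "-"
        p1 <- cand$pos[d]; p2 <- cand$pos[a]
        typ <- orient <- NA_character_
        start <- end <- NA_integer_
        if (!same_ctg) {
          typ <- "BND"; orient <- paste0(cand$side[d], cand$side[a])
        } else if (s1 == "+" && s2 == "+") {
          if (p2 > p1) { typ <- "DEL"; start <- p1 + 1L; end <- p2 - 1L }
          else { typ <- "DUP"; start <- p2; end <- p1 }
          orient <- "RL"
        } else if (s1 == "-" && s2 == "-") {
          if (p2 < p1) { typ <- "DEL"; start <- p2 + 1L; end <- p1 - 1L }
          else { typ <- "DUP"; start <- p1; end <- p2 }
          orient <- "LR"
        } else {
          typ <- "INV"
          start <- min(p1, p2); end <- max(p1, p2)
          orient <- if (cand$side[d] == "R") "RR" else "LL"
        }
        calls[[length(calls) + 1L]] <- data.frame(
          sample = cand$sample[i], type = typ, contig = cand$contig[d],
          start = start, end = end,
          contig2 = cand$contig[a], pos2 = p2, orient = orient,
          split_support = cand$split_support[i] + cand$split_support[j],
          discordant_support = cand$discordant_support[i] +
            cand$discordant_support[j],
          bp1 = p1, bp2 = p2, strand1 = s1, strand2 = s2,
          stringsAsFactors = FALSE)
        used[i] <- used[j] <- TRUE
      }
    }
  }
  ## unpaired candidates: realign the clipped sequence to the reference to
  ## recover the partner locus (the other side's cluster may sit below the
  ## split-support floor); otherwise report a one-sided breakend
  for (i in which(!used)) {
    hit <- find_clip_locus(cand$clip_seq[i], cand$side[i], ref,
                           config$clip_match_identity)
    if (!is.null(hit)) {
      if (cand$side[i] %in% c("R", "L")) {
        ## candidate is donor-anchored for side R, acceptor-anchored for L
        if (cand$side[i] == "R") {
          don <- list(contig = cand$contig[i], pos = cand$pos[i], strand = "+")
          acc <- hit
        } else {
          acc <- list(contig = cand$contig[i], pos = cand$pos[i], strand = "+")
          don <- hit
        }
      }
      same_ctg <- don$contig == acc$contig
      typ <- orient <- NA_character_; start <- end <- NA_integer_
      if (!same_ctg) {
        typ <- "BND"; orient <- paste0(cand$side[i], "*")
      } else if (don$strand == "+" && acc$strand == "+") {
        if (acc$pos > don$pos) { typ <- "DEL"; start <- don$pos + 1L
                                 end <- acc$pos - 1L }
        else { typ <- "DUP"; start <- acc$pos; end <- don$pos }
        orient <- "RL"
      } else if (don$strand == "-" && acc$strand == "-") {
        if (acc$pos < don$pos) { typ <- "DEL"; start <- acc$pos + 1L
                                 end <- don$pos - 1L }
        else { typ <- "DUP"; start <- don$pos; end <- acc$pos }
        orient <- "LR"
      } else {
        typ <- "INV"; start <- min(don$pos, acc$pos)
        end <- max(don$pos, acc$pos)
        orient <- if (don$strand == "+") "RR" else "LL"
      }
      calls[[length(calls) + 1L]] <- data.frame(
        sample = cand$sample[i], type = typ, contig = don$contig,
        start = start, end = end, contig2 = acc$contig, pos2 = acc$pos,
        orient = orient, split_support = cand$split_support[i],
        discordant_support = cand$discordant_support[i],
        bp1 = don$pos, bp2 = acc$pos, strand1 = don$strand,
        strand2 = acc$strand, stringsAsFactors = FALSE)
      next
    }
    calls[[length(calls) + 1L]] <- data.frame(
      sample = cand$sample[i], type = "BND", contig = cand$contig[i],
      start = cand$pos[i], end = cand$pos[i],
      contig2 = NA_character_, pos2 = NA_integer_,
      orient = paste0(cand$side[i], "-"),
      split_support = cand$split_support[i],
      discordant_support = cand$discordant_support[i],
      bp1 = cand$pos[i], bp2 = NA_integer_,
      strand1 = if (cand$side[i] == "R") "+" else "-",
      strand2 = NA_character_, stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(sample = character(0), type = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), contig2 = character(0),
                      pos2 = integer(0), orient = character(0),
                      split_support = integer(0),
                      discordant_support = integer(0), bp1 = integer(0),
                      bp2 = integer(0), strand1 = character(0),
                      strand2 = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, calls)
  ## two sub-threshold sides realigned independently can duplicate a call
  key <- paste(res$sample, res$type, res$contig, res$bp1, res$contig2,
               res$bp2)
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      res$split_support[idx[1]] <- sum(res$split_support[idx])
    }
    res <- res[keep, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Discover SV calls in one sample
#'
#' Convenience driver: estimates insert statistics, extracts abnormal reads,
#' clusters breakpoints and types junction pairs.
#'
#' @param records one sample's alignment records.
#' @param ref the \code{ReferenceGenome}.
#' @param config a \code{\link{pipeline_config}}.
#' @param insert_stats optional precomputed list(mean, sd).
#' @return SvCall data.frame (see \code{\link{pair_and_type}}).
#' @export
discover_calls <- function(records, ref, config = pipeline_config(),
                           insert_stats = NULL) {
  if (is.null(insert_stats)) insert_stats <- estimate_insert_stats(records)
  abn <- extract_abnormal_reads(records, config, insert_stats = insert_stats)
  cand <- cluster_breakpoints(abn, config, insert_stats)
  pair_and_type(cand, ref, config)
}
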
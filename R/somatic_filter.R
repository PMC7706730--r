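# Clone-to-clone somatic filtering, reciprocal-overlap merging, adjacency
# grouping into complex SVs, MDA-artifact flagging and germline-catalog
# exclusion.

## support shown by one sample's records at a breakpoint: clipped reads whose
## clip junction lies within tolerance, or inter-contig mates nearby
breakpoint_support <- function(records, contig, pos, config) {
  tol <- config$cluster_tolerance
  r <- records[records$contig == contig, , drop = FALSE]
  if (!nrow(r)) return(0L)
  right <- r$clip_right > config$soft_clip_min &
    abs(r$pos + r$mlen - 1L - pos) <= tol
  left <- r$clip_left > config$soft_clip_min & abs(r$pos - pos) <= tol
  inter <- r$mate_contig != r$contig & r$pos <= pos + config$window &
    (r$pos + r$mlen - 1L) >= pos - config$window
  sum(right | left) + sum(inter)
}

#' Vote calls somatic by clone-to-clone comparison
#'
#' Each case call is compared against every control clone: a comparison
#' votes the call somatic iff the control shows zero supporting abnormal
#' reads at the call's breakpoints.
#'
#' @param case_calls SvCall data.frame for one case clone.
#' @param control_records named list of record data.frames, one per control
#'   clone (the case clone itself excluded by the caller).
#' @param config a \code{\link{pipeline_config}}.
#' @return \code{case_calls} with columns \code{comparison_votes} and
#'   \code{n_controls} added.
#' @export
call_somatic_pairwise <- function(case_calls, control_records,
                                  config = pipeline_config()) {
  n <- nrow(case_calls)
  votes <- integer(n)
  for (i in seq_len(n)) {
    bps <- list(c(case_calls$contig[i], case_calls$bp1[i]))
    if (!is.na(case_calls$bp2[i]))
      bps <- c(bps, list(c(ifelse(is.na(case_calls$contig2[i]),
                                  case_calls$contig[i],
                                  case_calls$contig2[i]),
                           case_calls$bp2[i])))
    for (ctrl in control_records) {
      sup <- sum(vapply(bps, function(b)
        breakpoint_support(ctrl, b[1], as.integer(b[2]), config), 0L))
      if (sup == 0L) votes[i] <- votes[i] + 1L
    }
  }
  case_calls$comparison_votes <- votes
  case_calls$n_controls <- length(control_records)
  case_calls
}

## do two calls describe the same event? same type, breakpoints within tol
same_call <- function(a, b, tol) {
  a$type == b$type && a$contig == b$contig &&
    abs(a$bp1 - b$bp1) <= tol &&
    ((is.na(a$bp2) && is.na(b$bp2)) ||
       (!is.na(a$bp2) && !is.na(b$bp2) && abs(a$bp2 - b$bp2) <= tol))
}

#' Retain recurrently voted mosaic calls and identify carriers
#'
#' Calls consistently voted somatic across comparisons are retained as true
#' mosaic SVs: a call group (clones sharing the same breakpoints) is kept
#' when each carrier's votes reach \code{recurrence_fraction} of its
#' informative (non-carrier) comparisons. Shared calls are reported once
#' with the carrier list.
#'
#' @param calls_by_clone named list of voted SvCall data.frames (one per
#'   clone, from \code{\link{call_somatic_pairwise}}).
#' @param config a \code{\link{pipeline_config}}.
#' @return SvCall data.frame with \code{carriers} (comma-separated) and
#'   \code{n_carriers}.
#' @export
recurrence_filter <- function(calls_by_clone, config = pipeline_config()) {
  all_calls <- do.call(rbind, calls_by_clone)
  if (is.null(all_calls) || !nrow(all_calls)) return(all_calls)
  rownames(all_calls) <- NULL
  n_clones <- length(calls_by_clone)
  tol <- config$cluster_tolerance
  ## group identical calls across clones (single pass; call counts are small)
  grp <- rep(NA_integer_, nrow(all_calls))
  g <- 0L
  for (i in seq_len(nrow(all_calls))) {
    if (!is.na(grp[i])) next
    g <- g + 1L; grp[i] <- g
    if (i < nrow(all_calls)) for (j in (i + 1L):nrow(all_calls)) {
      if (is.na(grp[j]) && same_call(all_calls[i, ], all_calls[j, ], tol))
        grp[j] <- g
    }
  }
  kept <- list()
  for (gg in seq_len(g)) {
    idx <- which(grp == gg)
    carriers <- unique(all_calls$sample[idx])
    informative <- n_clones - length(carriers)
    if (informative == 0L) next  # present in every clone: germline-like
    need <- config$recurrence_fraction * informative
    votes <- all_calls$comparison_votes[idx]
    if (all(votes >= need)) {
      rep1 <- all_calls[idx[1], , drop = FALSE]
      rep1$split_support <- sum(all_calls$split_support[idx])
      rep1$carriers <- paste(sort(carriers), collapse = ",")
      rep1$n_carriers <- length(carriers)
      kept[[length(kept) + 1L]] <- rep1
    }
  }
  if (!length(kept)) {
    out <- all_calls[0, , drop = FALSE]
    out$carriers <- character(0); out$n_carriers <- integer(0)
    return(out)
  }
  res <- do.call(rbind, kept)
  rownames(res) <- NULL
  res
}

## reciprocal overlap fraction of two spans (0 when either is empty)
reciprocal_fraction <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1L
  if (ov <= 0L) return(0)
  min(ov / (e1 - s1 + 1L), ov / (e2 - s2 + 1L))
}

#' Merge calls with reciprocal overlap
#'
#' Calls of the same type whose spans overlap at least
#' \code{reciprocal_overlap} of both lengths are merged: span = union,
#' supports summed. Idempotent (applied to fixpoint).
#'
#' @param calls SvCall data.frame (spanned types only are merged; BNDs pass
#'   through).
#' @param config a \code{\link{pipeline_config}}.
#' @return merged SvCall data.frame.
#' @export
merge_reciprocal <- function(calls, config = pipeline_config()) {
  if (is.null(calls) || nrow(calls) < 2L) return(calls)
  spanned <- calls$type %in% c("DEL", "DUP", "INV", "INS") & !is.na(calls$start)
  rest <- calls[!spanned, , drop = FALSE]
  m <- calls[spanned, , drop = FALSE]
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(m)) {
      j <- i + 1L
      while (j <= nrow(m)) {
        if (m$sample[i] == m$sample[j] && m$type[i] == m$type[j] &&
            m$contig[i] == m$contig[j] &&
            reciprocal_fraction(m$start[i], m$end[i], m$start[j], m$end[j]) >=
              config$reciprocal_overlap) {
          m$start[i] <- min(m$start[i], m$start[j])
          m$end[i] <- max(m$end[i], m$end[j])
          m$split_support[i] <- m$split_support[i] + m$split_support[j]
          m$discordant_support[i] <- m$discordant_support[i] +
            m$discordant_support[j]
          m <- m[-j, , drop = FALSE]
          merged_any <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  res <- rbind(m, rest)
  rownames(res) <- NULL
  res
}

#' Group adjacent calls into complex SVs
#'
#' Single-linkage grouping of same-sample calls whose breakpoints lie within
#' \code{adjacency} bp of each other; groups of two or more events are
#' labeled complex. Every call belongs to exactly one group.
#'
#' @param calls SvCall data.frame.
#' @param config a \code{\link{pipeline_config}}.
#' @return \code{calls} with columns \code{group} (integer id) and
#'   \code{complex} (logical).
#' @export
group_adjacent_complex <- function(calls, config = pipeline_config()) {
  n <- nrow(calls)
  if (!n) { calls$group <- integer(0); calls$complex <- logical(0); return(calls) }
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  adj <- config$adjacency
  bp_list <- lapply(seq_len(n), function(i) {
    b <- list(c(calls$contig[i], calls$bp1[i]))
    if (!is.na(calls$bp2[i]))
      b <- c(b, list(c(ifelse(is.na(calls$contig2[i]), calls$contig[i],
                              calls$contig2[i]), calls$bp2[i])))
    b
  })
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (calls$sample[i] != calls$sample[j]) next
    close <- any(vapply(bp_list[[i]], function(a)
      any(vapply(bp_list[[j]], function(b)
        a[1] == b[1] && abs(as.integer(a[2]) - as.integer(b[2])) <= adj,
        TRUE)), TRUE))
    if (close) parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, 0L)
  calls$group <- match(roots, unique(roots))
  sizes <- table(calls$group)
  calls$complex <- sizes[as.character(calls$group)] >= 2L
  calls
}

#' Flag MDA chimera-artifact groups
#'
#' A group is flagged iff it contains a one-sided inverted breakend — an
#' inversion-type junction (orient RR or LL, or an unpaired breakend)
#' lacking its reciprocal opposite-orientation partner in the group —
#' adjacent to a duplication. The fully reciprocal deletion+duplication
#' pattern of an excised circle is never flagged.
#'
#' @param grouped calls with a \code{group} column
#'   (\code{\link{group_adjacent_complex}}).
#' @param config a \code{\link{pipeline_config}}.
#' @return \code{grouped} with logical column \code{mda_artifact}.
#' @export
flag_mda_artifacts <- function(grouped, config = pipeline_config()) {
  grouped$mda_artifact <- FALSE
  for (g in unique(grouped$group)) {
    idx <- which(grouped$group == g)
    gg <- grouped[idx, , drop = FALSE]
    has_dup <- any(gg$type == "DUP")
    inv_or <- gg$orient[gg$type == "INV"]
    one_sided_inv <- (("RR" %in% inv_or) != ("LL" %in% inv_or)) ||
      any(gg$type == "BND" & gg$orient %in% c("R-", "L-") & has_dup & nrow(gg) >= 2L)
    if (has_dup && one_sided_inv) grouped$mda_artifact[idx] <- TRUE
  }
  grouped
}

#' Remove calls matching a germline SV catalog
#'
#' Calls reciprocally overlapping a catalog interval at
#' \code{reciprocal_overlap} or more are removed and reported.
#'
#' @param calls SvCall data.frame.
#' @param catalog data.frame with columns contig, start, end (1-based
#'   inclusive), e.g. read from a BED file via \code{\link{read_bed}}; may
#'   be empty.
#' @param config a \code{\link{pipeline_config}}.
#' @return list(kept, removed).
#' @export
filter_known_germline <- function(calls, catalog,
                                  config = pipeline_config()) {
  if (is.null(catalog) || !nrow(catalog)) return(list(kept = calls,
                                                      removed = calls[0, ]))
  if (!all(c("contig", "start", "end") %in% names(catalog)))
    stop("catalog must have columns contig, start, end")
  drop <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (is.na(calls$start[i])) next
    hit <- catalog$contig == calls$contig[i]
    for (j in which(hit)) {
      if (reciprocal_fraction(calls$start[i], calls$end[i],
                              catalog$start[j], catalog$end[j]) >=
          config$reciprocal_overlap) { drop[i] <- TRUE; break }
    }
  }
  list(kept = calls[!drop, , drop = FALSE],
       removed = calls[drop, , drop = FALSE])
}

#' Read a BED file of intervals
#'
#' @param path BED path (0-based half-open); returns 1-based inclusive.
#' @return data.frame contig, start, end (plus name when present).
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("malformed BED: fewer than 3 columns")
  if (!is.numeric(bed[[2]]) || !is.numeric(bed[[3]]))
    stop("malformed BED: non-numeric coordinates")
  out <- data.frame(contig = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(bed) >= 4L) out$name <- bed[[4]]
  out
}
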
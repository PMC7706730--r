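# Replication-model reconstruction: pool junction adjacencies observed in
# assembled contigs and walk them from the left anchor flank to the right,
# yielding the ordered oriented segment chain of the alternate allele. The
# walk needs only the junctions, so large inserted segments whose interiors
# attract no abnormal reads are reconstructed in full.

flip_strand <- function(s) ifelse(s == "+", "-", "+")

## mirror of a junction as it appears in a reverse-orientation contig
mirror_junction <- function(j) {
  data.frame(donor_contig = j$acc_contig, donor_pos = j$acc_pos,
             donor_strand = flip_strand(j$acc_strand),
             acc_contig = j$donor_contig, acc_pos = j$donor_pos,
             acc_strand = flip_strand(j$donor_strand),
             overlap = j$overlap, stringsAsFactors = FALSE)
}

## pool junctions from several contigs: add mirrors, dedupe within tolerance
pool_junctions <- function(junction_list, tol = 10L) {
  js <- do.call(rbind, junction_list)
  if (is.null(js) || !nrow(js)) return(js)
  js <- rbind(js, do.call(rbind, lapply(seq_len(nrow(js)), function(i)
    mirror_junction(js[i, ]))))
  js$support <- 1L
  keep <- rep(TRUE, nrow(js))
  for (i in seq_len(nrow(js) - 1L)) {
    if (!keep[i]) next
    for (j in (i + 1L):nrow(js)) {
      if (!keep[j]) next
      if (js$donor_contig[i] == js$donor_contig[j] &&
          js$acc_contig[i] == js$acc_contig[j] &&
          js$donor_strand[i] == js$donor_strand[j] &&
          js$acc_strand[i] == js$acc_strand[j] &&
          abs(js$donor_pos[i] - js$donor_pos[j]) <= tol &&
          abs(js$acc_pos[i] - js$acc_pos[j]) <= tol) {
        js$support[i] <- js$support[i] + 1L
        keep[j] <- FALSE
      }
    }
  }
  js <- js[keep, , drop = FALSE]
  ## pair each junction with its mirror so the walk consumes both at once
  js$mirror_of <- NA_integer_
  for (i in seq_len(nrow(js))) {
    if (!is.na(js$mirror_of[i])) next
    mi <- mirror_junction(js[i, ])
    for (j in seq_len(nrow(js))) {
      if (j == i || !is.na(js$mirror_of[j])) next
      if (js$donor_contig[j] == mi$donor_contig &&
          js$acc_contig[j] == mi$acc_contig &&
          js$donor_strand[j] == mi$donor_strand &&
          js$acc_strand[j] == mi$acc_strand &&
          abs(js$donor_pos[j] - mi$donor_pos) <= tol &&
          abs(js$acc_pos[j] - mi$acc_pos) <= tol) {
        js$mirror_of[i] <- j; js$mirror_of[j] <- i
        break
      }
    }
  }
  rownames(js) <- NULL
  js
}

## enumerate walks of the junction graph from the left flank of the anchor
## region; every walk that returns to the anchor contig forward strand and
## runs out of junctions is a candidate chain. Bounded DFS (junction counts
## per locus are tiny); co-optimal chains are disambiguated downstream by
## the explanation score.
walk_chain_all <- function(junctions, region, max_depth = 16L,
                           max_chains = 40L) {
  chains <- list()
  recurse <- function(c0, pos, strand, used, pieces, depth) {
    if (length(chains) >= max_chains || depth > max_depth) return()
    cand <- which(!used & junctions$donor_contig == c0 &
                    junctions$donor_strand == strand)
    cand <- if (strand == "+") cand[junctions$donor_pos[cand] >= pos]
            else cand[junctions$donor_pos[cand] <= pos]
    ## terminating option: run to the region end on the anchor forward strand
    if (c0 == region$contig && strand == "+" && pos <= region$end) {
      done <- c(pieces, list(data.frame(contig = c0, start = pos,
                                        end = region$end, strand = "+",
                                        stringsAsFactors = FALSE)))
      chain <- do.call(rbind, done)
      rownames(chain) <- NULL
      if (all(chain$start <= chain$end))
        chains[[length(chains) + 1L]] <<- chain
      if (!length(cand)) return()
    } else if (!length(cand)) return()  # dead end off the anchor flank
    ## explore nearest junctions first
    ord <- cand[order(abs(junctions$donor_pos[cand] - pos))]
    for (k in ord) {
      dp <- junctions$donor_pos[k]
      piece <- if (strand == "+")
        data.frame(contig = c0, start = pos, end = dp, strand = "+",
                   stringsAsFactors = FALSE)
      else data.frame(contig = c0, start = dp, end = pos, strand = "-",
                      stringsAsFactors = FALSE)
      used2 <- used
      used2[k] <- TRUE
      if (!is.na(junctions$mirror_of[k])) used2[junctions$mirror_of[k]] <- TRUE
      recurse(junctions$acc_contig[k], junctions$acc_pos[k],
              junctions$acc_strand[k], used2, c(pieces, list(piece)),
              depth + 1L)
    }
  }
  recurse(region$contig, region$start, "+", rep(FALSE, nrow(junctions)),
          list(), 0L)
  ## prefer chains consuming more junctions (more of the evidence explained)
  if (length(chains) > 1L) {
    nj <- vapply(chains, nrow, 0L)
    chains <- chains[order(-nj)]
  }
  chains
}

#' Classify a resolved segment chain as a rearrangement model
#'
#' Given the ordered oriented chain covering the anchor region (first and
#' last pieces are the collinear anchor flanks), derives the event list:
#' deletions are reference sub-spans of the replaced region covered zero
#' times, duplications spans with total copy count of two or more,
#' inversions reverse-orientation segments, insertions segments from other
#' contigs or outside the anchor neighborhood. Template switches are chain
#' junctions where replication did not continue contiguously, with their
#' reference jump distances; the absolute size is |replaced reference length
#' - alternate length|.
#'
#' @param chain data.frame(contig, start, end, strand) in alternate-allele
#'   order, flanks included (e.g. from the junction walk).
#' @param ref a \code{ReferenceGenome}.
#' @param anchor_region list(contig, start, end) neighborhood of the event.
#' @param config a \code{\link{pipeline_config}}.
#' @return a \code{RearrangementModel}: list(chain, events, classes,
#'   template_switches, switch_jumps, segment_sizes, deleted_sizes,
#'   replaced_span, absolute_size, junction_mh, junctions).
#' @export
classify_rearrangement <- function(chain, ref, anchor_region,
                                   config = pipeline_config()) {
  if (is.null(chain) || !nrow(chain)) stop("empty chain: unresolved model")
  n <- nrow(chain)
  c0 <- anchor_region$contig
  ## junction table between adjacent pieces
  if (n >= 2L) {
    juncs <- data.frame(
      donor_contig = chain$contig[-n],
      donor_pos = ifelse(chain$strand[-n] == "+", chain$end[-n], chain$start[-n]),
      donor_strand = chain$strand[-n],
      acc_contig = chain$contig[-1],
      acc_pos = ifelse(chain$strand[-1] == "+", chain$start[-1], chain$end[-1]),
      acc_strand = chain$strand[-1], stringsAsFactors = FALSE)
    contiguous <- juncs$donor_contig == juncs$acc_contig &
      juncs$donor_strand == juncs$acc_strand &
      ifelse(juncs$donor_strand == "+", juncs$acc_pos - juncs$donor_pos,
             juncs$donor_pos - juncs$acc_pos) == 1L
    juncs <- juncs[!contiguous, , drop = FALSE]
  } else {
    juncs <- data.frame(donor_contig = character(0), donor_pos = integer(0),
                        donor_strand = character(0), acc_contig = character(0),
                        acc_pos = integer(0), acc_strand = character(0),
                        stringsAsFactors = FALSE)
  }
  switches <- nrow(juncs)
  jumps <- ifelse(juncs$donor_contig == juncs$acc_contig,
                  abs(juncs$acc_pos - juncs$donor_pos) - 1L, NA_integer_)
  mh <- vapply(seq_len(nrow(juncs)), function(i)
    detect_microhomology(ref,
      donor = list(contig = juncs$donor_contig[i], pos = juncs$donor_pos[i],
                   strand = juncs$donor_strand[i]),
      acceptor = list(contig = juncs$acc_contig[i], pos = juncs$acc_pos[i],
                      strand = juncs$acc_strand[i]),
      max_mh = config$max_mh), 0L)

  ## replaced span between the outer flanks (collinear "+" pieces on c0)
  if (n >= 2L) {
    rep_start <- chain$end[1] + 1L      # first base after the left flank
    rep_end <- chain$start[n] - 1L      # last base before the right flank
    inner <- chain[-c(1L, n), , drop = FALSE]
  } else {
    rep_start <- 1L; rep_end <- 0L
    inner <- chain[0, , drop = FALSE]
  }
  alt_len <- if (nrow(inner)) sum(inner$end - inner$start + 1L) else 0L
  ref_len <- max(rep_end - rep_start + 1L, 0L)
  absolute_size <- abs(ref_len - alt_len)

  ## event derivation over the neighborhood of the replaced span (falling
  ## back to the supplied anchor region for degenerate chains)
  ev <- list()
  region <- if (n >= 2L && rep_end >= rep_start - 1L) {
    c(max(1L, rep_start - config$window),
      min(nchar(ref$contigs[[c0]]), rep_end + config$window))
  } else c(anchor_region$start, anchor_region$end)
  loc <- which(inner$contig == c0 & inner$start <= region[2] &
                 inner$end >= region[1])
  if (ref_len > 0L) {
    delspan <- IRanges::IRanges(rep_start, rep_end)
    covered <- if (length(loc))
      IRanges::reduce(IRanges::IRanges(inner$start[loc], inner$end[loc]))
    else IRanges::IRanges()
    gaps <- IRanges::setdiff(delspan, covered)
    for (i in seq_along(gaps))
      ev[[length(ev) + 1L]] <- data.frame(
        type = "DEL", contig = c0, start = IRanges::start(gaps)[i],
        end = IRanges::end(gaps)[i], stringsAsFactors = FALSE)
  }
  if (length(loc)) {
    segs <- IRanges::IRanges(inner$start[loc], inner$end[loc])
    cov <- IRanges::coverage(segs, width = region[2])
    base1 <- IRanges::IRanges(region[1], region[2])
    if (ref_len > 0L)
      base1 <- IRanges::setdiff(base1, IRanges::IRanges(rep_start, rep_end))
    dup_r <- IRanges::reduce(c(
      methods::as(IRanges::slice(cov, lower = 2), "IRanges"),
      IRanges::intersect(methods::as(IRanges::slice(cov, lower = 1), "IRanges"), base1)))
    for (i in seq_along(dup_r))
      ev[[length(ev) + 1L]] <- data.frame(
        type = "DUP", contig = c0, start = IRanges::start(dup_r)[i],
        end = IRanges::end(dup_r)[i], stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(inner))) {
    if (inner$strand[i] == "-")
      ev[[length(ev) + 1L]] <- data.frame(
        type = "INV", contig = inner$contig[i], start = inner$start[i],
        end = inner$end[i], stringsAsFactors = FALSE)
    distal <- inner$contig[i] != c0 || inner$end[i] < region[1] ||
      inner$start[i] > region[2]
    if (distal)
      ev[[length(ev) + 1L]] <- data.frame(
        type = "INS", contig = inner$contig[i], start = inner$start[i],
        end = inner$end[i], stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) {
    e <- do.call(rbind, ev); e$size <- e$end - e$start + 1L
    e[order(e$type, e$start), , drop = FALSE]
  } else {
    data.frame(type = character(0), contig = character(0), start = integer(0),
               end = integer(0), size = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(chain = chain, events = events, classes = sort(events$type),
                 template_switches = switches, switch_jumps = jumps,
                 segment_sizes = inner$end - inner$start + 1L,
                 deleted_sizes = events$size[events$type == "DEL"],
                 replaced_span = c(start = rep_start, end = rep_end),
                 absolute_size = absolute_size, junction_mh = mh,
                 junctions = juncs), class = "RearrangementModel")
}

#' @export
print.RearrangementModel <- function(x, ...) {
  cat("RearrangementModel:", nrow(x$chain), "chain piece(s);",
      x$template_switches, "template switch(es); events:",
      if (length(x$classes)) paste(x$classes, collapse = "+") else "none",
      "; |size|", x$absolute_size, "bp; MH:",
      paste(x$junction_mh, collapse = ","), "\n")
  invisible(x)
}

#' Size spectra of resolved rearrangement models
#'
#' Three labeled size lists as used for replication-model summaries: sizes
#' of individual rearranged segments, of each template-switch jump, and of
#' deleted (non-replicated) regions.
#'
#' @param models list of \code{RearrangementModel}.
#' @return list(segments, switches, deleted) of integer vectors.
#' @export
size_spectra <- function(models) {
  list(segments = unlist(lapply(models, `[[`, "segment_sizes")),
       switches = unlist(lapply(models, function(m)
         m$switch_jumps[!is.na(m$switch_jumps)])),
       deleted = unlist(lapply(models, `[[`, "deleted_sizes")))
}

#' Reconstruct the alternate-allele sequence of a model
#'
#' @param model a \code{RearrangementModel}.
#' @param ref a \code{ReferenceGenome}.
#' @return the alternate haplotype sequence across the model's chain
#'   (flanks included).
#' @export
model_alt_sequence <- function(model, ref) {
  map_sequence(ref$contigs, finish_map(data.frame(
    contig = model$chain$contig, ref_start = model$chain$start,
    ref_end = model$chain$end, strand = model$chain$strand,
    stringsAsFactors = FALSE)))
}

#' Explanation score of a model against its abnormal reads
#'
#' The fraction of abnormal reads in the event neighborhood that align
#' end-to-end to the reconstructed alternate allele with at most
#' \code{max_mismatch} mismatches (either orientation). Calls whose score
#' does not exceed \code{score_threshold} are rejected as unexplained.
#'
#' @param model a \code{RearrangementModel}.
#' @param abn abnormal reads (strictly abnormal; rescued mates excluded).
#' @param ref a \code{ReferenceGenome}.
#' @param config a \code{\link{pipeline_config}}.
#' @return list(score, n_reads, retained) — retained iff score strictly
#'   exceeds the threshold.
#' @export
explanation_score <- function(model, abn, ref, config = pipeline_config()) {
  if ("rescued" %in% names(abn)) abn <- abn[!abn$rescued, , drop = FALSE]
  reads <- unique(abn$seq)
  if (!length(reads)) return(list(score = NA_real_, n_reads = 0L,
                                  retained = FALSE))
  alt <- model_alt_sequence(model, ref)
  ok <- vapply(reads, read_fits, TRUE, target = alt,
               max_mismatch = config$max_mismatch, USE.NAMES = FALSE)
  score <- mean(ok)
  list(score = score, n_reads = length(reads),
       retained = score > config$score_threshold)
}

## does the read align end-to-end somewhere in target (either orientation)
## with <= max_mismatch mismatches? anchored on exact 20-mers.
read_fits <- function(read, target, max_mismatch = 2L) {
  for (seq in c(read, rc(read))) {
    L <- nchar(seq)
    anchors <- unique(pmax(1L, c(1L, L %/% 2L - 9L, L - 19L)))
    for (astart in anchors) {
      a <- substr(seq, astart, min(astart + 19L, L))
      hits <- gregexpr(a, target, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (p in hits) {
        off <- p - astart
        if (off < 0L || off + L > nchar(target)) next
        if (str_mismatches(seq, substr(target, off + 1L, off + L)) <=
            max_mismatch) return(TRUE)
      }
    }
  }
  FALSE
}

#' Detect extrachromosomal circular DNA patterns
#'
#' A deletion and a duplication with reciprocally matching breakpoints
#' (both ends coincide within the cluster tolerance) are fused into one
#' circular-DNA event — the circle excised from the deleted region — and
#' removed from the plain call list.
#'
#' @param calls SvCall data.frame.
#' @param config a \code{\link{pipeline_config}}.
#' @param ref optional \code{ReferenceGenome}; when given, the circle
#'   junction's microhomology is measured and attached.
#' @return list(circles = data.frame(sample, contig, start, end, del_row,
#'   dup_row[, junction_mh]), calls = remaining calls).
#' @export
detect_eccdna <- function(calls, config = pipeline_config(), ref = NULL) {
  tol <- config$cluster_tolerance
  circles <- list()
  drop <- rep(FALSE, nrow(calls))
  dels <- which(calls$type == "DEL")
  dups <- which(calls$type == "DUP")
  for (i in dels) for (j in dups) {
    if (drop[i] || drop[j]) next
    if (calls$sample[i] != calls$sample[j]) next
    if (calls$contig[i] != calls$contig[j]) next
    if (abs(calls$start[i] - calls$start[j]) <= tol &&
        abs(calls$end[i] - calls$end[j]) <= tol) {
      circles[[length(circles) + 1L]] <- data.frame(
        sample = calls$sample[i], contig = calls$contig[i],
        start = min(calls$start[i], calls$start[j]),
        end = max(calls$end[i], calls$end[j]),
        del_row = i, dup_row = j, stringsAsFactors = FALSE)
      drop[i] <- drop[j] <- TRUE
    }
  }
  circ_df <- if (length(circles)) do.call(rbind, circles) else
    data.frame(sample = character(0), contig = character(0),
               start = integer(0), end = integer(0), del_row = integer(0),
               dup_row = integer(0), stringsAsFactors = FALSE)
  if (!is.null(ref) && nrow(circ_df)) {
    ## the circle junction joins the span's end back to its start
    circ_df$junction_mh <- vapply(seq_len(nrow(circ_df)), function(i)
      detect_microhomology(ref,
        donor = list(contig = circ_df$contig[i], pos = circ_df$end[i],
                     strand = "+"),
        acceptor = list(contig = circ_df$contig[i], pos = circ_df$start[i],
                        strand = "+"),
        max_mh = config$max_mh), 0L)
  }
  list(circles = circ_df, calls = calls[!drop, , drop = FALSE])
}

#' Resolve one SV locus into a rearrangement model
#'
#' Extracts abnormal reads (with mates) around the locus, assembles them,
#' aligns every contig to the reference, pools the junction adjacencies and
#' walks them into the alternate-allele chain, then classifies the model,
#' measures junction microhomologies and computes the explanation score.
#'
#' @param records one sample's alignment records.
#' @param locus list(contig, start, end): the anchor neighborhood of the
#'   candidate event (where the allele replaces reference sequence).
#' @param ref a \code{ReferenceGenome}.
#' @param config a \code{\link{pipeline_config}}.
#' @param extra_loci optional data.frame(contig, start, end) of additional
#'   breakpoint neighborhoods to pull abnormal reads from (the other members
#'   of a complex group; donor loci of inserted segments).
#' @param index optional prebuilt \code{\link{kmer_index}}.
#' @param insert_stats optional list(mean, sd).
#' @return list(model, score, contigs, alternatives, unresolved_reason);
#'   \code{model} is NULL when the locus cannot be walked. When several
#'   chains explain the junction graph, the one whose reconstructed allele
#'   explains the most abnormal reads is reported and the others returned in
#'   \code{alternatives}.
#' @export
resolve_call <- function(records, locus, ref, config = pipeline_config(),
                         extra_loci = NULL, index = NULL,
                         insert_stats = NULL) {
  loci <- data.frame(contig = locus$contig, start = locus$start,
                     end = locus$end, stringsAsFactors = FALSE)
  if (!is.null(extra_loci) && nrow(extra_loci))
    loci <- unique(rbind(loci, extra_loci[, c("contig", "start", "end")]))
  resolve_core(records, loci, list(locus), ref, config, index, insert_stats)
}

## shared machinery: extract/assemble/align once, then walk every candidate
## anchor region and keep the model explaining the most abnormal reads
resolve_core <- function(records, loci, candidate_anchors, ref, config,
                         index = NULL, insert_stats = NULL) {
  if (is.null(insert_stats)) insert_stats <- estimate_insert_stats(records)
  abn_list <- lapply(seq_len(nrow(loci)), function(i)
    extract_abnormal_reads(records, config, locus = as.list(loci[i, ]),
                           insert_stats = insert_stats, include_mates = TRUE))
  abn <- unique(do.call(rbind, abn_list))
  if (nrow(abn) < 2L)
    return(list(model = NULL, score = NULL, contigs = list(),
                alternatives = list(),
                unresolved_reason = "fewer than 2 abnormal reads"))
  ## local assembly per breakpoint neighborhood keeps read sets small and
  ## every junction represented
  contigs <- list()
  for (ab in abn_list) {
    if (nrow(ab) < 2L) next
    contigs <- c(contigs, assemble_contigs(ab$seq, config$min_overlap,
                                           config$max_mismatch))
  }
  contigs <- Filter(function(x) x$n_reads >= 2L, contigs)
  seen <- !duplicated(vapply(contigs, `[[`, "", "sequence"))
  contigs <- contigs[seen]
  if (!length(contigs))
    return(list(model = NULL, score = NULL, contigs = contigs,
                alternatives = list(),
                unresolved_reason = "no multi-read contig"))
  if (is.null(index)) index <- kmer_index(ref, config$seed_k)
  jl <- list()
  for (ct in contigs) {
    alns <- align_contig(ct$sequence, ref, config, index)
    if (!nrow(alns)) next
    ch <- chain_segments(alns, nchar(ct$sequence), config,
                         contig_seq = ct$sequence, ref = ref)
    if (nrow(ch$junctions)) jl[[length(jl) + 1L]] <- ch$junctions
  }
  pooled <- pool_junctions(jl, config$cluster_tolerance)
  if (is.null(pooled) || !nrow(pooled))
    return(list(model = NULL, score = NULL, contigs = contigs,
                alternatives = list(),
                unresolved_reason = "no junctions recovered"))
  ## enumerate candidate chains from every anchor, deduplicated by their
  ## junction structure (flank extents vary with the anchor window only)
  chains <- list(); keys <- character(0); regions <- list()
  for (anc in candidate_anchors) {
    region <- list(contig = anc$contig,
                   start = max(1L, anc$start - config$window),
                   end = min(nchar(ref$contigs[[anc$contig]]),
                             anc$end + config$window))
    for (chain in walk_chain_all(pooled, region)) {
      n <- nrow(chain)
      key <- if (n < 2L) paste0("null:", chain$contig[1]) else
        paste(c(chain$contig[1], chain$end[1], chain$start[n],
                unlist(chain[-c(1L, n), c("contig", "start", "end",
                                          "strand")])), collapse = ":")
      if (key %in% keys) next
      keys <- c(keys, key)
      chains[[length(chains) + 1L]] <- chain
      regions[[length(regions) + 1L]] <- region
    }
  }
  if (!length(chains))
    return(list(model = NULL, score = NULL, contigs = contigs,
                alternatives = list(),
                unresolved_reason = "no walk reaches the right anchor flank"))
  models <- lapply(seq_along(chains), function(i)
    classify_rearrangement(chains[[i]], ref, regions[[i]], config))
  ## model selection scores on the junction-informative (clipped) reads;
  ## discordant-only reads fit any near-reference chain
  sel_abn <- abn[abn$clip_left > config$soft_clip_min |
                   abn$clip_right > config$soft_clip_min, , drop = FALSE]
  if (!nrow(sel_abn)) sel_abn <- abn
  scores <- lapply(models, explanation_score, abn = sel_abn, ref = ref,
                   config = config)
  vals <- vapply(scores, `[[`, 0, "score")
  ## among best-scoring models prefer the one explaining more junctions
  best <- which(vals >= max(vals) - 1e-9)
  if (length(best) > 1L) {
    nsw <- vapply(models[best], `[[`, 0L, "template_switches")
    best <- best[which.max(nsw)]
  } else best <- best[1]
  ## the reported score covers every abnormal read in the neighborhood
  final_score <- explanation_score(models[[best]], abn, ref, config)
  list(model = models[[best]], score = final_score, contigs = contigs,
       alternatives = models[-best], unresolved_reason = NULL)
}

#' Resolve a complex call group
#'
#' Convenience wrapper around \code{\link{resolve_call}} for a group of
#' adjacent calls (one \code{group} from
#' \code{\link{group_adjacent_complex}}): the tightest same-contig call span
#' is used as the anchor and every other breakpoint neighborhood contributes
#' abnormal reads.
#'
#' @param records one sample's alignment records.
#' @param group_calls the group's SvCall rows.
#' @param ref a \code{ReferenceGenome}.
#' @param config a \code{\link{pipeline_config}}.
#' @param index optional prebuilt \code{\link{kmer_index}}.
#' @param insert_stats optional list(mean, sd).
#' @return as \code{\link{resolve_call}}.
#' @export
resolve_group <- function(records, group_calls, ref,
                          config = pipeline_config(), index = NULL,
                          insert_stats = NULL) {
  bps <- list()
  for (i in seq_len(nrow(group_calls))) {
    bps[[length(bps) + 1L]] <- data.frame(
      contig = group_calls$contig[i], pos = group_calls$bp1[i],
      stringsAsFactors = FALSE)
    if (!is.na(group_calls$bp2[i]))
      bps[[length(bps) + 1L]] <- data.frame(
        contig = ifelse(is.na(group_calls$contig2[i]), group_calls$contig[i],
                        group_calls$contig2[i]),
        pos = group_calls$bp2[i], stringsAsFactors = FALSE)
  }
  bps <- unique(do.call(rbind, bps))
  ## candidate anchors: every adjacency cluster of breakpoints per contig
  ## (the walk scoring decides which is the true replacement site)
  anchors <- list()
  for (cn in unique(bps$contig)) {
    apos <- sort(bps$pos[bps$contig == cn])
    cl <- cumsum(c(0L, diff(apos) > config$adjacency))
    for (g in unique(cl)) {
      span <- range(apos[cl == g])
      anchors[[length(anchors) + 1L]] <- list(contig = cn, start = span[1],
                                              end = span[2])
    }
  }
  loci <- data.frame(contig = bps$contig, start = bps$pos, end = bps$pos,
                     stringsAsFactors = FALSE)
  resolve_core(records, loci, anchors, ref, config, index, insert_stats)
}
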
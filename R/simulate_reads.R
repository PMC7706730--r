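# Paired-end clone-sequencing simulator.
#
# Reads are sampled from clone haplotypes and *projected* onto the reference:
# a read wholly inside one chain segment maps contiguously; a read crossing
# an alt junction is anchored to the segment holding most of it, with the
# bases past the junction soft-clipped; mates falling in segments from
# different contigs get inter-contig mate fields; pairs straddling a deletion
# have inflated insert sizes. The output mimics a name-sorted SAM projection:
# sequences are stored in reference orientation, positions are 1-based.

#' Describe a sequenced clone (or bulk sample)
#'
#' @param clone_id,brain_id identifiers.
#' @param harbored_svs data.frame with columns label, cell_fraction: the SV
#'   alleles this clone carries and the fraction of its cells carrying each
#'   (1.0 for clonal events, i.e. heterozygous in every cell, allele fraction
#'   0.5; lower for subclonal culture-acquired events). NULL for none.
#' @param unique_snv_count number of clone-private somatic SNVs to embed at
#'   allele fraction 0.5 (placed outside SV spans).
#' @param mda whether this sample should also receive MDA chimera artifacts
#'   when the scenario asks for them.
#' @param coverage mean sequence depth.
#' @param insert_mean,insert_sd fragment-size distribution (bp).
#' @param read_length read length (bp).
#' @param error_rate per-base substitution error rate.
#' @return an object of class \code{CloneSpec}.
#' @export
clone_spec <- function(clone_id, brain_id = "brain1", harbored_svs = NULL,
                       unique_snv_count = 0L, mda = FALSE, coverage = 30,
                       insert_mean = 400, insert_sd = 50, read_length = 150L,
                       error_rate = 0.001) {
  if (coverage <= 0) stop("coverage must be positive")
  if (is.null(harbored_svs))
    harbored_svs <- data.frame(label = character(0), cell_fraction = numeric(0),
                               stringsAsFactors = FALSE)
  stopifnot(all(harbored_svs$cell_fraction >= 0 & harbored_svs$cell_fraction <= 1))
  structure(list(clone_id = clone_id, brain_id = brain_id,
                 harbored_svs = harbored_svs,
                 unique_snv_count = as.integer(unique_snv_count), mda = mda,
                 coverage = coverage, insert_mean = insert_mean,
                 insert_sd = insert_sd, read_length = as.integer(read_length),
                 error_rate = error_rate),
            class = "CloneSpec")
}

## ---- piece maps -------------------------------------------------------------
## A piece map is a data.frame(contig, ref_start, ref_end, strand) in alt
## order; alt coordinates are accumulated here.
finish_map <- function(map) {
  w <- map$ref_end - map$ref_start + 1L
  map$alt_end <- cumsum(w)
  map$alt_start <- map$alt_end - w + 1L
  map
}

identity_map <- function(contig, len) {
  finish_map(data.frame(contig = contig, ref_start = 1L, ref_end = len,
                        strand = "+", stringsAsFactors = FALSE))
}

## piece map for a contig carrying the given truth records (anchors sorted,
## non-overlapping)
sv_contig_map <- function(contig, len, truths) {
  truths <- truths[order(vapply(truths, `[[`, 0L, "anchor_pos"))]
  rows <- list(); cur <- 1L
  for (tr in truths) {
    a <- tr$anchor_pos; ds <- tr$deleted_span
    if (a <= cur) stop("overlapping SV anchors on ", contig)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = contig, ref_start = cur, ref_end = a - 1L, strand = "+",
      stringsAsFactors = FALSE)
    ch <- tr$chain
    for (i in seq_len(nrow(ch)))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ch$contig[i], ref_start = ch$start[i], ref_end = ch$end[i],
        strand = ch$strand[i], stringsAsFactors = FALSE)
    cur <- a + ds
  }
  rows[[length(rows) + 1L]] <- data.frame(
    contig = contig, ref_start = cur, ref_end = len, strand = "+",
    stringsAsFactors = FALSE)
  finish_map(do.call(rbind, rows))
}

## template sequence implied by a piece map over a set of source sequences
map_sequence <- function(seqs, map) {
  parts <- vapply(seq_len(nrow(map)), function(i) {
    s <- substr(seqs[[map$contig[i]]], map$ref_start[i], map$ref_end[i])
    if (map$strand[i] == "-") rc(s) else s
  }, "")
  paste0(parts, collapse = "")
}

## ---- projection -------------------------------------------------------------
## project fragment-end reads given by alt intervals [s, e] and natural strand
## (TRUE = forward on the template) through a piece map; seq supplied in
## template orientation. Returns a data.frame of projected records.
project_reads <- function(map, s, e, fwd, seqs_template) {
  n <- length(s)
  pi_s <- findInterval(s, map$alt_start)
  pi_e <- findInterval(e, map$alt_start)
  out <- data.frame(contig = character(n), pos = integer(n),
                    strand = character(n), mlen = integer(n),
                    clip_left = integer(n), clip_right = integer(n),
                    seq = character(n), stringsAsFactors = FALSE)
  ## fast path: read inside one piece
  inside <- which(pi_s == pi_e)
  if (length(inside)) {
    p <- pi_s[inside]
    plus <- map$strand[p] == "+"
    pos <- ifelse(plus,
                  map$ref_start[p] + (s[inside] - map$alt_start[p]),
                  map$ref_end[p] - (e[inside] - map$alt_start[p]))
    out$contig[inside] <- map$contig[p]
    out$pos[inside] <- as.integer(pos)
    out$mlen[inside] <- e[inside] - s[inside] + 1L
    natural <- ifelse(fwd[inside], "+", "-")
    flipped <- ifelse(fwd[inside], "-", "+")
    out$strand[inside] <- ifelse(plus, natural, flipped)
    sq <- substring(seqs_template, s[inside], e[inside])
    flip <- !plus
    if (any(flip)) sq[flip] <- rc(sq[flip])
    out$seq[inside] <- sq
  }
  ## crossing reads: anchor to the piece with the largest overlap
  for (i in which(pi_s != pi_e)) {
    idx <- pi_s[i]:pi_e[i]
    ov_s <- pmax(s[i], map$alt_start[idx])
    ov_e <- pmin(e[i], map$alt_end[idx])
    anchor <- idx[which.max(ov_e - ov_s)]
    ms <- max(s[i], map$alt_start[anchor])
    me <- min(e[i], map$alt_end[anchor])
    lclip <- ms - s[i]; rclip <- e[i] - me
    plus <- map$strand[anchor] == "+"
    pos <- if (plus) map$ref_start[anchor] + (ms - map$alt_start[anchor])
           else map$ref_end[anchor] - (me - map$alt_start[anchor])
    sq <- substr(seqs_template, s[i], e[i])
    if (!plus) sq <- rc(sq)
    out$contig[i] <- map$contig[anchor]
    out$pos[i] <- as.integer(pos)
    out$mlen[i] <- me - ms + 1L
    out$clip_left[i] <- if (plus) lclip else rclip
    out$clip_right[i] <- if (plus) rclip else lclip
    natural <- if (fwd[i]) "+" else "-"
    out$strand[i] <- if (plus) natural else if (natural == "+") "-" else "+"
    out$seq[i] <- sq
  }
  out
}

## generate n_pairs from one template (described by a piece map over source
## sequences) and project them. Returns the standard record data.frame.
simulate_pairs_from_map <- function(seqs, map, n_pairs, read_length,
                                    insert_mean, insert_sd, error_rate,
                                    sample_id, id_prefix, circular_len = NULL) {
  if (n_pairs == 0L) return(empty_records())
  tmpl <- map_sequence(seqs, map)
  tlen <- if (is.null(circular_len)) nchar(tmpl) else circular_len
  frag <- pmax(as.integer(round(rnorm(n_pairs, insert_mean, insert_sd))),
               read_length)
  frag <- pmin(frag, nchar(tmpl))
  ## circular templates: fragments may start anywhere on the circle and wrap
  ## into the doubled copy; linear templates stay within bounds
  span <- if (is.null(circular_len)) pmax(tlen - frag + 1L, 1L) else tlen
  start <- 1L + floor(runif(n_pairs) * span)
  start <- pmin(start, nchar(tmpl) - frag + 1L)
  r1s <- start; r1e <- start + read_length - 1L
  r2e <- start + frag - 1L; r2s <- r2e - read_length + 1L
  p1 <- project_reads(map, r1s, r1e, rep(TRUE, n_pairs), tmpl)
  p2 <- project_reads(map, r2s, r2e, rep(FALSE, n_pairs), tmpl)
  assemble_pair_records(p1, p2, sample_id, id_prefix, read_length,
                        insert_mean, insert_sd, error_rate)
}

empty_records <- function() {
  data.frame(sample = character(0), read_id = character(0), mate = integer(0),
             contig = character(0), pos = integer(0), strand = character(0),
             mlen = integer(0), clip_left = integer(0), clip_right = integer(0),
             seq = character(0), mate_contig = character(0),
             mate_pos = integer(0), isize = integer(0), proper = logical(0),
             mapq = integer(0), stringsAsFactors = FALSE)
}

assemble_pair_records <- function(p1, p2, sample_id, id_prefix, read_length,
                                  insert_mean, insert_sd, error_rate) {
  n <- nrow(p1)
  ids <- paste0(id_prefix, ":", seq_len(n))
  mk <- function(p, mate, q) {
    data.frame(sample = sample_id, read_id = ids, mate = mate,
               contig = p$contig, pos = p$pos, strand = p$strand,
               mlen = p$mlen, clip_left = p$clip_left,
               clip_right = p$clip_right, seq = p$seq,
               mate_contig = q$contig, mate_pos = q$pos,
               isize = NA_integer_, proper = FALSE, mapq = 60L,
               stringsAsFactors = FALSE)
  }
  r1 <- mk(p1, 1L, p2); r2 <- mk(p2, 2L, p1)
  same <- p1$contig == p2$contig
  lo <- pmin(p1$pos, p2$pos)
  hi <- pmax(p1$pos + p1$mlen - 1L, p2$pos + p2$mlen - 1L)
  isz <- ifelse(same, hi - lo + 1L, NA_integer_)
  r1$isize <- r2$isize <- as.integer(isz)
  full <- p1$clip_left + p1$clip_right + p2$clip_left + p2$clip_right == 0L
  fr <- p1$strand != p2$strand
  sane <- !is.na(isz) & isz >= read_length &
    isz <= insert_mean + 4 * insert_sd
  proper <- same & full & fr & sane
  r1$proper <- r2$proper <- proper
  recs <- rbind(r1, r2)
  apply_base_errors(recs, error_rate)
}

apply_base_errors <- function(recs, error_rate) {
  if (error_rate <= 0 || !nrow(recs)) return(recs)
  rl <- nchar(recs$seq)
  n_err <- rbinom(nrow(recs), rl, error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(rl[i], n_err[i])
    old <- str_at(recs$seq[i], pos)
    new <- vapply(old, function(b) sample(setdiff(BASES, b), 1L), "")
    recs$seq[i] <- str_assign(recs$seq[i], pos, new)
  }
  recs
}

#' CIGAR strings for simulated alignment records
#'
#' @param recs a record data.frame as returned by \code{simulate_clone_reads}.
#' @return character vector of CIGARs (soft clips + match run).
#' @export
record_cigar <- function(recs) {
  paste0(ifelse(recs$clip_left > 0, paste0(recs$clip_left, "S"), ""),
         recs$mlen, "M",
         ifelse(recs$clip_right > 0, paste0(recs$clip_right, "S"), ""))
}

## ---- clone simulation -------------------------------------------------------

#' Simulate reference-projected paired-end reads for a set of clones
#'
#' Each clone is diploid: haplotype 1 carries the germline heterozygous SNP
#' alternate alleles; haplotype 2 carries the clone-private somatic SNVs (in
#' every cell of the clone, allele fraction 0.5) and, in the fraction of
#' cells given by \code{cell_fraction}, the SV alleles the clone harbors.
#' Homozygous SNPs sit on both haplotypes. Junction-crossing reads are
#' soft-clipped at the junction; clip lengths equal the bases past it.
#'
#' @param ref an (implanted) \code{ReferenceGenome}.
#' @param clones list of \code{CloneSpec}.
#' @param truths named list of \code{TruthRecord} (names = labels) for the
#'   alleles referenced by the clones.
#' @param seed integer seed; fixed seed + fixed specs give identical output.
#' @return named list of per-clone record data.frames; each carries the
#'   clone's private-SNV positions in \code{attr(, "private_snvs")}.
#' @export
simulate_clone_reads <- function(ref, clones, truths = list(), seed = 1L) {
  set.seed(seed)
  out <- list()
  for (cl in clones) {
    out[[cl$clone_id]] <- simulate_one_clone(ref, cl, truths)
  }
  out
}

simulate_one_clone <- function(ref, cl, truths) {
  rl <- cl$read_length
  ## genome-wide haplotype sequences
  h1 <- h2 <- ref$contigs
  if (nrow(ref$hom_snps)) {
    for (cn in unique(ref$hom_snps$contig)) {
      s <- ref$hom_snps[ref$hom_snps$contig == cn, ]
      h1[[cn]] <- str_assign(h1[[cn]], s$pos, s$alt)
      h2[[cn]] <- str_assign(h2[[cn]], s$pos, s$alt)
    }
  }
  if (nrow(ref$het_snps)) {
    for (cn in unique(ref$het_snps$contig)) {
      s <- ref$het_snps[ref$het_snps$contig == cn, ]
      h1[[cn]] <- str_assign(h1[[cn]], s$pos, s$alt)
    }
  }
  ## clone-private SNVs on haplotype 2, outside SV spans
  my_truths <- truths[cl$harbored_svs$label]
  snvs <- place_private_snvs(ref, cl$unique_snv_count, my_truths)
  if (nrow(snvs)) {
    for (cn in unique(snvs$contig)) {
      s <- snvs[snvs$contig == cn, ]
      h2[[cn]] <- str_assign(h2[[cn]], s$pos, s$alt)
    }
  }

  recs <- list()
  for (cn in names(ref$contigs)) {
    L <- nchar(ref$contigs[[cn]])
    n_pairs <- as.integer(round(cl$coverage * L / (2 * rl)))
    if (n_pairs == 0L) next
    tr_here <- my_truths[vapply(my_truths, function(t) t$anchor_contig == cn, TRUE)]
    f <- 0
    if (length(tr_here)) {
      cf <- cl$harbored_svs$cell_fraction[match(
        vapply(tr_here, `[[`, "", "label"), cl$harbored_svs$label)]
      if (length(unique(cf)) > 1L)
        stop("SVs on one contig within a clone must share cell_fraction")
      f <- cf[1]
    }
    probs <- c(h1 = 0.5, h2sv = 0.5 * f, h2plain = 0.5 * (1 - f))
    counts <- as.vector(rmultinom(1L, n_pairs, probs))
    idmap <- identity_map(cn, L)
    pools <- list(
      list(map = idmap, seqs = h1, n = counts[1], tag = "h1"),
      list(map = if (length(tr_here)) sv_contig_map(cn, L, tr_here) else idmap,
           seqs = h2, n = counts[2], tag = "sv"),
      list(map = idmap, seqs = h2, n = counts[3], tag = "h2"))
    for (p in pools) {
      if (p$n == 0L) next
      recs[[length(recs) + 1L]] <- simulate_pairs_from_map(
        p$seqs, p$map, p$n, rl, cl$insert_mean, cl$insert_sd, cl$error_rate,
        cl$clone_id, paste(cl$clone_id, cn, p$tag, sep = "_"))
    }
  }
  res <- if (length(recs)) do.call(rbind, recs) else empty_records()
  rownames(res) <- NULL
  attr(res, "private_snvs") <- snvs
  attr(res, "clone") <- cl
  res
}

place_private_snvs <- function(ref, n, truths) {
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  lens <- nchar(ref$contigs)
  ## exclusion: SV anchor spans and chain segments, padded
  excl <- list()
  for (tr in truths) {
    excl[[length(excl) + 1L]] <- data.frame(
      contig = tr$anchor_contig,
      start = tr$anchor_pos - 500L,
      end = tr$anchor_pos + tr$deleted_span + 500L)
    ch <- tr$chain
    for (i in seq_len(nrow(ch)))
      excl[[length(excl) + 1L]] <- data.frame(
        contig = ch$contig[i], start = ch$start[i] - 500L,
        end = ch$end[i] + 500L)
  }
  excl <- if (length(excl)) do.call(rbind, excl) else NULL
  picked <- 0L; rows <- list(); guard <- 0L
  while (picked < n && guard < 50L) {
    guard <- guard + 1L
    cn <- sample(names(lens), 1L, prob = lens)
    pos <- sample.int(lens[[cn]] - 200L, 1L) + 100L
    if (!is.null(excl) &&
        any(excl$contig == cn & pos >= excl$start & pos <= excl$end)) next
    rb <- str_at(ref$contigs[[cn]], pos)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = cn, pos = pos, ref = rb,
      alt = sample(setdiff(BASES, rb), 1L), stringsAsFactors = FALSE)
    picked <- picked + 1L
    guard <- 0L
  }
  if (!length(rows)) return(empty)
  unique(do.call(rbind, rows))
}

#' Inject MDA chimera artifact reads
#'
#' Emulates the most frequent chimeric artifact of multiple displacement
#' amplification: a fold-back junction producing a one-sided inverted
#' breakend, adjacent (< 1000 bp) to a short duplicated span, with no
#' consistent reciprocal partner. Artifacts go into one sample only and are
#' absent from any truth file.
#'
#' @param ref a \code{ReferenceGenome}.
#' @param rate expected artifact loci per megabase of genome (0 = none).
#' @param seed integer seed.
#' @param sample_id sample receiving the artifacts.
#' @param depth read coverage over each artifact template.
#' @param read_length,insert_mean,insert_sd,error_rate sequencing parameters.
#' @return record data.frame; artifact loci in \code{attr(, "artifact_loci")}.
#' @export
simulate_mda_chimeras <- function(ref, rate, seed = 1L, sample_id = "mda",
                                  depth = 25, read_length = 150L,
                                  insert_mean = 400, insert_sd = 50,
                                  error_rate = 0.001) {
  if (rate < 0) stop("rate must be >= 0")
  set.seed(seed)
  glen <- genome_length(ref)
  n_loci <- rpois(1L, rate * glen / 1e6)
  loci <- data.frame(contig = character(0), inv_pos = integer(0),
                     dup_start = integer(0), dup_end = integer(0),
                     stringsAsFactors = FALSE)
  if (n_loci == 0L)
    return(structure(empty_records(), artifact_loci = loci))
  recs <- list()
  lens <- nchar(ref$contigs)
  for (i in seq_len(n_loci)) {
    cn <- sample(names(lens), 1L, prob = lens)
    L <- lens[[cn]]
    P <- sample.int(L - 6000L, 1L) + 3000L
    delta <- sample(5:60, 1L)
    ## fold-back template: forward approach then inverted re-priming
    fb_map <- finish_map(data.frame(
      contig = cn, ref_start = c(P - 900L, P - 700L), ref_end = c(P, P - delta),
      strand = c("+", "-"), stringsAsFactors = FALSE))
    ## adjacent short duplication: tandem repeat of [Q1, Q2]
    gap <- sample(100:800, 1L)
    dlen <- sample(80:300, 1L)
    Q2 <- P - gap; Q1 <- Q2 - dlen + 1L
    dup_map <- finish_map(data.frame(
      contig = cn, ref_start = c(Q1 - 600L, Q1, Q1),
      ref_end = c(Q2, Q2, Q2 + 600L),
      strand = "+", stringsAsFactors = FALSE))
    np <- function(map) {
      tlen <- sum(map$ref_end - map$ref_start + 1L)
      as.integer(round(depth * tlen / (2 * read_length)))
    }
    recs[[length(recs) + 1L]] <- simulate_pairs_from_map(
      ref$contigs, fb_map, np(fb_map), read_length, insert_mean, insert_sd,
      error_rate, sample_id, paste0("mdafb", i))
    recs[[length(recs) + 1L]] <- simulate_pairs_from_map(
      ref$contigs, dup_map, np(dup_map), read_length, insert_mean, insert_sd,
      error_rate, sample_id, paste0("mdadup", i))
    loci <- rbind(loci, data.frame(contig = cn, inv_pos = P, dup_start = Q1,
                                   dup_end = Q2, stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, recs)
  rownames(res) <- NULL
  structure(res, artifact_loci = loci)
}

#' Simulate reads from an excised circular DNA
#'
#' Emits read pairs from an extrachromosomal circle corresponding to the
#' reference span [start, end]: coverage is uniform over the circle and pairs
#' crossing the circle junction project as a duplication-like junction
#' (right clip at \code{end} joining back to \code{start}), reciprocal to the
#' deletion left on the chromosome.
#'
#' @param ref a \code{ReferenceGenome}.
#' @param contig,start,end circle span (1-based inclusive).
#' @param coverage mean depth over the circle.
#' @param sample_id sample label.
#' @param seed integer seed.
#' @param read_length,insert_mean,insert_sd,error_rate sequencing parameters.
#' @return record data.frame.
#' @export
simulate_eccdna_reads <- function(ref, contig, start, end, coverage = 30,
                                  sample_id = "cell1", seed = 1L,
                                  read_length = 150L, insert_mean = 400,
                                  insert_sd = 50, error_rate = 0.001) {
  set.seed(seed)
  clen <- end - start + 1L
  ## doubled template so fragments can wrap around the junction
  map <- finish_map(data.frame(contig = contig, ref_start = start,
                               ref_end = end, strand = "+",
                               stringsAsFactors = FALSE)[c(1, 1), ])
  n_pairs <- as.integer(round(coverage * clen / (2 * read_length)))
  simulate_pairs_from_map(ref$contigs, map, n_pairs, read_length, insert_mean,
                          insert_sd, error_rate, sample_id,
                          paste0(sample_id, "_ecc"), circular_len = clen)
}
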
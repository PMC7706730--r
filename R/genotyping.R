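# Pseudoreference genotyping: the assembled alternate allele is flanked by
# reference sequence and every sample's reads are re-mapped to it; only
# uniquely mapping reads crossing an allele-diagnostic position count, so a
# carrier shows the SV at ~50% allele fraction and a zero-count sample gets
# an extrapolated allele-fraction upper bound.

#' Build a pseudoreference for one resolved SV
#'
#' Concatenates reference flanks around the anchor to the alternate-allele
#' contig. Homozygous SNPs in the flanks (panel alternate-allele frequency
#' at least 0.9 across clones) are reverted to the reference base so that
#' reads do not map to the SV allele merely because of shared homozygous
#' differences from the reference; heterozygous sites are left untouched.
#'
#' @param model a \code{RearrangementModel} (or any chain data.frame in its
#'   \code{chain} slot; flank pieces first/last).
#' @param ref a \code{ReferenceGenome}.
#' @param config a \code{\link{pipeline_config}} (flank length).
#' @param snp_panel optional data.frame(contig, pos, ref, alt, hom_fraction):
#'   sites with \code{hom_fraction >= 0.9} are reverted. Defaults to the
#'   genome's own homozygous SNP table.
#' @return a \code{PseudoReference}: list(sequence, ref_sequence, junctions
#'   (ALT-diagnostic positions), anchor (contig/start/end of the replaced
#'   span), flank, reverted_sites).
#' @export
build_pseudoreference <- function(model, ref, config = pipeline_config(),
                                  snp_panel = NULL) {
  chain <- model$chain
  if (is.null(chain) || !nrow(chain)) stop("empty model chain")
  n <- nrow(chain)
  c0 <- chain$contig[1]
  flank <- config$flank
  rep_start <- model$replaced_span["start"]
  rep_end <- model$replaced_span["end"]
  L <- nchar(ref$contigs[[c0]])
  lf_start <- max(1L, rep_start - flank)
  rf_end <- min(L, rep_end + flank)
  ## trim the walk flanks to the requested flank width
  chain$start[1] <- lf_start
  chain$end[n] <- rf_end
  alt_map <- finish_map(data.frame(contig = chain$contig,
                                   ref_start = chain$start,
                                   ref_end = chain$end, strand = chain$strand,
                                   stringsAsFactors = FALSE))
  sequence <- map_sequence(ref$contigs, alt_map)
  ## reference-allele twin: flanks plus the replaced span
  ref_sequence <- substr(ref$contigs[[c0]], lf_start, rf_end)
  ## ALT-diagnostic positions: junction coordinates in pseudoreference space
  junctions <- alt_map$alt_end[-nrow(alt_map)]
  ## revert homozygous SNPs in the flank pieces
  if (is.null(snp_panel)) {
    snp_panel <- ref$hom_snps
    if (nrow(snp_panel)) snp_panel$hom_fraction <- 1.0
  }
  reverted <- data.frame(contig = character(0), pos = integer(0),
                         pseudo_pos = integer(0), stringsAsFactors = FALSE)
  if (!is.null(snp_panel) && nrow(snp_panel)) {
    hom <- snp_panel[snp_panel$hom_fraction >= 0.9, , drop = FALSE]
    for (i in seq_len(nrow(hom))) {
      hit <- which(alt_map$contig == hom$contig[i] &
                     alt_map$ref_start <= hom$pos[i] &
                     alt_map$ref_end >= hom$pos[i])
      for (p in hit) {
        off <- if (alt_map$strand[p] == "+") hom$pos[i] - alt_map$ref_start[p]
               else alt_map$ref_end[p] - hom$pos[i]
        ppos <- alt_map$alt_start[p] + off
        b <- hom$ref[i]
        if (alt_map$strand[p] == "-") b <- chartr("ACGT", "TGCA", b)
        sequence <- str_assign(sequence, ppos, b)
        reverted <- rbind(reverted, data.frame(
          contig = hom$contig[i], pos = hom$pos[i], pseudo_pos = ppos,
          stringsAsFactors = FALSE))
      }
      ## and in the reference twin
      if (hom$contig[i] == c0 && hom$pos[i] >= lf_start && hom$pos[i] <= rf_end)
        ref_sequence <- str_assign(ref_sequence, hom$pos[i] - lf_start + 1L,
                                   hom$ref[i])
    }
  }
  ## competitor targets: the reference context of every donor locus, so a
  ## plain read from a segment's home region never counts as unique to the
  ## SV allele (the whole-genome side of "uniquely mapped")
  competitors <- character(0)
  if (n > 2L) {
    inner <- chain[-c(1L, n), , drop = FALSE]
    competitors <- vapply(seq_len(nrow(inner)), function(i) {
      Lc <- nchar(ref$contigs[[inner$contig[i]]])
      substr(ref$contigs[[inner$contig[i]]],
             max(1L, inner$start[i] - flank),
             min(Lc, inner$end[i] + flank))
    }, "")
  }
  structure(list(sequence = sequence, ref_sequence = ref_sequence,
                 junctions = junctions, chain = chain,
                 competitors = competitors,
                 anchor = list(contig = c0, start = rep_start, end = rep_end,
                               flank_start = lf_start, flank_end = rf_end),
                 flank = flank, reverted_sites = reverted),
            class = "PseudoReference")
}

## best end-to-end ungapped match score of a read in a target; returns
## list(score, start) with score = matches - mismatches, or score -Inf.
best_ungapped_hit <- function(read, target, anchors = c(1L, 61L, 121L)) {
  L <- nchar(read)
  best <- -Inf; at <- NA_integer_
  anchors <- unique(pmin(pmax(anchors, 1L), max(L - 19L, 1L)))
  tried <- integer(0)
  for (astart in anchors) {
    a <- substr(read, astart, min(astart + 19L, L))
    hits <- gregexpr(a, target, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (p in hits) {
      off <- p - astart
      if (off < 0L || off + L > nchar(target)) next
      if (off %in% tried) next
      tried <- c(tried, off)
      mm <- str_mismatches(read, substr(target, off + 1L, off + L))
      sc <- (L - mm) - mm
      if (sc > best) { best <- sc; at <- off + 1L }
    }
  }
  list(score = best, start = at)
}

#' Count uniquely mapping allele-diagnostic reads
#'
#' A read supports the ALT allele iff its best alignment to the
#' pseudoreference beats its best alignment to the reference allele by at
#' least \code{map_margin} score units and crosses an ALT-diagnostic
#' position (a junction of the allele); REF-diagnostic reads mirror this
#' across the replaced span. Reads fitting both alleles equally (flank
#' reads) count for neither.
#'
#' @param reads character vector of read sequences.
#' @param pseudo a \code{PseudoReference}.
#' @param config a \code{\link{pipeline_config}}.
#' @return list(alt, ref): unique diagnostic read counts.
#' @export
map_reads_unique <- function(reads, pseudo, config = pipeline_config()) {
  margin <- config$map_margin
  alt_n <- 0L; ref_n <- 0L
  ## REF-diagnostic positions: the replaced-span edges in ref_sequence space
  ref_bnd <- c(pseudo$anchor$start, pseudo$anchor$end + 1L) -
    pseudo$anchor$flank_start + 1L
  comp <- pseudo$competitors
  ## best score per target across both read orientations, then one margin
  ## comparison; orientation-wise comparison would let a weak hit win when
  ## the true home locus matches in the other orientation
  best2 <- function(seqs, target) {
    out <- list(score = -Inf, start = NA_integer_)
    for (sq in seqs) {
      h <- best_ungapped_hit(sq, target)
      if (is.finite(h$score) && h$score > out$score) out <- h
    }
    out
  }
  for (rd in reads) {
    seqs <- c(rd, rc(rd))
    L <- nchar(rd)
    ha <- best2(seqs, pseudo$sequence)
    hr <- best2(seqs, pseudo$ref_sequence)
    hc <- -L
    for (cmp in comp) {
      s <- best2(seqs, cmp)$score
      if (is.finite(s) && s > hc) hc <- s
    }
    if (is.finite(ha$score) &&
        ha$score - max(hr$score, hc, -L) >= margin) {
      span <- c(ha$start, ha$start + L - 1L)
      if (any(pseudo$junctions >= span[1] & pseudo$junctions < span[2]))
        alt_n <- alt_n + 1L
    } else if (is.finite(hr$score) &&
               hr$score - max(ha$score, hc, -L) >= margin) {
      span <- c(hr$start, hr$start + L - 1L)
      if (any(ref_bnd > span[1] & ref_bnd <= span[2]))
        ref_n <- ref_n + 1L
    }
  }
  list(alt = alt_n, ref = ref_n)
}

#' Allele-fraction upper bound from assay capacity
#'
#' In a true carrier the ALT-diagnostic read count corresponds to ~50%
#' allele frequency; extrapolating to a single supporting read gives the
#' largest allele fraction consistent with observing zero reads.
#'
#' @param unique_read_capacity_N ALT-diagnostic read count observed in a
#'   true carrier (the assay's capacity); must be >= 1.
#' @return upper bound as a fraction (0.5 / N).
#' @examples
#' af_upper_bound(167)   # 0.003, i.e. < 0.3%
#' @export
af_upper_bound <- function(unique_read_capacity_N) {
  if (any(unique_read_capacity_N < 1)) stop("no assay capacity (N = 0)")
  0.5 / unique_read_capacity_N
}

#' Genotype an SV across samples on its pseudoreference
#'
#' The allele fraction is rate-normalized: a complex allele offers one
#' diagnostic window per junction while the reference allele offers only
#' its replaced-span edges, so raw read counts are divided by the width of
#' each allele's union of diagnostic windows before forming the fraction
#' (a clonal heterozygous carrier then sits at ~0.5 regardless of the
#' allele's junction count).
#'
#' @param sample_records named list of alignment record data.frames.
#' @param pseudo a \code{PseudoReference}.
#' @param config a \code{\link{pipeline_config}}.
#' @return GenotypeResult data.frame: sample, unique_alt_reads,
#'   unique_ref_reads, w_alt, w_ref (diagnostic window widths),
#'   allele_fraction, present, af_upper_bound (attached to absent samples,
#'   from the carrier capacity).
#' @export
genotype_all <- function(sample_records, pseudo,
                         config = pipeline_config()) {
  anc <- pseudo$anchor
  ## only junction-informative reads can be diagnostic: soft-clipped reads
  ## near any breakend locus (allele junctions project to the anchor edges
  ## and the donor-segment edges) plus full-length reads spanning the
  ## replaced-span edges (the REF-diagnostic positions)
  ch <- pseudo$chain
  n <- nrow(ch)
  edge_rows <- list(
    data.frame(contig = anc$contig, pos = c(anc$start - 1L, anc$end + 1L),
               stringsAsFactors = FALSE))
  if (n > 2L) {
    inner <- ch[-c(1L, n), , drop = FALSE]
    edge_rows[[2L]] <- data.frame(
      contig = rep(inner$contig, 2L), pos = c(inner$start, inner$end),
      stringsAsFactors = FALSE)
  }
  edges <- unique(do.call(rbind, edge_rows))
  res <- lapply(names(sample_records), function(sid) {
    recs <- sample_records[[sid]]
    keep <- rep(FALSE, nrow(recs))
    for (i in seq_len(nrow(edges))) {
      w <- recs$contig == edges$contig[i] &
        recs$pos <= edges$pos[i] + 400L &
        (recs$pos + recs$mlen) >= edges$pos[i] - 400L
      keep <- keep | w
    }
    cnt <- map_reads_unique(recs$seq[keep], pseudo, config)
    rl <- if (nrow(recs)) as.integer(stats::median(nchar(recs$seq))) else 150L
    w_alt <- diagnostic_window_width(pseudo$junctions, rl)
    w_ref <- diagnostic_window_width(
      c(anc$start - 1L, anc$end) - anc$flank_start + 1L, rl)
    af <- if (cnt$alt + cnt$ref > 0) {
      (cnt$alt / w_alt) / (cnt$alt / w_alt + cnt$ref / w_ref)
    } else NA_real_
    data.frame(sample = sid, unique_alt_reads = cnt$alt,
               unique_ref_reads = cnt$ref, w_alt = w_alt, w_ref = w_ref,
               allele_fraction = af, present = cnt$alt > 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  capacity <- max(out$unique_alt_reads)
  out$af_upper_bound <- ifelse(out$present, NA_real_,
                               if (capacity >= 1L) af_upper_bound(capacity)
                               else NA_real_)
  out
}

## width of the union of read-start windows from which a read of length rl
## crosses at least one of the given junction coordinates with 3 bases to
## spare on each side
diagnostic_window_width <- function(junctions, rl) {
  if (!length(junctions)) return(1L)
  iv <- IRanges::reduce(IRanges::IRanges(junctions + 4L - rl,
                                         junctions - 2L))
  max(sum(IRanges::width(iv)), 1L)
}

#' Classify a call as clonal or subclonal
#'
#' Subclonal iff the allele fraction is significantly below 0.5 (one-sided
#' exact binomial test at alpha = 0.01), or any heterozygous SNP inside the
#' deleted region still shows both alleles in the carrier's reads
#' (heterozygous sites indicate two surviving haplotypes, while a clonal
#' deletion leaves only one).
#'
#' @param genotype one row of \code{\link{genotype_all}} for the carrier.
#' @param records the carrier clone's alignment records.
#' @param deleted_regions data.frame(contig, start, end) of the model's
#'   deletions (may be empty).
#' @param het_snps data.frame(contig, pos, ref, alt) heterozygous sites.
#' @param alpha significance level of the binomial test.
#' @return list(clonality = "clonal"|"subclonal", af_p_value,
#'   het_sites_both_alleles).
#' @export
classify_clonality <- function(genotype, records, deleted_regions = NULL,
                               het_snps = NULL, alpha = 0.01) {
  n <- genotype$unique_alt_reads + genotype$unique_ref_reads
  ## expected ALT share of diagnostic reads for a clonal het carrier,
  ## corrected for unequal diagnostic-window widths when known
  p0 <- if (all(c("w_alt", "w_ref") %in% names(genotype))) {
    genotype$w_alt / (genotype$w_alt + genotype$w_ref)
  } else 0.5
  p <- stats::binom.test(genotype$unique_alt_reads, n, p = p0,
                         alternative = "less")$p.value
  both <- 0L
  if (!is.null(deleted_regions) && nrow(deleted_regions) &&
      !is.null(het_snps) && nrow(het_snps)) {
    for (i in seq_len(nrow(deleted_regions))) {
      dr <- deleted_regions[i, ]
      sites <- het_snps[het_snps$contig == dr$contig & het_snps$pos >= dr$start &
                          het_snps$pos <= dr$end, , drop = FALSE]
      for (j in seq_len(nrow(sites))) {
        bases <- read_bases_at(records, sites$contig[j], sites$pos[j])
        if (sum(bases == sites$ref[j]) >= 2L && sum(bases == sites$alt[j]) >= 2L)
          both <- both + 1L
      }
    }
  }
  list(clonality = if (p < alpha || both > 0L) "subclonal" else "clonal",
       af_p_value = p, het_sites_both_alleles = both)
}

## bases observed at a reference position from fully matched read segments
read_bases_at <- function(records, contig, pos) {
  r <- records[records$contig == contig & records$clip_left == 0L &
                 records$clip_right == 0L &
                 records$pos <= pos & (records$pos + records$mlen - 1L) >= pos,
               , drop = FALSE]
  if (!nrow(r)) return(character(0))
  str_at_vec(r$seq, pos - r$pos + 1L)
}

str_at_vec <- function(seqs, pos) {
  vapply(seq_along(seqs), function(i) substr(seqs[i], pos[i], pos[i]), "")
}
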
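# Truth-file round trip: VCF 4.2 with breakend (BND) notation plus a BED of
# replaced reference spans. The VCF additionally serializes the allele
# composition (anchor, deleted span, segment chain, microhomologies,
# carriers) in INFO so the reader reconstructs TruthRecords losslessly.

bnd_alt <- function(side_here, partner_contig, partner_pos, side_partner) {
  loc <- paste0(partner_contig, ":", partner_pos)
  if (side_here == "R" && side_partner == "L") paste0("N[", loc, "[")
  else if (side_here == "R" && side_partner == "R") paste0("N]", loc, "]")
  else if (side_here == "L" && side_partner == "L") paste0("[", loc, "[N")
  else paste0("]", loc, "]N")
}

## junction side on the reference: a donor on "+" ends rightward (R); a donor
## on "-" attaches left of its position (L); acceptor mirrors.
junction_sides <- function(bp_row) {
  list(donor = if (bp_row$strandA == "+") "R" else "L",
       acceptor = if (bp_row$strandB == "+") "L" else "R")
}

#' Write truth records as a BND VCF plus a BED of replaced spans
#'
#' @param truths list of \code{TruthRecord}.
#' @param vcf_path output VCF path.
#' @param bed_path output BED path (0-based half-open spans; NULL to skip).
#' @param ref optional \code{ReferenceGenome} for contig headers.
#' @return \code{vcf_path}, invisibly.
#' @export
write_truth <- function(truths, vcf_path, bed_path = NULL, ref = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=clonesv",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate breakend">',
           '##INFO=<ID=EVENT,Number=1,Type=String,Description="Allele label">',
           '##INFO=<ID=JUNC,Number=1,Type=Integer,Description="Junction index">',
           '##INFO=<ID=MHLEN,Number=1,Type=Integer,Description="Junction microhomology length">',
           '##INFO=<ID=ANCHOR,Number=1,Type=String,Description="Anchor contig:pos">',
           '##INFO=<ID=DELSPAN,Number=1,Type=Integer,Description="Replaced reference span">',
           '##INFO=<ID=CHAIN,Number=1,Type=String,Description="Segment chain contig:start-end:strand|...">',
           '##INFO=<ID=MHS,Number=1,Type=String,Description="Requested microhomology per junction">',
           '##INFO=<ID=CARRIERS,Number=1,Type=String,Description="Carrier clones">',
           '##INFO=<ID=SVSIZE,Number=1,Type=Integer,Description="Absolute size |ref - alt|">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
           '##ALT=<ID=DEL,Description="Deletion">')
  if (!is.null(ref))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(ref$contigs),
                          nchar(ref$contigs)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  lines <- character(0)
  for (tr in truths) {
    chain_str <- if (nrow(tr$chain) == 0L) "." else paste(
      sprintf("%s:%d-%d:%s", tr$chain$contig, tr$chain$start, tr$chain$end,
              tr$chain$strand), collapse = "|")
    carriers <- if (length(tr$carriers)) paste(tr$carriers, collapse = "|") else "."
    common <- sprintf("EVENT=%s;ANCHOR=%s:%d;DELSPAN=%d;CHAIN=%s;MHS=%s;CARRIERS=%s;SVSIZE=%d",
                      tr$label, tr$anchor_contig, tr$anchor_pos, tr$deleted_span,
                      chain_str, paste(tr$junction_mh, collapse = ","),
                      carriers, tr$absolute_size)
    bp <- tr$breakpoints
    for (j in seq_len(nrow(bp))) {
      sides <- junction_sides(bp[j, ])
      id_d <- sprintf("%s_j%d_d", tr$label, j)
      id_a <- sprintf("%s_j%d_a", tr$label, j)
      info_d <- sprintf("SVTYPE=BND;MATEID=%s;JUNC=%d;MHLEN=%d",
                        id_a, j, tr$junction_mh[j])
      if (j == 1L) info_d <- paste(info_d, common, sep = ";")
      lines <- c(lines,
        paste(bp$contigA[j], bp$posA[j], id_d, "N",
              bnd_alt(sides$donor, bp$contigB[j], bp$posB[j], sides$acceptor),
              ".", "PASS", info_d, sep = "\t"),
        paste(bp$contigB[j], bp$posB[j], id_a, "N",
              bnd_alt(sides$acceptor, bp$contigA[j], bp$posA[j], sides$donor),
              ".", "PASS",
              sprintf("SVTYPE=BND;MATEID=%s;JUNC=%d;MHLEN=%d", id_d, j,
                      tr$junction_mh[j]), sep = "\t"))
    }
    ## symbolic twin for pure deletions
    if (nrow(tr$chain) == 0L && tr$deleted_span > 0L) {
      lines <- c(lines, paste(
        tr$anchor_contig, tr$anchor_pos - 1L, paste0(tr$label, "_sym"), "N",
        "<DEL>", ".", "PASS",
        sprintf("SVTYPE=DEL;EVENT=%s;END=%d", tr$label,
                tr$anchor_pos + tr$deleted_span - 1L), sep = "\t"))
    }
  }
  writeLines(c(hdr, lines), vcf_path)
  if (!is.null(bed_path)) {
    bed <- vapply(truths, function(tr) {
      paste(tr$anchor_contig, tr$anchor_pos - 1L,
            tr$anchor_pos + tr$deleted_span - 1L, tr$label, sep = "\t")
    }, "")
    writeLines(bed, bed_path)
  }
  invisible(vcf_path)
}

#' Write discovered SV calls as a VCF
#'
#' Spanned calls (DEL/DUP/INV) are written with symbolic ALT alleles and
#' END/SVLEN; breakends as BND records (one line per known end).
#'
#' @param calls SvCall data.frame (from \code{\link{pair_and_type}} or the
#'   downstream filters).
#' @param path output VCF path.
#' @param ref optional \code{ReferenceGenome} for contig headers.
#' @return \code{path}, invisibly.
#' @export
write_calls_vcf <- function(calls, path, ref = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=clonesv",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
           '##INFO=<ID=SAMPLE,Number=1,Type=String,Description="Sample">',
           '##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description="Split-read support">',
           '##ALT=<ID=DEL,Description="Deletion">',
           '##ALT=<ID=DUP,Description="Duplication">',
           '##ALT=<ID=INV,Description="Inversion">')
  if (!is.null(ref))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(ref$contigs),
                          nchar(ref$contigs)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  lines <- character(0)
  for (i in seq_len(nrow(calls))) {
    id <- sprintf("call%d", i)
    common <- sprintf("SAMPLE=%s;SUPPORT=%d", calls$sample[i],
                      calls$split_support[i])
    if (calls$type[i] %in% c("DEL", "DUP", "INV") && !is.na(calls$start[i])) {
      lines <- c(lines, paste(
        calls$contig[i], max(calls$start[i] - 1L, 1L), id, "N",
        paste0("<", calls$type[i], ">"), ".", "PASS",
        sprintf("SVTYPE=%s;END=%d;SVLEN=%d;%s", calls$type[i], calls$end[i],
                (calls$end[i] - calls$start[i] + 1L) *
                  if (calls$type[i] == "DEL") -1L else 1L, common),
        sep = "\t"))
    } else {
      alt <- if (!is.na(calls$bp2[i]) && !is.na(calls$contig2[i])) {
        sides <- junction_sides(data.frame(
          strandA = calls$strand1[i],
          strandB = ifelse(is.na(calls$strand2[i]), "+", calls$strand2[i])))
        bnd_alt(sides$donor, calls$contig2[i], calls$bp2[i], sides$acceptor)
      } else "N."
      lines <- c(lines, paste(
        calls$contig[i], calls$bp1[i], id, "N", alt, ".", "PASS",
        sprintf("SVTYPE=BND;%s", common), sep = "\t"))
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read truth records back from a truth VCF
#'
#' @param vcf_path path written by \code{\link{write_truth}}.
#' @return list of \code{TruthRecord}.
#' @export
read_truth <- function(vcf_path) {
  ln <- readLines(vcf_path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln)) return(list())
  fields <- strsplit(ln, "\t", fixed = TRUE)
  info <- vapply(fields, `[[`, "", 8L)
  get <- function(inf, key) {
    m <- regmatches(inf, regexec(paste0("(?:^|;)", key, "=([^;]*)"), inf))[[1]]
    if (length(m) < 2L) NA_character_ else m[2]
  }
  ## anchor lines are the j1 donor records carrying the composition
  anchor_idx <- which(grepl("ANCHOR=", info, fixed = TRUE))
  out <- list()
  for (i in anchor_idx) {
    inf <- info[i]
    label <- get(inf, "EVENT")
    anc <- strsplit(get(inf, "ANCHOR"), ":", fixed = TRUE)[[1]]
    ds <- as.integer(get(inf, "DELSPAN"))
    chain_str <- get(inf, "CHAIN")
    chain <- if (identical(chain_str, ".")) {
      data.frame(contig = character(0), start = integer(0), end = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(strsplit(chain_str, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
      se <- lapply(parts, function(p) as.integer(strsplit(p[2], "-", fixed = TRUE)[[1]]))
      data.frame(contig = vapply(parts, `[[`, "", 1L),
                 start = vapply(se, `[[`, 0L, 1L),
                 end = vapply(se, `[[`, 0L, 2L),
                 strand = vapply(parts, `[[`, "", 3L),
                 stringsAsFactors = FALSE)
    }
    mhs <- as.integer(strsplit(get(inf, "MHS"), ",", fixed = TRUE)[[1]])
    carriers_str <- get(inf, "CARRIERS")
    carriers <- if (identical(carriers_str, ".")) character(0) else
      strsplit(carriers_str, "|", fixed = TRUE)[[1]]
    spec <- alt_allele_spec(label, anc[1], as.integer(anc[2]), ds, chain, mhs)
    tr <- truth_from_spec(spec)
    tr$carriers <- carriers
    out[[label]] <- tr
  }
  out
}

## rebuild a TruthRecord from a spec without editing any reference
## (breakpoints and event arithmetic are functions of the allele description alone)
truth_from_spec <- function(spec) {
  juncs <- spec_junctions(spec)
  bp <- do.call(rbind, lapply(juncs, function(jn) {
    data.frame(contigA = jn$donor$contig, posA = piece_oriented_end(jn$donor),
               strandA = jn$donor$strand, contigB = jn$acceptor$contig,
               posB = piece_oriented_start(jn$acceptor),
               strandB = jn$acceptor$strand, stringsAsFactors = FALSE)
  }))
  bp$posB[nrow(bp)] <- spec$anchor_pos + spec$deleted_span
  events <- spec_truth_events(spec)
  alt_len <- if (nrow(spec$chain)) sum(spec$chain$end - spec$chain$start + 1L) else 0L
  structure(list(label = spec$label, anchor_contig = spec$anchor_contig,
                 anchor_pos = spec$anchor_pos, deleted_span = spec$deleted_span,
                 chain = spec$chain, breakpoints = bp, events = events,
                 classes = sort(events$type),
                 absolute_size = abs(spec$deleted_span - alt_len),
                 junction_mh = spec$junction_mh, carriers = character(0)),
            class = "TruthRecord")
}
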
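# Alternate-allele specification and implantation.
#
# An AltAlleleSpec describes a (possibly complex) SV allele as an ordered
# chain of oriented reference segments replacing a reference span at an
# anchor point. Implantation edits the reference so that every junction
# carries exactly the requested microhomology, then records exact truth
# breakpoints. This is the common language of the simulator and resolver.

#' Describe a complex SV allele
#'
#' @param label identifier for the allele.
#' @param anchor_contig,anchor_pos insertion point: \code{anchor_pos} is the
#'   first reference base removed (1-based); with \code{deleted_span = 0} the
#'   chain is inserted before \code{anchor_pos}.
#' @param deleted_span number of reference bases removed at the anchor (>= 0).
#' @param chain data.frame with columns contig, start, end, strand
#'   (1-based inclusive; strand "+" or "-") listing the oriented reference
#'   segments composing the alternate sequence, in order. May be empty
#'   (pure deletion); segments may repeat and may come from any contig.
#' @param junction_mh integer vector of requested microhomology lengths, one
#'   per junction: \code{nrow(chain) + 1} values (chain junctions plus the two
#'   anchor junctions collapse to one for an empty chain).
#' @return an object of class \code{AltAlleleSpec}.
#' @export
alt_allele_spec <- function(label, anchor_contig, anchor_pos, deleted_span,
                            chain = NULL, junction_mh = NULL) {
  if (is.null(chain) || nrow(chain) == 0L) {
    chain <- data.frame(contig = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
  }
  if (is.null(junction_mh)) junction_mh <- rep(0L, nrow(chain) + 1L)
  if (length(junction_mh) != nrow(chain) + 1L)
    stop("junction_mh must have length nrow(chain) + 1")
  if (any(junction_mh < 0)) stop("microhomology lengths must be >= 0")
  if (deleted_span < 0) stop("deleted_span must be >= 0")
  if (nrow(chain)) {
    stopifnot(all(chain$strand %in% c("+", "-")), all(chain$start <= chain$end))
  }
  structure(list(label = label, anchor_contig = anchor_contig,
                 anchor_pos = as.integer(anchor_pos),
                 deleted_span = as.integer(deleted_span),
                 chain = chain, junction_mh = as.integer(junction_mh)),
            class = "AltAlleleSpec")
}

## oriented end / flank helpers ------------------------------------------------
## A "piece" is list(contig, start, end, strand). Oriented start of "+" is
## start (upstream flank grows toward lower coords); of "-" it is end.

piece_len <- function(p) p$end - p$start + 1L

## oriented last base position and first base position on the reference
piece_oriented_end   <- function(p) if (p$strand == "+") p$end else p$start
piece_oriented_start <- function(p) if (p$strand == "+") p$start else p$end

## reference positions of the m bases immediately upstream of the piece's
## oriented start, ordered from the junction outward (distance 1, 2, ...)
upstream_flank_pos <- function(p, m) {
  if (p$strand == "+") p$start - seq_len(m) else p$end + seq_len(m)
}

## reference positions of the m bases immediately downstream of the piece's
## oriented end, ordered from the junction outward
downstream_flank_pos <- function(p, m) {
  if (p$strand == "+") p$end + seq_len(m) else p$start - seq_len(m)
}

## base in piece orientation at a reference position
oriented_base <- function(ref, contig, pos, strand) {
  b <- str_at(ref$contigs[[contig]], pos)
  if (strand == "-") chartr("ACGT", "TGCA", b) else b
}

## the junctions of a spec: list of (donor piece, acceptor piece)
spec_junctions <- function(spec) {
  a <- spec$anchor_pos; ds <- spec$deleted_span
  lflank <- list(contig = spec$anchor_contig, start = 1L, end = a - 1L, strand = "+")
  rflank <- list(contig = spec$anchor_contig, start = a + ds,
                 end = .Machine$integer.max, strand = "+")
  pieces <- c(list(lflank),
              lapply(seq_len(nrow(spec$chain)), function(i) as.list(spec$chain[i, ])),
              list(rflank))
  lapply(seq_len(length(pieces) - 1L),
         function(i) list(donor = pieces[[i]], acceptor = pieces[[i + 1L]]))
}

#' Implant a complex SV allele into a reference genome
#'
#' Realizes the allele described by an \code{AltAlleleSpec}: edits the
#' reference so that each junction carries exactly the requested
#' microhomology, builds the alternate sequence (reverse-orientation segments
#' reverse-complemented), and emits an exact \code{TruthRecord}.
#'
#' Microhomology of length m at a junction is realized by copying the donor's
#' last m emitted bases over the m reference bases immediately upstream of the
#' acceptor breakpoint (in acceptor orientation); one guard base beyond the
#' homology on each side is forced to mismatch so the recovered length is
#' exactly m. Edits are applied to the reference before read simulation, so
#' genome, reads and the microhomology operator are self-consistent. After
#' editing, every junction is re-measured; contradictory edits (overlapping
#' junction neighborhoods that cannot all be satisfied) are rejected.
#'
#' @param ref a \code{ReferenceGenome}.
#' @param spec an \code{AltAlleleSpec}.
#' @return list with elements \code{ref} (edited genome), \code{alt_sequence},
#'   and \code{truth} (a \code{TruthRecord}: label, anchor, deleted_span,
#'   chain, per-junction breakpoints, event table, event classes,
#'   absolute_size, junction_mh, carriers).
#' @export
implant_sv <- function(ref, spec) {
  stopifnot(inherits(spec, "AltAlleleSpec"))
  ctg <- ref$contigs[[spec$anchor_contig]]
  if (is.null(ctg)) stop("anchor contig not in reference")
  L <- nchar(ctg)
  a <- spec$anchor_pos; ds <- spec$deleted_span
  if (a < 2L || a + ds > L) stop("anchor/deleted span out of contig bounds")
  ch <- spec$chain
  for (i in seq_len(nrow(ch))) {
    cl <- nchar(ref$contigs[[ch$contig[i]]])
    if (is.null(cl) || ch$start[i] < 1L || ch$end[i] > cl)
      stop("chain segment ", i, " out of bounds")
  }

  juncs <- spec_junctions(spec)
  edits <- list()  # contig -> named int vector pos -> base char
  add_edit <- function(contig, pos, base) {
    cur <- edits[[contig]]
    key <- as.character(pos)
    if (!is.null(cur) && key %in% names(cur) && cur[[key]] != base)
      stop("conflicting microhomology edits at ", contig, ":", pos)
    cur[key] <- base
    edits[[contig]] <<- cur
  }

  for (j in seq_along(juncs)) {
    m <- spec$junction_mh[j]
    don <- juncs[[j]]$donor; acc <- juncs[[j]]$acceptor
    if (piece_len(don) < m + 1L && don$end != .Machine$integer.max)
      stop("donor piece of junction ", j, " too short for MH ", m)
    ## donor's emitted bases at distance 1..m+1 from the junction (oriented)
    don_pos <- if (don$strand == "+") don$end - 0:m else don$start + 0:m
    if (any(don_pos < 1L)) stop("junction ", j, " too close to contig start")
    don_bases <- oriented_base(ref, don$contig, don_pos, don$strand)
    ## target: acceptor upstream flank positions at distance 1..m+1
    acc_flank <- upstream_flank_pos(acc, m + 1L)
    if (any(acc_flank < 1L) || any(acc_flank > nchar(ref$contigs[[acc$contig]])))
      stop("acceptor flank of junction ", j, " out of bounds")
    ## copy homology bases (distances 1..m)
    for (i in seq_len(m)) {
      b <- don_bases[i]
      if (acc$strand == "-") b <- chartr("ACGT", "TGCA", b)
      add_edit(acc$contig, acc_flank[i], b)
    }
    ## left guard: base at distance m+1 must differ from donor's
    cur <- oriented_base(ref, acc$contig, acc_flank[m + 1L], acc$strand)
    if (cur == don_bases[m + 1L]) {
      b <- other_base(don_bases[m + 1L])
      if (acc$strand == "-") b <- chartr("ACGT", "TGCA", b)
      add_edit(acc$contig, acc_flank[m + 1L], b)
    }
    ## right guard: base just after the donor's oriented end must differ from
    ## the acceptor's first emitted base (forces right-side homology to zero)
    don_after <- downstream_flank_pos(don, 1L)
    acc_start_pos <- piece_oriented_start(acc)
    acc_first <- oriented_base(ref, acc$contig, acc_start_pos, acc$strand)
    if (don_after >= 1L && don_after <= nchar(ref$contigs[[don$contig]])) {
      cur <- oriented_base(ref, don$contig, don_after, don$strand)
      if (cur == acc_first) {
        b <- other_base(acc_first)
        if (don$strand == "-") b <- chartr("ACGT", "TGCA", b)
        add_edit(don$contig, don_after, b)
      }
    }
  }

  ## apply edits
  for (cn in names(edits)) {
    ev <- edits[[cn]]
    ref$contigs[[cn]] <- str_assign(ref$contigs[[cn]],
                                    as.integer(names(ev)), unname(ev))
  }
  ## drop germline SNPs whose reference base was edited
  drop_snps <- function(tab) {
    if (!nrow(tab)) return(tab)
    keep <- rep(TRUE, nrow(tab))
    for (cn in names(edits)) {
      pos <- as.integer(names(edits[[cn]]))
      keep <- keep & !(tab$contig == cn & tab$pos %in% pos)
    }
    tab[keep, , drop = FALSE]
  }
  ref$het_snps <- drop_snps(ref$het_snps)
  ref$hom_snps <- drop_snps(ref$hom_snps)

  ## verify realized microhomology junction by junction
  realized <- vapply(seq_along(juncs), function(j) {
    don <- juncs[[j]]$donor; acc <- juncs[[j]]$acceptor
    detect_microhomology(ref,
      donor = list(contig = don$contig, pos = piece_oriented_end(don),
                   strand = don$strand),
      acceptor = list(contig = acc$contig, pos = piece_oriented_start(acc),
                      strand = acc$strand),
      max_mh = max(spec$junction_mh) + 2L)
  }, 0L)
  if (!all(realized == spec$junction_mh))
    stop("conflicting microhomology edits: requested ",
         paste(spec$junction_mh, collapse = ","), " realized ",
         paste(realized, collapse = ","))

  ## alternate sequence
  alt_parts <- vapply(seq_len(nrow(ch)), function(i) {
    ref_fetch(ref, ch$contig[i], ch$start[i], ch$end[i], ch$strand[i])
  }, "")
  alt_sequence <- paste0(alt_parts, collapse = "")

  ## truth breakpoints: donor oriented end -> acceptor oriented start
  bp <- do.call(rbind, lapply(juncs, function(jn) {
    data.frame(contigA = jn$donor$contig,
               posA = piece_oriented_end(jn$donor),
               strandA = jn$donor$strand,
               contigB = jn$acceptor$contig,
               posB = piece_oriented_start(jn$acceptor),
               strandB = jn$acceptor$strand,
               stringsAsFactors = FALSE)
  }))
  bp$posB[nrow(bp)] <- a + ds  # right flank oriented start is finite

  events <- spec_truth_events(spec)
  truth <- structure(list(
    label = spec$label,
    anchor_contig = spec$anchor_contig, anchor_pos = a,
    deleted_span = ds, chain = ch,
    breakpoints = bp,
    events = events,
    classes = sort(events$type),
    absolute_size = abs(ds - nchar(alt_sequence)),
    junction_mh = spec$junction_mh,
    carriers = character(0)), class = "TruthRecord")
  list(ref = ref, alt_sequence = alt_sequence, truth = truth)
}

## Expected event table implied by a spec, from interval arithmetic alone
## (independent of the read-level resolver): deletions are sub-spans of the
## replaced region covered zero times by the chain; duplications are anchor
## regions with total copy count >= 2; inversions are reverse-orientation
## segments; insertions are segments from other contigs or outside the
## anchor neighborhood.
spec_truth_events <- function(spec, neighborhood = 2000L) {
  ch <- spec$chain
  a <- spec$anchor_pos; ds <- spec$deleted_span; c0 <- spec$anchor_contig
  region <- c(a - neighborhood, a + ds - 1L + neighborhood)
  ev <- list()
  local_idx <- which(ch$contig == c0 & ch$start <= region[2] & ch$end >= region[1])
  ## coverage over the anchor neighborhood: 1 everywhere except the deleted
  ## span (0), plus chain-segment copies
  if (ds > 0) {
    delspan <- IRanges::IRanges(a, a + ds - 1L)
    covered <- if (length(local_idx))
      IRanges::reduce(IRanges::IRanges(ch$start[local_idx], ch$end[local_idx]))
    else IRanges::IRanges()
    gaps <- IRanges::setdiff(delspan, covered)
    for (i in seq_along(gaps)) {
      ev[[length(ev) + 1L]] <- data.frame(
        type = "DEL", contig = c0, start = IRanges::start(gaps)[i],
        end = IRanges::end(gaps)[i], stringsAsFactors = FALSE)
    }
  }
  ## duplications: total copy number >= 2 within the neighborhood
  if (length(local_idx)) {
    segs <- IRanges::IRanges(ch$start[local_idx], ch$end[local_idx])
    cov <- IRanges::coverage(segs, width = region[2])
    base1 <- IRanges::IRanges(region[1], region[2])
    if (ds > 0) base1 <- IRanges::setdiff(base1, IRanges::IRanges(a, a + ds - 1L))
    total2 <- IRanges::slice(cov, lower = 2)         # chain alone covers twice
    dup_r <- IRanges::reduce(c(
      methods::as(total2, "IRanges"),
      IRanges::intersect(methods::as(IRanges::slice(cov, lower = 1), "IRanges"), base1)))
    for (i in seq_along(dup_r)) {
      ev[[length(ev) + 1L]] <- data.frame(
        type = "DUP", contig = c0, start = IRanges::start(dup_r)[i],
        end = IRanges::end(dup_r)[i], stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(ch))) {
    if (ch$strand[i] == "-")
      ev[[length(ev) + 1L]] <- data.frame(
        type = "INV", contig = ch$contig[i], start = ch$start[i],
        end = ch$end[i], stringsAsFactors = FALSE)
    distal <- ch$contig[i] != c0 || ch$end[i] < region[1] || ch$start[i] > region[2]
    if (distal)
      ev[[length(ev) + 1L]] <- data.frame(
        type = "INS", contig = ch$contig[i], start = ch$start[i],
        end = ch$end[i], stringsAsFactors = FALSE)
  }
  if (!length(ev))
    return(data.frame(type = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, ev)
  out$size <- out$end - out$start + 1L
  out[order(out$type, out$start), , drop = FALSE]
}

#' @export
print.TruthRecord <- function(x, ...) {
  cat("TruthRecord", x$label, "@", x$anchor_contig, x$anchor_pos,
      "del", x$deleted_span, "bp; chain of", nrow(x$chain),
      "segment(s); classes:", paste(x$classes, collapse = "+"),
      "; |size|", x$absolute_size, "bp\n")
  invisible(x)
}
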
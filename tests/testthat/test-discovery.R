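cfg <- pipeline_config()

test_that("abnormal-read criteria apply at their printed boundaries", {
  bg <- proper_background()
  ist <- estimate_insert_stats(bg)
  cut <- ist$mean + 3 * ist$sd
  recs <- rbind(bg,
    mk_rec(read_id = "clip31", clip_right = 31L, mlen = 119L),
    mk_rec(read_id = "clip30", clip_right = 30L, mlen = 120L),
    mk_rec(read_id = "meanins", isize = as.integer(round(ist$mean))),
    mk_rec(read_id = "bigins", isize = as.integer(ceiling(cut) + 5L),
           proper = FALSE),
    mk_rec(read_id = "xmate", mate_contig = "contig2", isize = NA_integer_,
           proper = FALSE))
  abn <- extract_abnormal_reads(recs, cfg, insert_stats = ist)
  expect_true("clip31" %in% abn$read_id)
  expect_false("clip30" %in% abn$read_id)
  expect_false("meanins" %in% abn$read_id)
  expect_true("bigins" %in% abn$read_id)
  expect_true("xmate" %in% abn$read_id)
})

test_that("insert statistics require enough proper pairs", {
  expect_error(estimate_insert_stats(proper_background(50L)), "proper pairs")
})

test_that("breakpoint clustering merges within tolerance and applies support", {
  clip_rec <- function(id, pos, n = 1L) {
    do.call(rbind, lapply(seq_len(n), function(i)
      mk_rec(read_id = paste0(id, i), pos = pos - 119L, mlen = 120L,
             clip_right = 31L,
             seq = strrep("A", 120L) |> paste0(strrep("C", 31L)))))
  }
  five <- clip_rec("a", 700L, 5L)
  cand <- cluster_breakpoints(five, cfg)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$split_support, 5L)
  expect_identical(cand$pos, 700L)

  close_far <- rbind(clip_rec("a", 300L, 3L),
                     clip_rec("b", 303L, 3L),
                     clip_rec("c", 2300L, 3L))
  cand2 <- cluster_breakpoints(close_far, cfg)
  expect_identical(nrow(cand2), 2L)

  weak <- clip_rec("w", 900L, 2L)
  expect_identical(nrow(cluster_breakpoints(weak, cfg)), 0L)
})

test_that("junction pairing types canonical signatures from clipped sequences", {
  ref <- build_reference(17, n_contigs = 2L, contig_length = 5000L,
                         snp_density = 0)
  mkcand <- function(contig, pos, side, clip) {
    data.frame(sample = "s1", contig = contig, pos = pos, side = side,
               split_support = 5L, discordant_support = 0L, clip_seq = clip,
               stringsAsFactors = FALSE)
  }
  fetch <- function(contig, s, e, strand = "+")
    clonesv:::ref_fetch(ref, contig, s, e, strand)
  ## deletion: right clip at 500 continues at 801; left clip at 801 carries
  ## the donor suffix
  del <- rbind(mkcand("contig1", 500L, "R", fetch("contig1", 801L, 840L)),
               mkcand("contig1", 801L, "L", fetch("contig1", 461L, 500L)))
  out <- pair_and_type(del, ref, cfg)
  expect_identical(out$type, "DEL")
  expect_identical(out$start, 501L)
  expect_identical(out$end, 800L)
  ## tandem duplication: (L at a, R at b)
  dup <- rbind(mkcand("contig1", 1200L, "L", fetch("contig1", 1961L, 2000L)),
               mkcand("contig1", 2000L, "R", fetch("contig1", 1200L, 1239L)))
  out2 <- pair_and_type(dup, ref, cfg)
  expect_identical(out2$type, "DUP")
  expect_identical(out2$start, 1200L)
  expect_identical(out2$end, 2000L)
  ## a lone inverted candidate is recovered by clip realignment as an
  ## inversion-type junction (its one-sidedness shows as a missing LL
  ## companion, which the MDA-artifact flag keys on)
  lone <- mkcand("contig1", 3000L, "R",
                 clonesv:::rc(fetch("contig1", 2911L, 2950L)))
  out3 <- pair_and_type(lone, ref, cfg)
  expect_identical(out3$type, "INV")
  expect_identical(out3$orient, "RR")
  expect_identical(out3$bp2, 2950L)
  ## a clip matching nowhere stays a one-sided breakend
  set.seed(4)
  noise <- paste0(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                  collapse = "")
  out4 <- pair_and_type(mkcand("contig1", 3000L, "R", noise), ref, cfg)
  expect_identical(out4$type, "BND")
  expect_identical(out4$orient, "R-")
  ## inter-contig pair becomes a two-sided BND
  bnd <- rbind(mkcand("contig1", 1500L, "R", fetch("contig2", 2500L, 2539L)),
               mkcand("contig2", 2500L, "L", fetch("contig1", 1461L, 1500L)))
  out5 <- pair_and_type(bnd, ref, cfg)
  expect_identical(out5$type, "BND")
  expect_identical(out5$contig, "contig1")
  expect_identical(out5$contig2, "contig2")
})

test_that("reciprocal-overlap merging hits the 50% boundary and is idempotent", {
  mkcall <- function(s1, e1, s2, e2) {
    data.frame(sample = "s", type = "DEL", contig = "c1",
               start = c(s1, s2), end = c(e1, e2), contig2 = "c1",
               pos2 = c(e1, e2), orient = "RL", split_support = c(3L, 4L),
               discordant_support = 0L, bp1 = c(s1, s2) - 1L,
               bp2 = c(e1, e2) + 1L, strand1 = "+", strand2 = "+",
               stringsAsFactors = FALSE)
  }
  ## overlap 50 of a 100-length call: exactly at the boundary -> merged
  m <- merge_reciprocal(mkcall(100L, 199L, 150L, 249L), cfg)
  expect_identical(nrow(m), 1L)
  expect_identical(m$start, 100L)
  expect_identical(m$end, 249L)
  expect_identical(m$split_support, 7L)
  ## 10/210 overlap: kept apart
  k <- merge_reciprocal(mkcall(100L, 199L, 190L, 399L), cfg)
  expect_identical(nrow(k), 2L)
  ## identical spans merge; a second application changes nothing
  i1 <- merge_reciprocal(mkcall(100L, 199L, 100L, 199L), cfg)
  expect_identical(nrow(i1), 1L)
  expect_identical(merge_reciprocal(i1, cfg), i1)
})

test_that("adjacency grouping partitions calls and links within 1000 bp", {
  mk <- function(contig, b1, b2, type = "DEL") {
    data.frame(sample = "s", type = type, contig = contig,
               start = min(b1, b2), end = max(b1, b2), contig2 = contig,
               pos2 = b2, orient = "RL", split_support = 5L,
               discordant_support = 0L, bp1 = b1, bp2 = b2, strand1 = "+",
               strand2 = "+", stringsAsFactors = FALSE)
  }
  calls <- rbind(mk("c1", 4000L, 5000L, "DEL"),
                 mk("c1", 5400L, 5600L, "INV"),
                 mk("c1", 10600L, 11000L, "DUP"))
  g <- group_adjacent_complex(calls, cfg)
  expect_identical(length(unique(g$group)), 2L)
  expect_identical(g$group[1], g$group[2])   # 400 bp apart: one complex group
  expect_false(g$group[3] == g$group[1])     # 5 kb away: separate
  expect_true(all(g$complex[1:2]))
  expect_false(g$complex[3])
  ## partition: every call in exactly one group
  expect_identical(sum(table(g$group)), nrow(calls))
})

test_that("germline-catalog filtering removes only reciprocal matches", {
  call <- data.frame(sample = "s", type = "DEL", contig = "c1", start = 1000L,
                     end = 2000L, contig2 = "c1", pos2 = 2001L, orient = "RL",
                     split_support = 5L, discordant_support = 0L, bp1 = 999L,
                     bp2 = 2001L, strand1 = "+", strand2 = "+",
                     stringsAsFactors = FALSE)
  exact <- data.frame(contig = "c1", start = 1000L, end = 2000L)
  r1 <- filter_known_germline(call, exact, cfg)
  expect_identical(nrow(r1$kept), 0L)
  expect_identical(nrow(r1$removed), 1L)
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0))
  r2 <- filter_known_germline(call, empty, cfg)
  expect_identical(nrow(r2$kept), 1L)
  partial <- data.frame(contig = "c1", start = 1900L, end = 11000L)
  r3 <- filter_known_germline(call, partial, cfg)
  expect_identical(nrow(r3$kept), 1L)
  expect_error(filter_known_germline(call, data.frame(a = 1), cfg), "catalog")
})

test_that("malformed BED files are rejected", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("c1\tx\t200"), f)
  expect_error(read_bed(f), "malformed|scan")
  writeLines(c("c1\t100"), f)
  expect_error(read_bed(f), "malformed|columns|scan")
})

test_that("clonal simple deletions >= 500 bp are recovered with high recall", {
  found <- logical(0)
  for (i in 1:20) {
    s <- 900 + i
    ref <- build_reference(s, n_contigs = 1L, contig_length = 25000L,
                           snp_density = 5e-4)
    set.seed(s)
    ds <- sample(500:2000, 1L)
    imp <- implant_sv(ref, alt_allele_spec("d", "contig1", 11000L, ds,
                                           junction_mh = 2L))
    cl <- clone_spec("c", harbored_svs = data.frame(
      label = "d", cell_fraction = 1, stringsAsFactors = FALSE),
      coverage = 30)
    rd <- simulate_clone_reads(imp$ref, list(cl), list(d = imp$truth),
                               seed = s + 50L)
    calls <- discover_calls(rd$c, imp$ref, cfg)
    hit <- any(calls$type == "DEL" & abs(calls$start - 11000L) <= 12L &
                 abs(calls$end - (11000L + ds - 1L)) <= 12L)
    found <- c(found, hit)
  }
  expect_gte(mean(found), 0.95)
})

test_that("SV-free diploid genomes yield zero discoveries", {
  for (i in 1:5) {
    ref <- build_reference(950 + i, n_contigs = 1L, contig_length = 25000L,
                           snp_density = 5e-4)
    rd <- simulate_clone_reads(ref, list(clone_spec("c", coverage = 30)),
                               seed = 970 + i)
    calls <- discover_calls(rd$c, ref, cfg)
    expect_identical(nrow(calls), 0L)
  }
})
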
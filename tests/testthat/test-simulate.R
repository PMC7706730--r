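test_that("pair counts follow the coverage identity and output is deterministic", {
  ref <- build_reference(5, n_contigs = 1L, contig_length = 100000L,
                         snp_density = 0)
  cl <- clone_spec("c1", coverage = 30)
  r1 <- simulate_clone_reads(ref, list(cl), seed = 9)$c1
  r2 <- simulate_clone_reads(ref, list(cl), seed = 9)$c1
  expect_identical(r1, r2)
  n_pairs <- nrow(r1) / 2
  expect_lt(abs(n_pairs - 10000) / 10000, 0.05)
  ## coverage conservation: aligned bases over genome length
  expect_lt(abs(sum(r1$mlen) / 100000 - 30) / 30, 0.05)
})

test_that("junction-crossing reads are soft-clipped by the bases past the junction", {
  ## constructed projection: reads are anchored to the junction side holding
  ## most of the read (as an aligner would score it) and the remainder is
  ## soft-clipped, so the clip length always equals the bases on the far
  ## side of the junction
  ref <- build_reference(6, n_contigs = 2L, contig_length = 10000L,
                         snp_density = 0)
  map <- clonesv:::finish_map(data.frame(
    contig = c("contig1", "contig2"), ref_start = c(1L, 5000L),
    ref_end = c(2000L, 7000L), strand = "+", stringsAsFactors = FALSE))
  tmpl <- clonesv:::map_sequence(ref$contigs, map)
  ## 40 bases before the junction: anchored on the acceptor, 40-base clip
  p <- clonesv:::project_reads(map, s = 1961L, e = 2110L, fwd = TRUE, tmpl)
  expect_identical(p$clip_left, 40L)
  expect_identical(p$clip_right, 0L)
  expect_identical(p$mlen, 110L)
  expect_identical(p$pos, 5000L)
  ## 110 bases before the junction: anchored on the donor, 40-base clip
  p2 <- clonesv:::project_reads(map, s = 1891L, e = 2040L, fwd = TRUE, tmpl)
  expect_identical(p2$clip_right, 40L)
  expect_identical(p2$mlen, 110L)
  expect_identical(p2$pos, 1891L)
  ## in both cases clip + match partition the read at the junction
  expect_identical(p$clip_left + p$mlen, 150L)
  expect_identical(p2$clip_right + p2$mlen, 150L)
  ## mate wholly beyond the junction maps to the other contig
  q <- clonesv:::project_reads(map, s = 2011L, e = 2160L, fwd = FALSE, tmpl)
  expect_identical(q$contig, "contig2")
  expect_identical(q$pos, 5010L)
})

test_that("junction-read ALT fraction tracks cell_fraction/2 for het SVs", {
  ## a clonal (f = 1) and two subclonal deletions: at a deletion junction,
  ## reads from the SV haplotype crossing it are soft-clipped at one of the
  ## two junction boundaries; reference-haplotype reads span it unclipped
  ref <- build_reference(36, n_contigs = 1L, contig_length = 40000L,
                         snp_density = 0)
  imp <- implant_sv(ref, alt_allele_spec("d", "contig1", 20000L, 800L,
                                         junction_mh = 2L))
  for (f in c(1.0, 0.4, 0.1)) {
    cl <- clone_spec("c", harbored_svs = data.frame(
      label = "d", cell_fraction = f, stringsAsFactors = FALSE),
      coverage = 40)
    r <- simulate_clone_reads(imp$ref, list(cl), list(d = imp$truth),
                              seed = round(100 * f))$c
    a <- 20000L; b <- 20800L  # junction: donor 19999, acceptor 20800
    alt <- sum((r$clip_right > 0L & abs(r$pos + r$mlen - 1L - (a - 1L)) <= 3L) |
                 (r$clip_left > 0L & abs(r$pos - b) <= 3L))
    ref_n <- sum(r$clip_left == 0L & r$clip_right == 0L &
                   r$pos <= a - 11L & (r$pos + r$mlen - 1L) >= a + 9L)
    n <- alt + ref_n
    band <- qbinom(c(0.005, 0.995), n, f / 2)
    expect_gte(alt, band[1])
    expect_lte(alt, band[2])
  }
})

test_that("every implanted junction is spanned by soft-clipped reads at 30x", {
  sc <- cached("roundtrip_quick", function()
    simulate_and_resolve(301, genome_kb = 50L, seg_range = c(80L, 400L)))
  r <- sc$reads$case
  bp <- sc$truth$breakpoints
  for (i in seq_len(nrow(bp))) {
    don_clip <- sum(r$contig == bp$contigA[i] &
                      ((r$clip_right > 0L &
                          abs(r$pos + r$mlen - 1L - bp$posA[i]) <= 5L) |
                         (r$clip_left > 0L & abs(r$pos - bp$posA[i]) <= 5L)))
    expect_gte(don_clip, 1L)
  }
})

test_that("clone-private SNVs sit outside SV spans at ~0.5 allele fraction", {
  sc <- brain_scenario()
  r <- sc$reads$clone4
  snvs <- attr(r, "private_snvs")
  expect_identical(nrow(snvs), 53L)
  fracs <- vapply(seq_len(nrow(snvs)), function(i) {
    b <- clonesv:::read_bases_at(r, snvs$contig[i], snvs$pos[i])
    if (length(b) < 8) return(NA_real_)
    mean(b == snvs$alt[i])
  }, 0)
  fracs <- fracs[!is.na(fracs)]
  expect_gt(mean(fracs), 0.35)
  expect_lt(mean(fracs), 0.65)
})

test_that("read-depth simulation reflects copy number and normalizes to 2", {
  sc <- brain_scenario()
  depth <- simulate_read_depth(sc$ref, sc$clones[c(3, 6)], sc$truths,
                               bin_size = 200L, seed = 5)
  prof <- depth_profile(depth)
  tis <- prof[prof$sample == "tissue", ]
  expect_lt(abs(mean(tis$cn) - 2), 0.05)
  ## clone2 carries the deletion at cell fraction 0.4: CN = 2 - 0.4 = 1.6
  tr <- sc$truths$del
  c2 <- prof[prof$sample == "clone2" & prof$contig == "contig2" &
               prof$bin_start >= tr$anchor_pos &
               prof$bin_end <= tr$anchor_pos + tr$deleted_span, ]
  expect_lt(abs(mean(c2$cn) - 1.6), 0.15)
  ## tissue (no carrier cells) stays diploid there
  t2 <- prof[prof$sample == "tissue" & prof$contig == "contig2" &
               prof$bin_start >= tr$anchor_pos &
               prof$bin_end <= tr$anchor_pos + tr$deleted_span, ]
  expect_lt(abs(mean(t2$cn) - 2), 0.15)
  expect_error(simulate_read_depth(sc$ref, sc$clones[6], sc$truths,
                                   bin_size = 10L), "bin_size")
})

test_that("MDA chimera injection is off at rate zero and marked at rate > 0", {
  ref <- build_reference(8, n_contigs = 1L, contig_length = 50000L,
                         snp_density = 0)
  none <- simulate_mda_chimeras(ref, rate = 0, seed = 3)
  expect_identical(nrow(none), 0L)
  expect_identical(nrow(attr(none, "artifact_loci")), 0L)
  some <- simulate_mda_chimeras(ref, rate = 60, seed = 3)
  loci <- attr(some, "artifact_loci")
  expect_gt(nrow(loci), 0L)
  expect_gt(nrow(some), 0L)
  ## fold-back and duplication junctions sit within 1000 bp of each other
  expect_true(all(loci$inv_pos - loci$dup_end <= 1000L))
})
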
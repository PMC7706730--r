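cfg <- pipeline_config()

test_that("a collinear full-coverage chain yields no events and no switches", {
  ref <- build_reference(81, n_contigs = 1L, contig_length = 20000L,
                         snp_density = 0)
  chain <- data.frame(contig = "contig1", start = 4000L, end = 8000L,
                      strand = "+", stringsAsFactors = FALSE)
  m <- classify_rearrangement(chain, ref,
                              list(contig = "contig1", start = 4000L,
                                   end = 8000L), cfg)
  expect_identical(m$template_switches, 0L)
  expect_identical(nrow(m$events), 0L)
  expect_identical(m$absolute_size, 0L)
})

test_that("a two-deletion + inverted-duplication chain has four template switches", {
  ## composition mirroring the most complex clonal SV: two deletions, one
  ## inversion and one duplication explained by four replication fork
  ## switches
  ref <- build_reference(82, n_contigs = 1L, contig_length = 20000L,
                         snp_density = 0)
  chain <- data.frame(
    contig = "contig1",
    start = c(3000L, 6151L, 6301L, 6544L, 7051L),
    end = c(6000L, 6450L, 6543L, 6900L, 10000L),
    strand = c("+", "+", "-", "+", "+"),
    stringsAsFactors = FALSE)
  m <- classify_rearrangement(chain, ref,
                              list(contig = "contig1", start = 5000L,
                                   end = 8000L), cfg)
  expect_identical(m$template_switches, 4L)
  expect_identical(sum(m$events$type == "DEL"), 2L)
  expect_identical(sum(m$events$type == "INV"), 1L)
  expect_identical(sum(m$events$type == "DUP"), 1L)
  ## deletions are the uncovered sub-spans of the replaced region
  expect_setequal(m$events$size[m$events$type == "DEL"],
                  c(6150L - 6001L + 1L, 7050L - 6901L + 1L))
})

test_that("size spectra are conserved and match the worked examples", {
  ref <- build_reference(83, n_contigs = 1L, contig_length = 30000L,
                         snp_density = 0)
  ## single 500-bp deletion
  del_chain <- data.frame(contig = "contig1", start = c(3000L, 10500L),
                          end = c(9999L, 15000L), strand = "+",
                          stringsAsFactors = FALSE)
  m1 <- classify_rearrangement(del_chain, ref,
                               list(contig = "contig1", start = 8000L,
                                    end = 12500L), cfg)
  sp1 <- size_spectra(list(m1))
  expect_identical(sp1$deleted, 500L)
  expect_length(sp1$segments, 0L)

  ## 1891-bp deletion with an adjacent 243-bp inverted fragment
  inv_chain <- data.frame(contig = "contig1",
                          start = c(3000L, 10001L, 12135L),
                          end = c(10000L, 10243L, 20000L),
                          strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  m2 <- classify_rearrangement(inv_chain, ref,
                               list(contig = "contig1", start = 9000L,
                                    end = 13000L), cfg)
  sp2 <- size_spectra(list(m2))
  expect_identical(sp2$deleted, 1891L)
  expect_true(243L %in% sp2$segments)

  ## conservation: inner footprint within the replaced span plus deleted
  ## bases equals the replaced span, for every model
  for (m in list(m1, m2)) {
    rep_len <- m$replaced_span["end"] - m$replaced_span["start"] + 1L
    inner <- m$chain[-c(1L, nrow(m$chain)), , drop = FALSE]
    inner <- inner[inner$contig == m$chain$contig[1], , drop = FALSE]
    foot <- 0L
    if (nrow(inner)) {
      ir <- IRanges::reduce(IRanges::IRanges(inner$start, inner$end))
      ir <- IRanges::intersect(ir, IRanges::IRanges(m$replaced_span["start"],
                                                    m$replaced_span["end"]))
      foot <- sum(IRanges::width(ir))
    }
    expect_identical(as.integer(foot + sum(m$deleted_sizes)),
                     as.integer(rep_len))
  }
})

test_that("microhomology detection recovers shared junction sequence", {
  seqs <- c(contig1 = paste0(strrep("A", 50), "GAT",
                             paste0(rep(c("C", "T", "G", "A"), 12),
                                    collapse = ""),
                             strrep("C", 47)))
  ref <- structure(list(contigs = seqs,
                        gaps = data.frame(), het_snps = data.frame(),
                        hom_snps = data.frame()), class = "ReferenceGenome")
  ## donor ends ...GAT at 53; acceptor at 120 with upstream bases also GAT
  ref$contigs[["contig1"]] <- clonesv:::str_assign(ref$contigs[["contig1"]],
                                                   117:119, c("G", "A", "T"))
  ref$contigs[["contig1"]] <- clonesv:::str_assign(ref$contigs[["contig1"]],
                                                   116L, "C")
  ref$contigs[["contig1"]] <- clonesv:::str_assign(ref$contigs[["contig1"]],
                                                   50L, "T")
  mh <- detect_microhomology(ref,
    donor = list(contig = "contig1", pos = 53L, strand = "+"),
    acceptor = list(contig = "contig1", pos = 120L, strand = "+"))
  expect_identical(mh, 3L)
  ## no shared bases -> 0
  ref2 <- ref
  ref2$contigs[["contig1"]] <- clonesv:::str_assign(ref2$contigs[["contig1"]],
                                                    117:119, c("C", "C", "G"))
  ref2$contigs[["contig1"]] <- clonesv:::str_assign(ref2$contigs[["contig1"]],
                                                    54L, "G")
  mh0 <- detect_microhomology(ref2,
    donor = list(contig = "contig1", pos = 53L, strand = "+"),
    acceptor = list(contig = "contig1", pos = 120L, strand = "+"))
  expect_identical(mh0, 0L)
})

test_that("the explanation score applies its strictly-greater threshold", {
  ref <- build_reference(84, n_contigs = 1L, contig_length = 20000L,
                         snp_density = 0)
  chain <- data.frame(contig = "contig1", start = c(3000L, 10500L),
                      end = c(9999L, 15000L), strand = "+",
                      stringsAsFactors = FALSE)
  m <- classify_rearrangement(chain, ref, list(contig = "contig1",
                                               start = 9000L, end = 11500L),
                              cfg)
  alt <- model_alt_sequence(m, ref)
  consistent <- substring(alt, seq(6900L, 7050L, by = 10L),
                          seq(7049L, 7199L, by = 10L))
  stray <- vapply(1:4, function(i)
    paste0(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""),
    "")
  mk <- function(seqs) data.frame(seq = seqs, rescued = FALSE,
                                  stringsAsFactors = FALSE)
  all_fit <- explanation_score(m, mk(consistent[1:16]), ref, cfg)
  expect_identical(all_fit$score, 1)
  expect_true(all_fit$retained)
  boundary <- explanation_score(m, mk(c(consistent[1:16], stray)), ref, cfg)
  expect_equal(boundary$score, 0.8)
  expect_false(boundary$retained)   # strictly-greater rule
  none <- explanation_score(m, mk(stray), ref, cfg)
  expect_identical(none$score, 0)
  expect_false(none$retained)
})

test_that("reciprocal deletion+duplication pairs fuse into circular DNA events", {
  mk <- function(type, s, e) data.frame(
    sample = "n12", type = type, contig = "chrY", start = s, end = e,
    contig2 = "chrY", pos2 = e, orient = "RL", split_support = 8L,
    discordant_support = 0L, bp1 = s - 1L, bp2 = e + 1L, strand1 = "+",
    strand2 = "+", stringsAsFactors = FALSE)
  calls <- rbind(mk("DEL", 10000L, 18000L), mk("DUP", 10004L, 17996L))
  out <- detect_eccdna(calls, cfg)
  expect_identical(nrow(out$circles), 1L)
  expect_identical(nrow(out$calls), 0L)
  expect_identical(out$circles$start, 10000L)
  ## offset by 5 kb: no circle
  far <- rbind(mk("DEL", 10000L, 18000L), mk("DUP", 15000L, 23000L))
  out2 <- detect_eccdna(far, cfg)
  expect_identical(nrow(out2$circles), 0L)
  expect_identical(nrow(out2$calls), 2L)
})

test_that("a simulated excision circle is detected with its correct span", {
  ref <- build_reference(85, n_contigs = 1L, contig_length = 60000L,
                         snp_density = 0)
  a <- 30000L; b <- 33000L
  imp <- implant_sv(ref, alt_allele_spec("circdel", "contig1", a,
                                         b - a + 1L, junction_mh = 0L))
  cl <- clone_spec("n12", harbored_svs = data.frame(
    label = "circdel", cell_fraction = 1, stringsAsFactors = FALSE))
  rd <- simulate_clone_reads(imp$ref, list(cl), list(circdel = imp$truth),
                             seed = 5)$n12
  circ <- simulate_eccdna_reads(imp$ref, "contig1", a, b, coverage = 15,
                                sample_id = "n12", seed = 6)
  calls <- discover_calls(rbind(rd, circ), imp$ref)
  out <- detect_eccdna(calls, cfg)
  expect_identical(nrow(out$circles), 1L)
  expect_lt(abs(out$circles$start - a), 11L)
  expect_lt(abs(out$circles$end - b), 11L)
  ## and such a reciprocal pair must not be MDA-flagged
  flagged <- flag_mda_artifacts(group_adjacent_complex(calls, cfg), cfg)
  expect_false(any(flagged$mda_artifact))
})

test_that("resolving the reverse-complemented contig yields the mirror model", {
  ref <- build_reference(86, n_contigs = 1L, contig_length = 20000L,
                         snp_density = 0)
  fwd <- paste0(substr(ref$contigs[[1]], 2001L, 2300L),
                clonesv:::rc(substr(ref$contigs[[1]], 9001L, 9400L)))
  al_f <- align_contig(fwd, ref, cfg)
  al_r <- align_contig(clonesv:::rc(fwd), ref, cfg)
  expect_identical(nrow(al_f), nrow(al_r))
  expect_setequal(al_f$rstart, al_r$rstart)
  expect_setequal(al_f$strand, c("+", "-"))
  expect_setequal(al_r$strand, c("+", "-"))
  ## orientations flip per segment
  f_plus <- al_f$rstart[al_f$strand == "+"]
  r_minus <- al_r$rstart[al_r$strand == "-"]
  expect_identical(sort(f_plus), sort(r_minus))
})
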
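cfg <- pipeline_config()

## one resolved deletion model on a bare reference, for construction tests
simple_model <- function(seed = 91, ds = 600L) {
  ref <- build_reference(seed, n_contigs = 1L, contig_length = 30000L,
                         snp_density = 0)
  a <- 15000L
  chain <- data.frame(contig = "contig1", start = c(10000L, a + ds),
                      end = c(a - 1L, 20000L), strand = "+",
                      stringsAsFactors = FALSE)
  m <- classify_rearrangement(chain, ref,
                              list(contig = "contig1", start = a - 2000L,
                                   end = a + ds + 2000L), cfg)
  list(ref = ref, model = m, a = a, ds = ds)
}

test_that("pseudoreference has flank+contig+flank structure and reverts hom SNPs", {
  s <- simple_model()
  ps <- build_pseudoreference(s$model, s$ref, cfg)
  ## pure deletion: alt allele is just the two 2-kb flanks
  expect_identical(nchar(ps$sequence), 4000L)
  expect_identical(nchar(ps$ref_sequence), 4000L + s$ds)
  expect_identical(length(ps$junctions), 1L)
  expect_identical(nrow(ps$reverted_sites), 0L)

  ## a homozygous SNP in the left flank is reverted; a het SNP is untouched
  ref2 <- s$ref
  hom_pos <- s$a - 1000L; het_pos <- s$a - 900L
  hom_ref <- substr(ref2$contigs[[1]], hom_pos, hom_pos)
  panel <- data.frame(contig = "contig1", pos = c(hom_pos, het_pos),
                      ref = c(hom_ref, "A"), alt = c("N", "N"),
                      hom_fraction = c(0.95, 0.4), stringsAsFactors = FALSE)
  ## make the genome carry a non-reference base at the hom site
  ref2$contigs[[1]] <- clonesv:::str_assign(ref2$contigs[[1]], hom_pos,
                                            setdiff(c("A", "C", "G", "T"),
                                                    hom_ref)[1])
  ps2 <- build_pseudoreference(s$model, ref2, cfg, snp_panel = panel)
  expect_identical(nrow(ps2$reverted_sites), 1L)
  expect_identical(ps2$reverted_sites$pos, hom_pos)
  rp <- ps2$reverted_sites$pseudo_pos
  expect_identical(substr(ps2$sequence, rp, rp), hom_ref)
})

test_that("only junction-crossing reads are allele-diagnostic", {
  s <- simple_model()
  ps <- build_pseudoreference(s$model, s$ref, cfg)
  ## read spanning the ALT junction exactly: unique ALT
  junc <- ps$junctions[1]
  alt_read <- substr(ps$sequence, junc - 75L, junc + 74L)
  ## read wholly inside a flank: present in both alleles, counts for neither
  flank_read <- substr(ps$sequence, 101L, 250L)
  ## read spanning the REF breakpoint: unique REF
  ref_read <- substr(ps$ref_sequence, 2000L - 75L + 1L, 2000L + 75L)
  cnt <- map_reads_unique(c(alt_read, flank_read, ref_read), ps, cfg)
  expect_identical(cnt$alt, 1L)
  expect_identical(cnt$ref, 1L)
})

test_that("allele-fraction upper bound follows 0.5/N and decreases in N", {
  expect_equal(af_upper_bound(167), 0.5 / 167)
  expect_lt(af_upper_bound(167), 0.003)
  expect_equal(af_upper_bound(1), 0.5)
  expect_equal(af_upper_bound(50), 0.01)
  ns <- c(1, 2, 5, 10, 100, 1000)
  expect_true(all(diff(af_upper_bound(ns)) < 0))
  expect_error(af_upper_bound(0), "capacity")
})

test_that("carriers genotype present at ~50% AF; SV-free samples are clean", {
  sc <- brain_scenario()
  ## resolve the subclonal deletion from its carrier
  tr <- sc$truths$del
  res <- resolve_call(sc$reads$clone2,
                      list(contig = tr$anchor_contig, start = tr$anchor_pos,
                           end = tr$anchor_pos + tr$deleted_span),
                      sc$ref, cfg)
  expect_false(is.null(res$model))
  ps <- build_pseudoreference(res$model, sc$ref, cfg)
  gt <- genotype_all(sc$reads[c("clone2", "clone3", "tissue")], ps, cfg)
  expect_true(gt$present[gt$sample == "clone2"])
  expect_false(any(gt$present[gt$sample != "clone2"]))
  ## absent samples carry the extrapolated bound from carrier capacity
  cap <- gt$unique_alt_reads[gt$sample == "clone2"]
  expect_equal(gt$af_upper_bound[gt$sample == "clone3"], 0.5 / cap)
  ## subclonal carrier at cell fraction 0.4: normalized AF ~ 0.2; the raw
  ## ALT count follows a binomial with window-corrected success share
  row <- gt[gt$sample == "clone2", ]
  af <- row$allele_fraction
  n <- row$unique_alt_reads + row$unique_ref_reads
  r <- 0.2 / (1 - 0.2)   # ALT/REF haplotype-read rate ratio at AF 0.2
  p0 <- r * row$w_alt / (r * row$w_alt + row$w_ref)
  band <- qbinom(c(0.005, 0.995), n, p0)
  expect_gte(row$unique_alt_reads, band[1])
  expect_lte(row$unique_alt_reads, band[2])
  expect_lt(abs(af - 0.2), 0.15)
})

test_that("clonality classification uses AF and deleted-region het SNPs", {
  ## clonal: AF right at 0.5
  g <- data.frame(unique_alt_reads = 80L, unique_ref_reads = 80L)
  r1 <- classify_clonality(g, mk_rec()[0, ])
  expect_identical(r1$clonality, "clonal")
  ## subclonal by allele fraction (cell fraction ~0.2 -> AF ~0.1)
  g2 <- data.frame(unique_alt_reads = 16L, unique_ref_reads = 144L)
  r2 <- classify_clonality(g2, mk_rec()[0, ])
  expect_identical(r2$clonality, "subclonal")
  ## subclonal by surviving het SNP in the deleted region, regardless of AF
  het <- data.frame(contig = "contig1", pos = 1075L, ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  reads <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      mk_rec(read_id = paste0("ra", i), pos = 1000L,
             seq = strrep("A", 150L)))),
    do.call(rbind, lapply(1:5, function(i)
      mk_rec(read_id = paste0("rg", i), pos = 1000L,
             seq = paste0(strrep("A", 75L), "G", strrep("A", 74L))))))
  r3 <- classify_clonality(g, reads,
                           deleted_regions = data.frame(contig = "contig1",
                                                        start = 1000L,
                                                        end = 1200L),
                           het_snps = het)
  expect_identical(r3$clonality, "subclonal")
  expect_identical(r3$het_sites_both_alleles, 1L)
})

test_that("allele-fraction recovery tracks cell fraction with small error", {
  ## the discovery clone's resolved allele genotypes carriers at cell
  ## fractions 1.0, 0.5 and 0.2; mean absolute AF error stays <= 0.05
  errs <- c()
  for (i in 1:7) {
    s <- 800 + i
    ref <- build_reference(s, n_contigs = 2L, contig_length = 40000L,
                           snp_density = 5e-4)
    spec <- alt_allele_spec("cx", "contig1", 20000L, 600L,
      chain = data.frame(contig = c("contig2", "contig1"),
                         start = c(9000L, 32000L), end = c(9299L, 32299L),
                         strand = c("+", "-"), stringsAsFactors = FALSE),
      junction_mh = c(2L, 3L, 2L))
    imp <- implant_sv(ref, spec)
    mk <- function(id, f) clone_spec(id, harbored_svs = data.frame(
      label = "cx", cell_fraction = f, stringsAsFactors = FALSE),
      coverage = 30)
    rd <- simulate_clone_reads(imp$ref,
                               list(mk("c10", 1), mk("c05", 0.5),
                                    mk("c02", 0.2)),
                               list(cx = imp$truth), seed = s + 100L)
    res <- resolve_call(rd$c10,
                        list(contig = "contig1", start = 20000L,
                             end = 20600L), imp$ref, cfg,
                        extra_loci = data.frame(contig = spec$chain$contig,
                                                start = spec$chain$start,
                                                end = spec$chain$end))
    expect_false(is.null(res$model))
    ps <- build_pseudoreference(res$model, imp$ref, cfg)
    gt <- genotype_all(rd, ps, cfg)
    f <- c(c10 = 1, c05 = 0.5, c02 = 0.2)[gt$sample]
    errs <- c(errs, abs(gt$allele_fraction - f / 2))
  }
  expect_lte(mean(errs), 0.05)
  expect_gte(length(errs), 20L)
})
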
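cfg <- pipeline_config()

## ten tiny clones, one private deletion in cloneA, one germline deletion in
## everyone, one deletion shared by exactly two clones
pairwise_scenario <- function() cached("pairwise", function() {
  ref <- build_reference(33, n_contigs = 1L, contig_length = 40000L,
                         snp_density = 0)
  priv <- implant_sv(ref, alt_allele_spec("priv", "contig1", 8000L, 700L,
                                          junction_mh = 2L))
  shared <- implant_sv(priv$ref, alt_allele_spec("shared", "contig1", 20000L,
                                                 900L, junction_mh = 3L))
  germ <- implant_sv(shared$ref, alt_allele_spec("germ", "contig1", 32000L,
                                                 800L, junction_mh = 2L))
  ref <- germ$ref
  truths <- list(priv = priv$truth, shared = shared$truth, germ = germ$truth)
  ids <- paste0("cl", 1:10)
  clones <- lapply(ids, function(id) {
    svs <- "germ"
    if (id == "cl1") svs <- c(svs, "priv")
    if (id %in% c("cl4", "cl8")) svs <- c(svs, "shared")
    clone_spec(id, harbored_svs = data.frame(label = svs, cell_fraction = 1,
                                             stringsAsFactors = FALSE),
               coverage = 30)
  })
  reads <- simulate_clone_reads(ref, clones, truths, seed = 101)
  calls <- lapply(reads, discover_calls, ref = ref, config = cfg)
  list(ref = ref, truths = truths, reads = reads, calls = calls)
})

test_that("clone-to-clone comparison votes separate somatic from germline", {
  sc <- pairwise_scenario()
  voted <- lapply(names(sc$reads), function(id) {
    call_somatic_pairwise(sc$calls[[id]], sc$reads[names(sc$reads) != id], cfg)
  })
  names(voted) <- names(sc$reads)
  ## private deletion: 9/9 votes in its carrier
  v1 <- voted$cl1
  priv <- v1[v1$type == "DEL" & abs(v1$start - 8000L) < 50L, ]
  expect_identical(nrow(priv), 1L)
  expect_identical(priv$comparison_votes, 9L)
  ## germline deletion: 0 votes everywhere
  for (id in names(voted)) {
    g <- voted[[id]]
    g <- g[g$type == "DEL" & abs(g$start - 32000L) < 50L, ]
    if (nrow(g)) expect_identical(g$comparison_votes, rep(0L, nrow(g)))
  }
  ## two-carrier deletion: 8/9 votes for each carrier
  for (id in c("cl4", "cl8")) {
    s <- voted[[id]]
    s <- s[s$type == "DEL" & abs(s$start - 20000L) < 50L, ]
    expect_identical(s$comparison_votes, 8L)
  }
  ## recurrence filter keeps the mosaic calls, reports the shared one once
  kept <- recurrence_filter(voted, cfg)
  expect_identical(sum(abs(kept$start - 32000L) < 50L), 0L)  # germline gone
  shared <- kept[abs(kept$start - 20000L) < 50L, ]
  expect_identical(nrow(shared), 1L)
  expect_identical(shared$n_carriers, 2L)
  expect_setequal(strsplit(shared$carriers, ",")[[1]], c("cl4", "cl8"))
  priv_kept <- kept[abs(kept$start - 8000L) < 50L, ]
  expect_identical(nrow(priv_kept), 1L)
  expect_identical(priv_kept$carriers, "cl1")
})

test_that("pairwise voting is never symmetric for the same locus", {
  sc <- pairwise_scenario()
  ## if A's call at a locus is voted somatic against B, then B (lacking the
  ## event) cannot also hold a supported call there
  a <- call_somatic_pairwise(sc$calls$cl1, sc$reads["cl2"], cfg)
  priv <- a[a$type == "DEL" & abs(a$start - 8000L) < 50L, ]
  expect_identical(priv$comparison_votes, 1L)
  b <- sc$calls$cl2
  expect_identical(nrow(b[b$type == "DEL" & abs(b$start - 8000L) < 50L, ]), 0L)
})

test_that("recurrence threshold removes under-voted calls", {
  fake <- data.frame(sample = "cl1", type = "DEL", contig = "c", start = 1e4,
                     end = 1.1e4, contig2 = "c", pos2 = 1.1e4, orient = "RL",
                     split_support = 5L, discordant_support = 0L, bp1 = 9999,
                     bp2 = 11001, strand1 = "+", strand2 = "+",
                     comparison_votes = 3L, n_controls = 9L,
                     stringsAsFactors = FALSE)
  by_clone <- c(list(cl1 = fake),
                lapply(paste0("cl", 2:10), function(i) fake[0, ]))
  expect_identical(nrow(recurrence_filter(by_clone, cfg)), 0L)
  fake$comparison_votes <- 9L
  by_clone$cl1 <- fake
  expect_identical(nrow(recurrence_filter(by_clone, cfg)), 1L)
})

test_that("MDA artifact flagging hits injected chimera loci but not circles", {
  ref <- build_reference(55, n_contigs = 1L, contig_length = 200000L,
                         snp_density = 0)
  art <- simulate_mda_chimeras(ref, rate = 50, seed = 9, sample_id = "n1")
  loci <- attr(art, "artifact_loci")
  expect_gte(nrow(loci), 5L)
  bg <- simulate_clone_reads(ref, list(clone_spec("n1", coverage = 4)),
                             seed = 10)$n1
  recs <- rbind(bg, art)
  ist <- list(mean = 400, sd = 50)
  abn <- extract_abnormal_reads(recs, cfg, insert_stats = ist)
  cand <- cluster_breakpoints(abn, cfg, ist)
  calls <- pair_and_type(cand, ref, cfg)
  grouped <- group_adjacent_complex(calls, cfg)
  flagged <- flag_mda_artifacts(grouped, cfg)
  hit <- vapply(seq_len(nrow(loci)), function(i) {
    near <- flagged$contig == loci$contig[i] &
      (abs(flagged$bp1 - loci$inv_pos[i]) < 1500L |
         abs(flagged$bp1 - loci$dup_start[i]) < 1500L)
    any(flagged$mda_artifact[near])
  }, TRUE)
  expect_gte(mean(hit), 0.9)

  ## the reciprocal DEL+DUP circle pattern is never flagged as an artifact
  ecc <- data.frame(sample = "n1", type = c("DEL", "DUP"), contig = "c",
                    start = 5000L, end = 8000L, contig2 = "c", pos2 = 8000L,
                    orient = c("RL", "RL"), split_support = 6L,
                    discordant_support = 0L, bp1 = c(4999L, 8001L),
                    bp2 = c(8001L, 4999L), strand1 = "+", strand2 = "+",
                    stringsAsFactors = FALSE)
  ge <- flag_mda_artifacts(group_adjacent_complex(ecc, cfg), cfg)
  expect_false(any(ge$mda_artifact))
  ## and a lone simple deletion is not flagged either
  del <- ecc[1, ]
  gd <- flag_mda_artifacts(group_adjacent_complex(del, cfg), cfg)
  expect_false(any(gd$mda_artifact))
})
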
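# Shared fixture builders. Everything is generated in code at test time;
# expensive scenarios are built lazily and cached for the session.

.scen_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.scen_cache[[key]])) .scen_cache[[key]] <- builder()
  .scen_cache[[key]]
}

## a minimal alignment record row for constructed-input tests
mk_rec <- function(sample = "s1", contig = "contig1", pos = 1000L,
                   strand = "+", mlen = 150L, clip_left = 0L,
                   clip_right = 0L, seq = strrep("A", 150L),
                   mate_contig = contig, mate_pos = pos + 250L,
                   isize = 400L, proper = TRUE, mate = 1L,
                   read_id = "r1") {
  data.frame(sample = sample, read_id = read_id, mate = mate, contig = contig,
             pos = pos, strand = strand, mlen = mlen, clip_left = clip_left,
             clip_right = clip_right, seq = seq, mate_contig = mate_contig,
             mate_pos = mate_pos, isize = isize, proper = proper, mapq = 60L,
             stringsAsFactors = FALSE)
}

## proper-pair background so insert statistics are estimable
proper_background <- function(n = 150L, contig = "contig1") {
  do.call(rbind, lapply(seq_len(n), function(i)
    mk_rec(read_id = paste0("bg", i), contig = contig, pos = 1000L + 10L * i,
           isize = as.integer(round(400 + sin(i) * 40)))))
}

## random complex allele spec on a reference; segments placed apart from the
## anchor and from each other. Sizes and microhomologies follow the study
## conditions (1-5 segments of 50-2000 bp, 2-4 bp junction MH).
random_complex_spec <- function(ref, label, rng_seed, n_segments = NULL,
                                seg_range = c(50L, 2000L), mh_range = c(2L, 4L),
                                del_range = c(10L, 2000L)) {
  set.seed(rng_seed)
  lens <- nchar(ref$contigs)
  c0 <- sample(names(lens), 1L)
  if (is.null(n_segments)) n_segments <- sample(1:5, 1L)
  anchor <- sample(seq(5000L, lens[[c0]] - 5000L), 1L)
  ds <- sample(del_range[1]:del_range[2], 1L)
  used <- data.frame(contig = c0, start = anchor - 3000L,
                     end = anchor + ds + 3000L, stringsAsFactors = FALSE)
  segs <- list()
  guard <- 0L
  while (length(segs) < n_segments && guard < 200L) {
    guard <- guard + 1L
    cn <- sample(names(lens), 1L)
    w <- sample(seg_range[1]:seg_range[2], 1L)
    s <- sample(seq(3000L, lens[[cn]] - 3000L - w), 1L)
    e <- s + w - 1L
    clash <- any(used$contig == cn & used$start <= e + 100L &
                   used$end >= s - 100L)
    if (clash) next
    used <- rbind(used, data.frame(contig = cn, start = s - 100L,
                                   end = e + 100L, stringsAsFactors = FALSE))
    segs[[length(segs) + 1L]] <- data.frame(
      contig = cn, start = s, end = e,
      strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
  }
  chain <- do.call(rbind, segs)
  mh <- sample(mh_range[1]:mh_range[2], nrow(chain) + 1L, replace = TRUE)
  alt_allele_spec(label, c0, anchor, ds, chain, mh)
}

## simulate one clone carrying one allele and resolve it end to end
simulate_and_resolve <- function(seed, coverage = 30, genome_kb = 100L,
                                 ...) {
  ref <- build_reference(seed, n_contigs = 2L,
                         contig_length = genome_kb * 1000L,
                         snp_density = 5e-4)
  spec <- random_complex_spec(ref, "sv", rng_seed = seed + 1000L, ...)
  imp <- implant_sv(ref, spec)
  cl <- clone_spec("case", harbored_svs = data.frame(
    label = "sv", cell_fraction = 1, stringsAsFactors = FALSE),
    coverage = coverage)
  reads <- simulate_clone_reads(imp$ref, list(cl), list(sv = imp$truth),
                                seed = seed + 2000L)
  calls <- discover_calls(reads$case, imp$ref)
  grouped <- group_adjacent_complex(calls, pipeline_config())
  ## one implanted event per replicate: local assembly may bridge groups
  ## whose switches jump beyond the adjacency window, so resolve over every
  ## call of the sample
  res <- resolve_group(reads$case, grouped, imp$ref)
  list(ref = imp$ref, spec = spec, truth = imp$truth, reads = reads,
       calls = calls, grouped = grouped, res = res)
}

## compare a resolved model to its truth record; returns a list of logicals
model_matches_truth <- function(model, truth, tol_bp = NULL) {
  if (is.null(tol_bp)) tol_bp <- max(truth$junction_mh) + 2L
  cls_ok <- identical(sort(model$classes), sort(truth$classes))
  abs_ok <- model$absolute_size == truth$absolute_size
  mh_ok <- length(model$junction_mh) == length(truth$junction_mh) &&
    all(sort(model$junction_mh) == sort(truth$junction_mh))
  ## breakpoints: every truth junction matched by a model junction
  bp_ok <- TRUE
  tb <- truth$breakpoints; mj <- model$junctions
  for (i in seq_len(nrow(tb))) {
    hit <- any(mj$donor_contig == tb$contigA[i] &
                 mj$acc_contig == tb$contigB[i] &
                 abs(mj$donor_pos - tb$posA[i]) <= tol_bp &
                 abs(mj$acc_pos - tb$posB[i]) <= tol_bp)
    mir <- any(mj$acc_contig == tb$contigA[i] &
                 mj$donor_contig == tb$contigB[i] &
                 abs(mj$acc_pos - tb$posA[i]) <= tol_bp &
                 abs(mj$donor_pos - tb$posB[i]) <= tol_bp)
    if (!hit && !mir) bp_ok <- FALSE
  }
  list(classes = cls_ok, absolute_size = abs_ok, mh = mh_ok,
       breakpoints = bp_ok,
       all = cls_ok && abs_ok && mh_ok && bp_ok)
}

## a small multi-clone brain: one clonal complex SV shared by two clones,
## one subclonal deletion, two SV-free clones, plus tissue. Cached.
brain_scenario <- function() cached("brain", function() {
  ref <- build_reference(42, n_contigs = 2L, contig_length = 60000L,
                         snp_density = 5e-4)
  cx <- alt_allele_spec("cx", "contig1", 25000L, 13L,
    chain = data.frame(contig = c("contig1", "contig2"),
                       start = c(40000L, 9000L), end = c(40158L, 9139L),
                       strand = c("-", "+"), stringsAsFactors = FALSE),
    junction_mh = c(2L, 3L, 2L))
  i1 <- implant_sv(ref, cx)
  del <- alt_allele_spec("del", "contig2", 30000L, 900L, junction_mh = 3L)
  i2 <- implant_sv(i1$ref, del)
  ref2 <- i2$ref
  truths <- list(cx = i1$truth, del = i2$truth)
  truths$cx$carriers <- c("clone4", "clone8")
  truths$del$carriers <- "clone2"
  clones <- list(
    clone_spec("clone4", harbored_svs = data.frame(label = "cx",
      cell_fraction = 1, stringsAsFactors = FALSE), unique_snv_count = 53L),
    clone_spec("clone8", harbored_svs = data.frame(label = "cx",
      cell_fraction = 1, stringsAsFactors = FALSE), unique_snv_count = 65L),
    clone_spec("clone2", harbored_svs = data.frame(label = "del",
      cell_fraction = 0.4, stringsAsFactors = FALSE)),
    clone_spec("clone3"), clone_spec("clone5"),
    clone_spec("tissue"))
  reads <- simulate_clone_reads(ref2, clones, truths, seed = 77)
  list(ref = ref2, truths = truths, clones = clones, reads = reads)
})
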
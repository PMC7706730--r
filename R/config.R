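#' Pipeline configuration
#'
#' Returns the default parameter set used across discovery, assembly,
#' genotyping and filtering, with any named override applied. Defaults follow
#' the clone-comparison workflow: soft-clip threshold of 30 bases,
#' 2-kb windows and flanks, 50% reciprocal overlap for merging, 1000-bp
#' adjacency for complex-SV grouping, explanation-score cutoff 0.8, 200-bp
#' read-depth bins, 1-Mb assembly-gap exclusion, and the deletion/duplication
#' normalized copy-number thresholds (1.6/1.4 and 2.6/2.4 with a 0.5
#' difference and a 60% clone-panel majority).
#'
#' @param ... named overrides of individual parameters.
#' @return a list of class \code{clonesv_config}.
#' @examples
#' cfg <- pipeline_config(min_split_support = 5)
#' cfg$soft_clip_min
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    soft_clip_min      = 30L,     # bases; abnormal iff clip strictly greater
    window             = 2000L,   # bp around each event end
    discordance_sds    = 3,       # insert-size cutoff = mean + k * SD
    min_split_support  = 3L,      # reads per breakpoint cluster
    cluster_tolerance  = 10L,     # bp for clip clustering / breakpoint matching
    reciprocal_overlap = 0.5,     # fraction of BOTH spans
    adjacency          = 1000L,   # bp, complex-SV grouping
    recurrence_fraction = 0.8,    # fraction of informative comparisons
    score_threshold    = 0.8,     # explanation score, strictly-greater retained
    clip_match_identity = 0.9,    # clipped-sequence agreement for pairing
    flank              = 2000L,   # bp pseudoreference flanks
    bin_size           = 200L,    # bp read-depth bins
    gap_exclusion      = 1000000L, # bp distance from assembly gaps
    del_tissue_min     = 1.6,
    del_clone_max      = 1.4,
    cn_difference      = 0.5,
    clone_majority     = 0.6,
    dup_clone_min      = 2.6,
    dup_other_max      = 2.4,
    dup_tissue_reading = "mirror", # "mirror": tissue <= dup_other_max; "printed": tissue >= dup_other_max
    snv_rate           = 5.1,     # SNVs per day per progenitor
    pg_per_genome      = 10,      # pg DNA per diploid genome (ddPCR arithmetic)
    max_mh             = 20L,     # microhomology search limit
    min_overlap        = 20L,     # assembly suffix/prefix overlap
    max_mismatch       = 2L,      # assembly / read-consistency mismatch budget
    seed_k             = 15L,     # contig-alignment seed k-mer
    min_identity       = 0.9,     # contig-alignment identity floor
    min_align_len      = 20L,     # shortest reported contig alignment
    map_margin         = 5L,      # unique-mapping score margin
    chain_min_cover    = 0.95     # contig fraction a chain must explain
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config parameter(s): ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  structure(cfg, class = "clonesv_config")
}
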
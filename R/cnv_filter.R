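#' Read-depth post-filter for CNV-supported calls
#'
#' Applies the normalized copy-number criteria to one deletion or
#' duplication call. A deletion passes iff tissue CN >= 1.6, clone CN <=
#' 1.4, tissue - clone >= 0.5, at least 60% of the other same-brain clones
#' have CN >= 1.6, and the call is more than 1 Mb from any assembly gap.
#' Duplications mirror the logic with the 2.6/2.4 thresholds (clone CN >=
#' 2.6, at least 60% of other clones below 2.4, and — under the default
#' mirror-consistent reading — tissue CN <= 2.4; the config switch
#' \code{dup_tissue_reading = "printed"} requires tissue CN >= 2.4
#' instead). Every failure lists the violated clause.
#'
#' @param profiles data.frame from \code{\link{depth_profile}} covering the
#'   case clone, the tissue and the clone panel.
#' @param call list(type = "DEL"|"DUP", contig, start, end).
#' @param config a \code{\link{pipeline_config}}.
#' @param clone,tissue sample names of the case clone and the bulk tissue.
#' @param panel character vector of the other same-brain clones; NULL uses
#'   every profiled sample except \code{clone} and \code{tissue}.
#' @param gaps data.frame(contig, start, end) of assembly gaps.
#' @return list(pass, reasons, clone_cn, tissue_cn, panel_fraction).
#' @export
cnv_depth_filter <- function(profiles, call, config = pipeline_config(),
                             clone, tissue, panel = NULL, gaps = NULL) {
  if (is.null(panel))
    panel <- setdiff(unique(profiles$sample), c(clone, tissue))
  mean_cn <- function(sid) {
    d <- profiles[profiles$sample == sid & profiles$contig == call$contig &
                    profiles$bin_start <= call$end &
                    profiles$bin_end >= call$start, , drop = FALSE]
    if (!nrow(d)) return(NA_real_)
    mean(d$cn)
  }
  clone_cn <- mean_cn(clone)
  tissue_cn <- mean_cn(tissue)
  panel_cn <- vapply(panel, mean_cn, 0)
  if (anyNA(c(clone_cn, tissue_cn)) || anyNA(panel_cn) || !length(panel_cn))
    return(list(pass = FALSE, reasons = "insufficient panel",
                clone_cn = clone_cn, tissue_cn = tissue_cn,
                panel_fraction = NA_real_))
  reasons <- character(0)
  if (call$type == "DEL") {
    if (tissue_cn < config$del_tissue_min)
      reasons <- c(reasons, sprintf("tissue CN %.2f < %.1f", tissue_cn,
                                    config$del_tissue_min))
    if (clone_cn > config$del_clone_max)
      reasons <- c(reasons, sprintf("clone CN %.2f > %.1f", clone_cn,
                                    config$del_clone_max))
    if (tissue_cn - clone_cn < config$cn_difference)
      reasons <- c(reasons, sprintf("tissue - clone %.2f < %.1f",
                                    tissue_cn - clone_cn, config$cn_difference))
    frac <- mean(panel_cn >= config$del_tissue_min)
    if (frac < config$clone_majority)
      reasons <- c(reasons, sprintf("only %.0f%% of other clones have CN >= %.1f",
                                    100 * frac, config$del_tissue_min))
  } else if (call$type == "DUP") {
    if (clone_cn < config$dup_clone_min)
      reasons <- c(reasons, sprintf("clone CN %.2f < %.1f", clone_cn,
                                    config$dup_clone_min))
    if (config$dup_tissue_reading == "mirror") {
      if (tissue_cn > config$dup_other_max)
        reasons <- c(reasons, sprintf("tissue CN %.2f > %.1f", tissue_cn,
                                      config$dup_other_max))
    } else {
      if (tissue_cn < config$dup_other_max)
        reasons <- c(reasons, sprintf("tissue CN %.2f < %.1f", tissue_cn,
                                      config$dup_other_max))
    }
    if (clone_cn - tissue_cn < config$cn_difference)
      reasons <- c(reasons, sprintf("clone - tissue %.2f < %.1f",
                                    clone_cn - tissue_cn, config$cn_difference))
    frac <- mean(panel_cn < config$dup_other_max)
    if (frac < config$clone_majority)
      reasons <- c(reasons, sprintf("only %.0f%% of other clones below %.1f",
                                    100 * frac, config$dup_other_max))
  } else stop("cnv_depth_filter handles DEL and DUP calls only")
  if (!is.null(gaps) && nrow(gaps)) {
    g <- gaps[gaps$contig == call$contig, , drop = FALSE]
    if (nrow(g)) {
      dist <- pmax(0L, pmax(g$start - call$end, call$start - g$end))
      if (any(dist <= config$gap_exclusion))
        reasons <- c(reasons, sprintf("within %d bp of an assembly gap",
                                      config$gap_exclusion))
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons, clone_cn = clone_cn,
       tissue_cn = tissue_cn, panel_fraction = frac)
}
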
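# Lineage timing from clone-unique SNV counts, discovery-sensitivity
# estimation, droplet digital PCR allele-frequency statistics, and the
# incidence comparison test.

#' Time the divergence of two clones from their unique SNV counts
#'
#' SNVs unique to each of two clones sharing an SV arose after their common
#' ancestor divided; with a constant accumulation rate, the mean unique
#' count over the rate gives the time back to the divergence.
#'
#' @param n1,n2 SNV counts unique to each clone.
#' @param rate somatic SNV accumulation rate per day per progenitor
#'   (default 5.1).
#' @return a \code{TimingEstimate}: list(divergence_days, divergence_weeks
#'   (raw), divergence_weeks_rounded (half-up), inputs).
#' @examples
#' divergence_time(53, 65)   # ~11.6 days, reported as ~2 weeks
#' @export
divergence_time <- function(n1, n2, rate = 5.1) {
  if (rate <= 0) stop("rate must be positive")
  if (n1 < 0 || n2 < 0) stop("SNV counts must be non-negative")
  days <- mean(c(n1, n2)) / rate
  weeks <- days / 7
  structure(list(divergence_days = days, divergence_weeks = weeks,
                 divergence_weeks_rounded = floor(weeks + 0.5),
                 inputs = list(n1 = n1, n2 = n2, rate = rate)),
            class = "TimingEstimate")
}

#' @export
print.TimingEstimate <- function(x, ...) {
  cat(sprintf("Divergence ~%.2f days (= %.2f wk, reported as ~%d wk) from N1 = %d, N2 = %d at %.1f SNVs/day\n",
              x$divergence_days, x$divergence_weeks,
              x$divergence_weeks_rounded, x$inputs$n1, x$inputs$n2,
              x$inputs$rate))
  invisible(x)
}

#' Time the origin of a shared SV
#'
#' @param harvest_weeks_pc age at cell harvest, weeks postconception.
#' @param timing a \code{TimingEstimate}.
#' @return list(origin_weeks (raw), origin_weeks_rounded).
#' @examples
#' origin_time(16, divergence_time(53, 65))   # ~14 wk postconception
#' @export
origin_time <- function(harvest_weeks_pc, timing) {
  raw <- harvest_weeks_pc - timing$divergence_weeks
  rounded <- harvest_weeks_pc - timing$divergence_weeks_rounded
  if (raw < 0) stop("divergence predates conception: inputs inconsistent")
  if (raw == 0) warning("origin at conception is implausible")
  list(origin_weeks = raw, origin_weeks_rounded = rounded)
}

#' Estimate discovery sensitivity against a two-bulk truth set
#'
#' The truth set is the reciprocal-overlap intersection of two independent
#' bulk call sets; each clone's sensitivity is the fraction of truth-set
#' entries recovered (reciprocally) among its own calls.
#'
#' @param clone_calls named list of call data.frames (contig, start, end,
#'   type) per clone.
#' @param bulk1_calls,bulk2_calls bulk call data.frames.
#' @param config a \code{\link{pipeline_config}} (reciprocal_overlap).
#' @return a \code{SensitivityReport}: list(truth_set, per_clone,
#'   mean_sensitivity).
#' @export
estimate_sensitivity <- function(clone_calls, bulk1_calls, bulk2_calls,
                                 config = pipeline_config()) {
  frac <- config$reciprocal_overlap
  matches <- function(x, set) {
    vapply(seq_len(nrow(x)), function(i) {
      any(set$contig == x$contig[i] &
            vapply(seq_len(nrow(set)), function(j)
              set$contig[j] == x$contig[i] &&
                reciprocal_fraction(x$start[i], x$end[i],
                                    set$start[j], set$end[j]) >= frac, TRUE))
    }, TRUE)
  }
  truth <- bulk1_calls[nrow(bulk1_calls) > 0 &
                         matches(bulk1_calls, bulk2_calls), , drop = FALSE]
  if (!nrow(truth))
    return(structure(list(truth_set = truth, per_clone = numeric(0),
                          mean_sensitivity = NA_real_),
                     class = "SensitivityReport"))
  per_clone <- vapply(clone_calls, function(cc) {
    if (is.null(cc) || !nrow(cc)) return(0)
    mean(matches(truth, cc))
  }, 0)
  structure(list(truth_set = truth, per_clone = per_clone,
                 mean_sensitivity = mean(per_clone)),
            class = "SensitivityReport")
}

#' @export
print.SensitivityReport <- function(x, ...) {
  cat("SensitivityReport: truth set of", nrow(x$truth_set), "SVs; mean",
      sprintf("%.3f", x$mean_sensitivity), "over", length(x$per_clone),
      "clone(s)\n")
  invisible(x)
}

## Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Droplet digital PCR allele frequency with confidence interval
#'
#' Droplet occupancy follows a Poisson law: with k positive of n droplets
#' the copies-per-droplet concentration is lambda = -ln(1 - k/n); the SV
#' allele frequency is the ratio of the variant-channel to the
#' reference-channel concentration. The 95% CI propagates the Wilson
#' binomial interval of each channel's positive fraction through the
#' lambda transform, combining the channels as independent errors on the
#' log-ratio scale.
#'
#' @param var_pos,var_total variant-channel positive and total droplets.
#' @param ref_pos,ref_total reference-channel positive and total droplets.
#' @param conf confidence level.
#' @return a \code{DdpcrResult}: list(lambda_var, lambda_ref,
#'   allele_fraction, ci (lower/upper), counts).
#' @examples
#' ddpcr_af(50, 20000, 10000, 20000)
#' @export
ddpcr_af <- function(var_pos, var_total, ref_pos, ref_total, conf = 0.95) {
  if (var_total <= 0 || ref_total <= 0) stop("droplet totals must be positive")
  if (var_pos > var_total || ref_pos > ref_total)
    stop("positives cannot exceed totals")
  if (var_pos == var_total || ref_pos == ref_total)
    stop("saturated assay: all droplets positive")
  if (ref_pos == 0) stop("no reference-channel signal")
  lam <- function(k, n) -log(1 - k / n)
  lv <- lam(var_pos, var_total)
  lr <- lam(ref_pos, ref_total)
  af <- lv / lr
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ## transform each channel's Wilson bounds through lambda
  wv <- wilson_ci(var_pos, var_total, conf)
  wr <- wilson_ci(ref_pos, ref_total, conf)
  lv_ci <- -log(1 - wv)
  lr_ci <- -log(1 - wr)
  if (var_pos == 0) {
    lower <- 0
    upper <- lv_ci["upper"] / lr_ci["lower"]
    af <- 0
  } else {
    ## independent propagation on the log scale
    se_lv <- (log(lv_ci["upper"]) - log(lv_ci["lower"])) / (2 * z)
    se_lr <- (log(lr_ci["upper"]) - log(lr_ci["lower"])) / (2 * z)
    se <- sqrt(se_lv^2 + se_lr^2)
    lower <- exp(log(af) - z * se)
    upper <- exp(log(af) + z * se)
  }
  structure(list(lambda_var = lv, lambda_ref = lr, allele_fraction = af,
                 ci = c(lower = unname(lower), upper = unname(upper)),
                 counts = list(var_pos = var_pos, var_total = var_total,
                               ref_pos = ref_pos, ref_total = ref_total)),
            class = "DdpcrResult")
}

#' @export
print.DdpcrResult <- function(x, ...) {
  cat(sprintf("ddPCR AF %.4g%% (95%% CI %.4g%% - %.4g%%); lambda var %.4g, ref %.4g\n",
              100 * x$allele_fraction, 100 * x$ci["lower"], 100 * x$ci["upper"],
              x$lambda_var, x$lambda_ref))
  invisible(x)
}

#' Maximum sensitivity of a ddPCR assay from input mass
#'
#' @param input_ng DNA input in nanograms.
#' @param pg_per_genome picograms of DNA per diploid genome. The default 10
#'   reproduces the standard 40 ng to 4000 genome-equivalents arithmetic;
#'   the textbook diploid value is ~6.6 pg.
#' @return list(genome_equivalents, min_detectable_fraction_pct).
#' @examples
#' ddpcr_max_sensitivity(40)   # 4000 genomes, 0.025%
#' @export
ddpcr_max_sensitivity <- function(input_ng, pg_per_genome = 10) {
  if (input_ng <= 0 || pg_per_genome <= 0) stop("inputs must be positive")
  ge <- input_ng * 1000 / pg_per_genome
  list(genome_equivalents = ge, min_detectable_fraction_pct = 100 / ge)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with the standard minimum-likelihood two-sided
#' convention: the p-value sums the probabilities of all tables with the
#' same margins whose probability does not exceed that of the observed
#' table (within a relative tolerance of 1e-7, as customary).
#'
#' @param a,b,c,d the 2x2 table counts (rows = groups, columns = outcome).
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_two_sided(4, 37, 0, 36)
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  if (a + b + c + d == 0) stop("empty table")
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
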
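# Variant- and sample-level QC: allele-fraction plausibility band and
# coverage-depth tiers.

#' QC configuration
#'
#' Germline heterozygous calls are expected near 50% allele fraction; the
#' plausibility band (inclusive) flags calls outside 30-75%. Coverage tiers
#' count samples above/below the high/low mean-depth marks.
#'
#' @param vaf_min,vaf_max Inclusive allele-fraction band (defaults 0.30,
#'   0.75).
#' @param coverage_high,coverage_low Depth tier marks (defaults 100, 30).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(vaf_min = 0.30, vaf_max = 0.75,
                      coverage_high = 100, coverage_low = 30) {
  if (!(vaf_min >= 0 && vaf_min < vaf_max && vaf_max <= 1))
    stop("need 0 <= vaf_min < vaf_max <= 1")
  structure(list(vaf_min = vaf_min, vaf_max = vaf_max,
                 coverage_high = coverage_high, coverage_low = coverage_low),
            class = "qc_config")
}

#' Check an allele fraction against the plausibility band
#'
#' Flags annotate but never drop a variant; homozygous-looking calls
#' (VAF near 1) are flagged for review, not removed.
#'
#' @param vaf Numeric vector of allele fractions in [0, 1].
#' @param cfg A [qc_config()].
#' @return Character vector: "pass" or "out_of_band".
#' @export
vaf_check <- function(vaf, cfg = qc_config()) {
  if (any(is.na(vaf)) || any(vaf < 0 | vaf > 1))
    stop("VAF must lie in [0, 1]")
  ifelse(vaf >= cfg$vaf_min & vaf <= cfg$vaf_max, "pass", "out_of_band")
}

#' Summarize per-sample mean coverage depths
#'
#' Counts samples strictly above the high mark ("more than 100X") and
#' strictly below the low mark ("less than 30X").
#'
#' @param depths Numeric vector of per-sample mean depths.
#' @param cfg A [qc_config()].
#' @return list: n_samples, n_over_high, n_under_low, min, max, mean.
#' @export
coverage_summary <- function(depths, cfg = qc_config()) {
  if (length(depths) == 0)
    return(list(n_samples = 0L, n_over_high = 0L, n_under_low = 0L,
                min = NA_real_, max = NA_real_, mean = NA_real_))
  if (any(is.na(depths)) || any(depths < 0)) stop("depths must be >= 0")
  list(n_samples = length(depths),
       n_over_high = sum(depths > cfg$coverage_high),
       n_under_low = sum(depths < cfg$coverage_low),
       min = min(depths), max = max(depths), mean = mean(depths))
}
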
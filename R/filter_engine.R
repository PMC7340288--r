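# Region-stratified filtering cascade with per-stage accounting:
# region split -> frequency -> region-specific stage (ClinVar prefilter for
# exons, splice-category requirement for deep introns).

#' Filtering configuration
#'
#' Frequency cut-offs are strict upper bounds ("less than"), matching the
#' diagnostic convention that a boundary value is not rare enough; variants
#' with no population frequency are retained by default.
#'
#' @param freq_max_exonic,freq_max_intronic,freq_max_splice Maximum gnomAD
#'   fraction for exonic / deep-intronic / splice-neighbourhood variants
#'   (default 0.001, i.e. 0.1%).
#' @param freq_max_utr Maximum fraction for UTR variants (default 0.0001,
#'   i.e. 0.01% - the stricter UTR filter).
#' @param keep_missing_frequency Retain variants absent from gnomAD
#'   (default TRUE).
#' @param clinvar_drop ClinVar statuses that drop an exonic variant at the
#'   prefilter stage.
#' @param clinvar_prefilter_regions Regions the ClinVar prefilter applies
#'   to (default exonic only).
#' @param splice_categories_required Splice-event flags, at least one of
#'   which a deep-intronic variant must carry to be retained.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(freq_max_exonic = 0.001,
                          freq_max_intronic = 0.001,
                          freq_max_splice = 0.001,
                          freq_max_utr = 0.0001,
                          keep_missing_frequency = TRUE,
                          clinvar_drop = c("benign", "likely_benign"),
                          clinvar_prefilter_regions = "EXON",
                          splice_categories_required =
                            c("new_donor", "new_acceptor",
                              "cryptic_strong_activation")) {
  fr <- c(freq_max_exonic, freq_max_intronic, freq_max_splice, freq_max_utr)
  if (any(fr < 0 | fr > 1)) stop("frequency thresholds must lie in [0,1]")
  structure(list(freq_max_exonic = freq_max_exonic,
                 freq_max_intronic = freq_max_intronic,
                 freq_max_splice = freq_max_splice,
                 freq_max_utr = freq_max_utr,
                 keep_missing_frequency = keep_missing_frequency,
                 clinvar_drop = clinvar_drop,
                 clinvar_prefilter_regions = clinvar_prefilter_regions,
                 splice_categories_required = splice_categories_required),
            class = "filter_config")
}

.region_freq_max <- function(region, cfg) {
  switch(region,
         EXON = cfg$freq_max_exonic,
         INTRON_DEEP = cfg$freq_max_intronic,
         INTRON_SPLICE = cfg$freq_max_splice,
         UTR5 = , UTR3 = cfg$freq_max_utr,
         stop("unknown region: ", region))
}

#' Region-specific population-frequency filter
#'
#' @param gnomad_af gnomAD allele fraction (NA when absent).
#' @param region Region class string.
#' @param cfg A [filter_config()].
#' @return list(retain = logical, reason = character) - reason is "" when
#'   retained.
#' @export
frequency_filter <- function(gnomad_af, region, cfg = filter_config()) {
  if (is.na(region)) stop("region must be set before frequency filtering")
  if (is.na(gnomad_af)) {
    if (cfg$keep_missing_frequency) return(list(retain = TRUE, reason = ""))
    return(list(retain = FALSE, reason = "no_frequency"))
  }
  if (gnomad_af < .region_freq_max(region, cfg))
    list(retain = TRUE, reason = "")
  else
    list(retain = FALSE, reason = "frequency")
}

#' ClinVar benign/likely-benign prefilter (exonic stage)
#'
#' @param clinvar_status ClinVar status string.
#' @param cfg A [filter_config()].
#' @return list(retain, reason).
#' @export
clinvar_prefilter <- function(clinvar_status, cfg = filter_config()) {
  if (!is.na(clinvar_status) && clinvar_status %in% cfg$clinvar_drop)
    list(retain = FALSE, reason = "clinvar_benign")
  else
    list(retain = TRUE, reason = "")
}

#' Splice-category filter for intronic variants
#'
#' Splice-neighbourhood variants bypass the category requirement (they are
#' retained for junction-deactivation review); deep-intronic variants are
#' retained only when flagged as a new donor/acceptor site or a strong
#' cryptic-site activation.
#'
#' @param region "INTRON_SPLICE" or "INTRON_DEEP".
#' @param events Character vector of splice-event flags for the variant
#'   (from splice scoring or annotation).
#' @param cfg A [filter_config()].
#' @return list(retain, reason).
#' @export
splice_category_filter <- function(region, events, cfg = filter_config()) {
  if (region == "INTRON_SPLICE") return(list(retain = TRUE, reason = ""))
  if (region != "INTRON_DEEP") stop("splice filter applies to introns only")
  if (is.null(events))
    stop("deep-intronic variant lacks a splice evaluation")
  if (any(events %in% cfg$splice_categories_required))
    list(retain = TRUE, reason = "")
  else
    list(retain = FALSE, reason = "no_splice_category")
}

#' Run the region-stratified filtering cascade
#'
#' Stages in order: region_split (accounting only), frequency (region
#' thresholds), clinvar_prefilter (exonic), splice_category (intronic).
#' Every variant receives a complete decision trail; at every stage
#' retained + dropped = input.
#'
#' @param variants data.frame with at least `cnomen`, `region`, `gnomad_af`,
#'   `clinvar_status`, `splice_events` (comma/semicolon-separated flags or
#'   "") columns. One row per distinct variant.
#' @param cfg A [filter_config()].
#' @return An object of class `filter_report`: list with `input_counts`
#'   (per region), `stages` (per-stage per-region retained/dropped),
#'   `retained` (final data.frame), `trail` (per-variant decisions).
#' @export
run_cascade <- function(variants, cfg = filter_config()) {
  regions <- c("EXON", "INTRON_SPLICE", "INTRON_DEEP", "UTR5", "UTR3")
  if (nrow(variants) > 0 && any(is.na(variants$region)))
    stop("all variants must be region-classified before the cascade")
  input_counts <- table(factor(variants$region, levels = regions))

  trail <- data.frame(cnomen = character(), stage = character(),
                      verdict = character(), reason = character(),
                      stringsAsFactors = FALSE)
  note <- function(cn, stage, verdict, reason) {
    trail[nrow(trail) + 1L, ] <<- list(cn, stage, verdict, reason)
  }

  ev_list <- if (is.null(variants$splice_events)) {
    rep(list(character()), nrow(variants))
  } else {
    lapply(variants$splice_events, function(s) {
      if (is.na(s) || s == "") character()
      else strsplit(s, "[,;|]")[[1]]
    })
  }

  keep <- rep(TRUE, nrow(variants))
  stage_counts <- list()
  count_stage <- function(name, before, after, region_sel) {
    data.frame(stage = name, input = sum(before & region_sel),
               retained = sum(after & region_sel),
               dropped = sum(before & region_sel) - sum(after & region_sel))
  }

  for (i in seq_len(nrow(variants)))
    note(variants$cnomen[i], "region_split", "retain", variants$region[i])
  stage_counts$region_split <- data.frame(
    stage = "region_split", input = nrow(variants),
    retained = nrow(variants), dropped = 0L)

  # frequency stage (all regions)
  before <- keep
  for (i in which(keep)) {
    r <- frequency_filter(variants$gnomad_af[i], variants$region[i], cfg)
    note(variants$cnomen[i], "frequency",
         if (r$retain) "retain" else "drop", r$reason)
    if (!r$retain) keep[i] <- FALSE
  }
  stage_counts$frequency <- count_stage("frequency", before, keep, TRUE)

  # exonic ClinVar prefilter
  sel <- variants$region %in% cfg$clinvar_prefilter_regions
  before <- keep
  for (i in which(keep & sel)) {
    st <- if (is.null(variants$clinvar_status)) NA_character_
          else variants$clinvar_status[i]
    r <- clinvar_prefilter(st, cfg)
    note(variants$cnomen[i], "clinvar_prefilter",
         if (r$retain) "retain" else "drop", r$reason)
    if (!r$retain) keep[i] <- FALSE
  }
  stage_counts$clinvar_prefilter <-
    count_stage("clinvar_prefilter", before, keep, sel)

  # intronic splice-category stage
  sel <- variants$region %in% c("INTRON_SPLICE", "INTRON_DEEP")
  before <- keep
  for (i in which(keep & sel)) {
    r <- splice_category_filter(variants$region[i], ev_list[[i]], cfg)
    note(variants$cnomen[i], "splice_category",
         if (r$retain) "retain" else "drop", r$reason)
    if (!r$retain) keep[i] <- FALSE
  }
  stage_counts$splice_category <-
    count_stage("splice_category", before, keep, sel)

  retained <- variants[keep, , drop = FALSE]
  rownames(retained) <- NULL
  report <- list(
    input_counts = input_counts,
    stages = do.call(rbind, stage_counts),
    retained = retained,
    retained_counts = table(factor(retained$region, levels = regions)),
    trail = trail,
    config = cfg)
  class(report) <- "filter_report"
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filtering cascade report\n")
  cat("  input per region:  ",
      paste(names(x$input_counts), as.integer(x$input_counts),
            sep = "=", collapse = "  "), "\n")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  stage %-18s input %5d  retained %5d  dropped %5d\n",
                x$stages$stage[i], x$stages$input[i],
                x$stages$retained[i], x$stages$dropped[i]))
  cat("  final retained:    ", nrow(x$retained), "\n")
  invisible(x)
}

#' Export a filter report
#'
#' @param report A `filter_report`.
#' @param json,tsv Optional output paths for the stage summary (JSON) and
#'   the decision trail (TSV).
#' @return The report, invisibly.
#' @export
export_filter_report <- function(report, json = NULL, tsv = NULL) {
  if (!is.null(json))
    jsonlite::write_json(list(
      input_counts = as.list(report$input_counts),
      stages = report$stages,
      retained_counts = as.list(report$retained_counts)),
      json, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv))
    utils::write.table(report$trail, tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(report)
}
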
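# Orchestration: load -> region classify -> cascade -> splice annotation ->
# ACMG classification -> cohort summary.

.CORE_LS_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2")

.round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Summarize classified variants over a cohort
#'
#' Distinct variants count once in variant tallies; a variant carried by
#' several patients counts once per patient in patient tallies. The
#' pathogenic-carrier percentage is computed against the configured cohort
#' size and rounded half-up to one decimal.
#'
#' @param variants data.frame of classified distinct variants with
#'   `region`, `acmg_class`, `gene_symbol` and `sample_id` (comma-separated
#'   for shared variants) columns.
#' @param cohort_size Number of patients in the cohort.
#' @return list of class `cohort_summary`.
#' @export
summarize_cohort <- function(variants, cohort_size) {
  regions <- c("EXON", "INTRON_SPLICE", "INTRON_DEEP", "UTR5", "UTR3")
  ids <- strsplit(variants$sample_id, ",", fixed = TRUE)
  patients <- unique(unlist(ids))
  if (cohort_size < length(patients))
    stop("cohort_size (", cohort_size, ") smaller than the number of ",
         "distinct patients (", length(patients), ")")
  by_region <- table(factor(variants$region, levels = regions))
  by_class <- table(factor(variants$acmg_class, levels = 1:5))
  core <- variants$gene_symbol %in% .CORE_LS_GENES
  ge4 <- variants$acmg_class >= 4
  patients_ge4 <- unique(unlist(ids[ge4]))
  per_patient <- table(unlist(ids))
  out <- list(
    n_variants = nrow(variants),
    n_by_region = by_region,
    n_intronic = sum(by_region[c("INTRON_SPLICE", "INTRON_DEEP")]),
    n_splice_neighbourhood = unname(by_region["INTRON_SPLICE"]),
    n_utr = sum(by_region[c("UTR5", "UTR3")]),
    n_by_class = by_class,
    n_core_ls_genes = sum(core),
    n_additional_genes = sum(!core),
    n_patients_with_reported_variant = length(patients),
    n_patients_with_class_ge4 = length(patients_ge4),
    pct_patients_class_ge4 =
      .round_half_up(100 * length(patients_ge4) / cohort_size, 1),
    per_patient_counts = per_patient,
    cohort_size = cohort_size)
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (", x$cohort_size, " patients)\n", sep = "")
  cat("  variants: ", x$n_variants, " (",
      paste(names(x$n_by_region), as.integer(x$n_by_region), sep = "=",
            collapse = " "), ")\n", sep = "")
  cat("  classes:  ",
      paste("class", names(x$n_by_class), "=", as.integer(x$n_by_class),
            collapse = "  "), "\n")
  cat("  genes:    core-LS =", x$n_core_ls_genes, " additional =",
      x$n_additional_genes, "\n")
  cat("  patients: ", x$n_patients_with_reported_variant,
      "with a reported variant;", x$n_patients_with_class_ge4,
      "with class >= 4 (", x$pct_patients_class_ge4, "% of cohort )\n")
  invisible(x)
}

# verify summary counts are recomputable from the per-variant rows
.verify_summary <- function(summary, variants) {
  stopifnot(
    summary$n_variants == nrow(variants),
    sum(summary$n_by_class) == nrow(variants),
    summary$n_core_ls_genes + summary$n_additional_genes == nrow(variants))
  invisible(TRUE)
}

#' Run the prioritization pipeline on the packaged reference fixture
#'
#' Loads the packaged 35-variant fixture, runs the region-stratified
#' cascade, classifies every retained variant with the ACMG engine and
#' summarizes at the study cohort size.
#'
#' @param cohort_size Cohort size for patient-level percentages
#'   (default 199).
#' @param filter_cfg,acmg_cfg Configurations.
#' @return list: `report` (filter_report), `classified` (data.frame with
#'   evidence and acmg_class), `summary` (cohort_summary).
#' @export
run_pipeline_fixture <- function(cohort_size = 199,
                                 filter_cfg = filter_config(),
                                 acmg_cfg = acmg_config()) {
  fixture <- load_table2_fixture()
  report <- run_cascade(fixture, filter_cfg)
  classified <- classify_variants(report$retained, acmg_cfg)
  summary <- summarize_cohort(classified, cohort_size)
  .verify_summary(summary, classified)
  list(report = report, classified = classified, summary = summary)
}

#' Run the prioritization pipeline on a cohort call set
#'
#' Stages: merge calls with annotations, reduce to distinct variants,
#' region-classify from HGVS c. names, evaluate splice impact of intronic
#' substitutions against panel-trained matrices, run the filtering cascade,
#' classify retained variants and summarize.
#'
#' @param vcf_records Per-carrier calls (data.frame from [read_vcf()] or
#'   [generate_cohort()]).
#' @param annotations Per-variant annotation table (data.frame from
#'   [read_annotation_table()] or [generate_cohort()]; raw `gnomad` /
#'   `clinvar` / `insilico` text columns are parsed if present).
#' @param panel Named list of `mmr_transcript` objects with sequences.
#' @param cohort_size Number of patients (default: distinct sample ids).
#' @param filter_cfg,acmg_cfg,splice_cfg Configurations.
#' @param matrices Splice matrices; default estimated from the panel.
#' @return list: `report`, `classified`, `summary`, `variants` (distinct
#'   annotated variants before filtering).
#' @export
run_pipeline <- function(vcf_records, annotations, panel,
                         cohort_size = NULL,
                         filter_cfg = filter_config(),
                         acmg_cfg = acmg_config(),
                         splice_cfg = splice_config(),
                         matrices = NULL) {
  if (is.null(cohort_size))
    cohort_size <- length(unique(vcf_records$sample_id))
  ann <- annotations
  if (!is.null(ann$gnomad)) {
    ann$gnomad_af <- parse_gnomad_freq(ann$gnomad); ann$gnomad <- NULL
  }
  if (!is.null(ann$clinvar)) {
    ann <- cbind(ann, parse_clinvar_cell(ann$clinvar)); ann$clinvar <- NULL
  }
  if (!is.null(ann$insilico) && is.character(ann$insilico))
    ann <- cbind(ann, .parse_insilico(ann$insilico))
  if (!is.null(ann$gene) && is.null(ann$gene_symbol))
    names(ann)[names(ann) == "gene"] <- "gene_symbol"
  if (!is.null(ann$transcript) && is.null(ann$transcript_id))
    names(ann)[names(ann) == "transcript"] <- "transcript_id"

  merged <- merge_annotations(vcf_records, ann, by = "position")

  # distinct variants with their carrier lists
  key <- paste(merged$chrom, merged$gpos, merged$ref, merged$alt)
  first <- !duplicated(key)
  variants <- merged[first, , drop = FALSE]
  carriers <- vapply(split(merged$sample_id, key), function(s)
    paste(sort(unique(s)), collapse = ","), character(1))
  variants$sample_id <- unname(carriers[key[first]])
  rownames(variants) <- NULL

  rc <- classify_regions(variants$cnomen)
  variants$region <- rc$region
  variants$splice_distance <- rc$splice_distance
  if (is.null(variants$consequence))
    variants$consequence <- consequence_from_pnomen(variants$pnomen)

  # splice evaluation for intronic substitutions
  if (is.null(matrices)) matrices <- estimate_splice_matrices(panel)
  variants$splice_delta <- NA_real_
  variants$splice_events <- ""
  intronic <- which(variants$region %in% c("INTRON_SPLICE", "INTRON_DEEP"))
  for (i in intronic) {
    tx <- panel[[variants$transcript_id[i]]]
    if (is.null(tx) || is.null(tx$seq)) next
    ev <- tryCatch(
      evaluate_variant(tx, parse_hgvs_c(variants$cnomen[i]), matrices,
                       splice_cfg),
      error = function(e) NULL)
    if (is.null(ev)) next
    variants$splice_delta[i] <- ev$delta
    variants$splice_events[i] <- paste(ev$events, collapse = ",")
  }

  report <- run_cascade(variants, filter_cfg)
  classified <- classify_variants(report$retained, acmg_cfg)
  vf <- rep(NA_character_, nrow(classified))
  ok <- !is.na(classified$vaf)
  vf[ok] <- vaf_check(pmin(1, pmax(0, classified$vaf[ok])))
  classified$vaf_flag <- vf
  summary <- summarize_cohort(classified, cohort_size)
  .verify_summary(summary, classified)
  list(report = report, classified = classified, summary = summary,
       variants = variants)
}
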
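# ACMG/AMP evidence derivation and 5-class combination.

.ACMG_CODES <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6),
                 paste0("PP", 1:5), "BA1", paste0("BS", 1:4),
                 paste0("BP", 1:7))

#' Evidence-derivation thresholds
#'
#' @param pm2_freq_max Named fractions per region below which (or when
#'   absent) a variant counts as absent/rare in controls (PM2); defaults
#'   mirror the filtering thresholds.
#' @param ba1_freq Stand-alone benign frequency (default 0.05).
#' @param bs1_freq Strong benign frequency (default 0.001).
#' @param pp3_min_deleterious Minimum concordant deleterious in-silico
#'   calls for PP3 / tolerated calls for BP4 (default 2).
#' @param canonical_splice_max Maximum |intron offset| for a splice
#'   disruption to count as canonical, PVS1-level (default 2).
#' @param deactivation_delta Nearest-splice-site change at or below which a
#'   canonical site counts as disrupted (default -0.1).
#' @return list of thresholds.
#' @export
acmg_config <- function(pm2_freq_max = c(EXON = 0.001, INTRON_SPLICE = 0.001,
                                         INTRON_DEEP = 0.001, UTR5 = 0.0001,
                                         UTR3 = 0.0001),
                        ba1_freq = 0.05, bs1_freq = 0.001,
                        pp3_min_deleterious = 2L,
                        canonical_splice_max = 2L,
                        deactivation_delta = -0.1) {
  list(pm2_freq_max = pm2_freq_max, ba1_freq = ba1_freq, bs1_freq = bs1_freq,
       pp3_min_deleterious = pp3_min_deleterious,
       canonical_splice_max = canonical_splice_max,
       deactivation_delta = deactivation_delta)
}

#' Derive ACMG evidence codes for one variant
#'
#' Deterministic, independent rules: PVS1 for null variants (nonsense,
#' frameshift) or canonical +/-1/2 splice-site deactivation; PM2 for
#' variants absent from or rare in gnomAD (region threshold); PP3/BP4 for
#' concordant in-silico predictions; PP5/BP6 for reported ClinVar
#' assertions; PS3/BS3 for well-established functional evidence; BA1/BS1
#' for common variants. Absent inputs simply yield no code.
#'
#' @param v List or one-row data.frame with (any of) `gnomad_af`, `region`,
#'   `clinvar_status`, `clinvar_n`, `insilico_deleterious`,
#'   `insilico_tolerated`, `functional_evidence`, `splice_distance`.
#' @param consequence Consequence kind string (e.g. "nonsense") or a list
#'   with `$kind`.
#' @param splice_eval Splice evaluation (list with `delta`, `events`) or
#'   NULL.
#' @param cfg An [acmg_config()].
#' @return Character vector of evidence codes.
#' @export
derive_evidence <- function(v, consequence = NULL, splice_eval = NULL,
                            cfg = acmg_config()) {
  g <- function(f) if (!is.null(v[[f]]) && length(v[[f]]) == 1 &&
                       !is.na(v[[f]])) v[[f]] else NA
  codes <- character()
  kind <- if (is.list(consequence)) consequence$kind else consequence

  # PVS1: null variant or canonical-site splice deactivation
  null_var <- !is.null(kind) && !is.na(kind) &&
    kind %in% c("nonsense", "frameshift")
  canon_splice <- FALSE
  sd <- g("splice_distance")
  if (!is.na(sd) && sd <= cfg$canonical_splice_max && !is.null(splice_eval)) {
    delta <- splice_eval$delta
    canon_splice <- ("deactivation" %in% splice_eval$events) ||
      (!is.null(delta) && !is.na(delta) && delta <= cfg$deactivation_delta)
  }
  if (null_var || canon_splice) codes <- c(codes, "PVS1")

  # population frequency: PM2 / BS1 / BA1
  af <- g("gnomad_af"); region <- g("region")
  fmax <- if (!is.na(region) && region %in% names(cfg$pm2_freq_max))
    cfg$pm2_freq_max[[region]] else min(cfg$pm2_freq_max)
  if (is.na(af) || af < fmax) codes <- c(codes, "PM2")
  if (!is.na(af) && af >= cfg$ba1_freq) codes <- c(codes, "BA1")
  if (!is.na(af) && af >= cfg$bs1_freq) codes <- c(codes, "BS1")

  # in-silico consensus: PP3 / BP4
  ndel <- g("insilico_deleterious"); ntol <- g("insilico_tolerated")
  ndel <- if (is.na(ndel)) 0L else ndel
  ntol <- if (is.na(ntol)) 0L else ntol
  if (ndel >= cfg$pp3_min_deleterious && ntol == 0) codes <- c(codes, "PP3")
  if (ntol >= cfg$pp3_min_deleterious && ndel == 0) codes <- c(codes, "BP4")

  # reported assertions: PP5 / BP6
  cs <- g("clinvar_status"); cn <- g("clinvar_n")
  if (!is.na(cs) && !is.na(cn) && cn >= 1) {
    if (cs %in% c("pathogenic", "likely_pathogenic")) codes <- c(codes, "PP5")
    if (cs %in% c("benign", "likely_benign")) codes <- c(codes, "BP6")
  }

  # functional studies: PS3 / BS3
  fe <- g("functional_evidence")
  if (!is.na(fe) && fe == "supports_pathogenic") codes <- c(codes, "PS3")
  if (!is.na(fe) && fe == "supports_benign") codes <- c(codes, "BS3")

  unique(codes)
}

#' Combine ACMG evidence codes into a 5-tier class
#'
#' Implements the published combining rules: pathogenic (class 5) e.g. for
#' PVS1 with one strong / two moderate / one moderate plus one supporting /
#' two supporting criteria, two strong criteria, or one strong with enough
#' moderate/supporting; likely pathogenic (class 4) for the weaker
#' combinations; benign (class 1) for stand-alone BA1 or two strong benign
#' criteria; likely benign (class 2); otherwise, or when pathogenic-side
#' and benign-side rows are simultaneously met, class 3 (uncertain
#' significance).
#'
#' @param codes Character vector of evidence codes.
#' @return Integer class 1-5.
#' @export
combine_evidence <- function(codes) {
  codes <- unique(codes)
  bad <- setdiff(codes, .ACMG_CODES)
  if (length(bad) > 0)
    stop("unknown evidence code(s): ", paste(bad, collapse = ", "))
  n_pvs <- sum(grepl("^PVS", codes))
  n_ps <- sum(grepl("^PS", codes))
  n_pm <- sum(grepl("^PM", codes))
  n_pp <- sum(grepl("^PP", codes))
  has_ba <- "BA1" %in% codes
  n_bs <- sum(grepl("^BS", codes))
  n_bp <- sum(grepl("^BP", codes))

  pathogenic <-
    (n_pvs >= 1 && (n_ps >= 1 || n_pm >= 2 ||
                    (n_pm == 1 && n_pp == 1) || n_pp >= 2)) ||
    n_ps >= 2 ||
    (n_ps == 1 && (n_pm >= 3 || (n_pm == 2 && n_pp >= 2) ||
                   (n_pm == 1 && n_pp >= 4)))
  likely_pathogenic <-
    (n_pvs >= 1 && n_pm == 1) ||
    (n_ps == 1 && n_pm >= 1 && n_pm <= 2) ||
    (n_ps == 1 && n_pp >= 2) ||
    n_pm >= 3 ||
    (n_pm == 2 && n_pp >= 2) ||
    (n_pm == 1 && n_pp >= 4)
  benign <- has_ba || n_bs >= 2
  likely_benign <- (n_bs == 1 && n_bp >= 1) || n_bp >= 2

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return(3L)          # contradictory evidence
  if (pathogenic) return(5L)
  if (likely_pathogenic) return(4L)
  if (benign) return(1L)
  if (likely_benign) return(2L)
  3L
}

#' Classify one variant: derive evidence, then combine
#'
#' @inheritParams derive_evidence
#' @return list(evidence = character vector, acmg_class = integer 1-5).
#' @export
classify_variant <- function(v, consequence = NULL, splice_eval = NULL,
                             cfg = acmg_config()) {
  ev <- derive_evidence(v, consequence, splice_eval, cfg)
  list(evidence = ev, acmg_class = combine_evidence(ev))
}

#' Classify every variant in an annotated table
#'
#' Convenience wrapper over [classify_variant()] for a data.frame of
#' annotated variants (fixture or cohort shape): the consequence comes from
#' a `consequence` column (or is interpreted from `pnomen`), the splice
#' evaluation from `splice_delta` / `splice_events` columns.
#'
#' @param variants Annotated variant data.frame.
#' @param cfg An [acmg_config()].
#' @return The input with `evidence` (comma-separated codes) and
#'   `acmg_class` columns appended.
#' @export
classify_variants <- function(variants, cfg = acmg_config()) {
  if (is.null(variants$consequence) && !is.null(variants$pnomen))
    variants$consequence <- consequence_from_pnomen(variants$pnomen)
  n <- nrow(variants)
  ev <- character(n); cls <- integer(n)
  for (i in seq_len(n)) {
    v <- as.list(variants[i, ])
    se <- list(
      delta = if (!is.null(variants$splice_delta))
        variants$splice_delta[i] else NA_real_,
      events = if (!is.null(variants$splice_events) &&
                   !is.na(variants$splice_events[i]) &&
                   nzchar(variants$splice_events[i]))
        strsplit(variants$splice_events[i], "[,;|]")[[1]] else character())
    r <- classify_variant(v, variants$consequence[i], se, cfg)
    ev[i] <- paste(r$evidence, collapse = ",")
    cls[i] <- r$acmg_class
  }
  variants$evidence <- ev
  variants$acmg_class <- cls
  variants
}
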
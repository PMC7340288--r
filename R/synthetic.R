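# Seeded generator of gene panels, cohorts and annotation tables with the
# statistical structure the prioritization pipeline assumes, so that every
# stage is testable without external data.

.MMR_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2", "MSH3", "PMS1", "MLH3",
                "EXO1", "RFC1", "RFC2", "RFC3", "RFC4", "RFC5", "PCNA",
                "LIG1", "RPA1", "RPA2", "RPA3", "POLD1", "POLD2", "POLD3",
                "POLD4")

#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline targets: 199 samples,
#' a 22-gene panel of about 1.213 Mb covering all introns, exons and UTRs,
#' about 97% of called variants intronic, and a small number of injected
#' rare pathogenic variants with known truth labels.
#'
#' @param seed Integer seed; the generator is bit-reproducible from
#'   (seed, config).
#' @param n_samples Cohort size (default 199).
#' @param panel_size_bp Total targeted span (default 1,213,000).
#' @param n_genes Number of panel genes (default 22; MMR pathway symbols).
#' @param region_mix Named proportions for intronic/exonic/utr variant
#'   placement (default 0.97/0.02/0.01); must sum to 1.
#' @param n_variants Number of unique variants to draw (default 10,680).
#' @param af_common_prop Proportion of variants drawn from the common part
#'   of the frequency spectrum (allele fraction above 0.2%; default 0.30).
#' @param af_absent_prop Proportion of *rare* variants absent from the
#'   population database (default 0.5).
#' @param n_injected_pathogenic Engineered pathogenic variants with truth
#'   labels (default 4: two stop-gains, one canonical splice-site hit, one
#'   functionally supported missense).
#' @param clinvar_label_noise Probability that a non-injected variant's
#'   ClinVar label is randomized (default 0.02).
#' @param vaf_outlier_prop Fraction of carrier VAFs drawn outside the
#'   30-75% heterozygous band (default 0.02).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 199L,
                       panel_size_bp = 1213000L, n_genes = 22L,
                       region_mix = c(intronic = 0.97, exonic = 0.02,
                                      utr = 0.01),
                       n_variants = 10680L,
                       af_common_prop = 0.30, af_absent_prop = 0.5,
                       n_injected_pathogenic = 4L,
                       clinvar_label_noise = 0.02,
                       vaf_outlier_prop = 0.02) {
  if (abs(sum(region_mix) - 1) > 1e-9) stop("region_mix must sum to 1")
  if (any(region_mix < 0)) stop("region_mix proportions must be in [0,1]")
  if (n_genes < 1 || n_genes > length(.MMR_GENES))
    stop("n_genes must be between 1 and ", length(.MMR_GENES))
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 panel_size_bp = as.integer(panel_size_bp),
                 n_genes = as.integer(n_genes), region_mix = region_mix,
                 n_variants = as.integer(n_variants),
                 af_common_prop = af_common_prop,
                 af_absent_prop = af_absent_prop,
                 n_injected_pathogenic = as.integer(n_injected_pathogenic),
                 clinvar_label_noise = clinvar_label_noise,
                 vaf_outlier_prop = vaf_outlier_prop),
            class = "sim_config")
}

# consensus profiles for generated junctions; canonical GT/AG invariant,
# other positions strongly conserved as at real canonical sites
.DONOR_CONSENSUS <- c("C", "A", "G", "G", "T", "A", "A", "G", "T")
.DONOR_INVARIANT <- c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                      FALSE)
.ACC_CONSENSUS <- c("T", "T", "T", "T", "T", "T", "C", "C", "T", "T", "T",
                    "C", "A", "G", "G")
.ACC_INVARIANT <- c(rep(FALSE, 12), TRUE, TRUE, FALSE)

.sample_consensus <- function(consensus, invariant, p = 0.98) {
  vapply(seq_along(consensus), function(i) {
    if (invariant[i] || stats::runif(1) < p) consensus[i]
    else sample(setdiff(.BASES, consensus[i]), 1)
  }, character(1))
}

#' Generate a synthetic gene panel with sequences
#'
#' Builds `n_genes` transcripts with realistic exon counts, strongly
#' canonical GT/AG junction windows, an ATG/stop-bounded CDS and 5'/3'
#' UTRs, totalling `panel_size_bp` within 1%. Deterministic for a seed.
#'
#' @param cfg A [sim_config()].
#' @return Named list of `mmr_transcript` objects with sequences.
#' @export
generate_panel <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  genes <- .MMR_GENES[seq_len(cfg$n_genes)]
  span_per_gene <- round(cfg$panel_size_bp / cfg$n_genes)
  panel <- list()
  for (gi in seq_along(genes)) {
    n_ex <- sample(6:14, 1)
    ex_len <- sample(100:250, n_ex, replace = TRUE)
    utr5 <- sample(150:300, 1); utr3 <- sample(250:600, 1)
    ex_len[1] <- ex_len[1] + utr5
    ex_len[n_ex] <- ex_len[n_ex] + utr3
    intron_total <- span_per_gene - sum(ex_len)
    if (intron_total < 300 * (n_ex - 1))
      stop("panel_size_bp too small for the requested gene structure")
    w <- stats::runif(n_ex - 1)
    in_len <- 300L + floor((intron_total - 300L * (n_ex - 1)) * w / sum(w))
    in_len[n_ex - 1] <- intron_total - sum(ex_len) -
      sum(in_len[-(n_ex - 1)]) + sum(ex_len)   # absorb rounding
    L <- sum(ex_len) + sum(in_len)

    seq_t <- paste(sample(.BASES, L, replace = TRUE), collapse = "")
    # transcript-space exon intervals
    starts <- cumsum(c(1L, utils::head(ex_len, -1) + in_len))
    ends <- starts + ex_len - 1L
    # CDS bounds in transcript (spliced) coordinates -> unspliced space
    cds_len_target <- sum(ex_len) - utr5 - utr3
    cds_len <- cds_len_target - (cds_len_target %% 3L)
    utr3_eff <- sum(ex_len) - utr5 - cds_len

    # force junction consensus windows (in transcript orientation)
    for (j in seq_len(n_ex - 1)) {
      e <- ends[j]
      dw <- .sample_consensus(.DONOR_CONSENSUS, .DONOR_INVARIANT)
      substr(seq_t, e - 2L, e + 6L) <- paste(dw, collapse = "")
      a <- starts[j + 1]
      aw <- .sample_consensus(.ACC_CONSENSUS, .ACC_INVARIANT)
      substr(seq_t, a - 14L, a) <- paste(aw, collapse = "")
    }
    # spliced position -> unspliced position
    spl_to_t <- function(n) {
      cum <- cumsum(ex_len); i <- which(n <= cum)[1]
      prev <- if (i > 1) cum[i - 1] else 0L
      starts[i] + (n - prev) - 1L
    }
    cds_from_t <- spl_to_t(utr5 + 1L)
    cds_to_t <- spl_to_t(utr5 + cds_len)
    # start and stop codons (away from junction windows: exons are >100 nt)
    substr(seq_t, cds_from_t, cds_from_t + 2L) <- "ATG"
    substr(seq_t, cds_to_t - 2L, cds_to_t) <- "TAA"

    strand <- if (gi %% 3 == 0) "-" else "+"
    offset <- 10001L
    if (strand == "+") {
      g_seq <- seq_t
      g_ex <- cbind(start = offset + starts - 1L, end = offset + ends - 1L)
      cds_g <- sort(c(offset + cds_from_t - 1L, offset + cds_to_t - 1L))
    } else {
      g_seq <- .revcomp(seq_t)
      g_ex <- cbind(start = offset + (L - ends), end = offset + (L - starts))
      g_ex <- g_ex[rev(seq_len(nrow(g_ex))), , drop = FALSE]
      cds_g <- sort(c(offset + (L - cds_from_t), offset + (L - cds_to_t)))
    }
    panel[[genes[gi]]] <- transcript(
      gene_symbol = genes[gi],
      transcript_id = sprintf("NM_SYN%04d.1", gi),
      chrom = paste0("chr", gi), strand = strand, exons = g_ex,
      cds_start = cds_g[1], cds_end = cds_g[2],
      seq = g_seq, seq_offset = offset)
  }
  stats::setNames(panel,
                  vapply(panel, `[[`, character(1), "transcript_id"))
}

# genomic interval pools per region class for one transcript
.region_pools <- function(tx) {
  ex <- tx$exons
  span <- c(ex[1, 1], ex[nrow(ex), 2])
  coding <- cbind(pmax(ex[, 1], tx$cds_start), pmin(ex[, 2], tx$cds_end))
  coding <- coding[coding[, 1] <= coding[, 2], , drop = FALSE]
  utr <- list()
  for (i in seq_len(nrow(ex))) {
    if (ex[i, 1] < tx$cds_start)
      utr[[length(utr) + 1]] <- c(ex[i, 1], min(ex[i, 2], tx$cds_start - 1L))
    if (ex[i, 2] > tx$cds_end)
      utr[[length(utr) + 1]] <- c(max(ex[i, 1], tx$cds_end + 1L), ex[i, 2])
  }
  utr <- if (length(utr)) do.call(rbind, utr) else
    matrix(integer(), ncol = 2)
  introns <- if (nrow(ex) > 1)
    cbind(ex[-nrow(ex), 2] + 1L, ex[-1, 1] - 1L) else
    matrix(integer(), ncol = 2)
  list(exonic = coding, utr = utr, intronic = introns)
}

.sample_position <- function(pool) {
  len <- pool[, 2] - pool[, 1] + 1L
  i <- sample.int(nrow(pool), 1, prob = len)
  pool[i, 1] + sample.int(len[i], 1) - 1L
}

# HGVS c. name of a genomic substitution on a transcript
.format_cnomen <- function(tx, gpos, ref_g, alt_g) {
  a <- project_genomic(tx, gpos)
  ref_t <- if (tx$strand == "+") ref_g else unname(.COMP[ref_g])
  alt_t <- if (tx$strand == "+") alt_g else unname(.COMP[alt_g])
  paste0("c.", .format_c_position(a$anchor_kind, a$anchor_pos,
                                  a$intron_offset),
         ref_t, ">", alt_t)
}

.base_at <- function(tx, gpos) {
  toupper(substr(tx$seq, gpos - tx$seq_offset + 1L, gpos - tx$seq_offset + 1L))
}

# engineer the injected pathogenic variants on a panel
.inject_pathogenic <- function(panel, n) {
  if (n == 0)
    return(data.frame(kind = character(), gene_symbol = character(),
                      transcript_id = character(), chrom = character(),
                      gpos = integer(), ref = character(), alt = character(),
                      cnomen = character(), pnomen = character(),
                      stringsAsFactors = FALSE))
  kinds <- rep(c("stop_gain", "splice_canonical", "missense_functional"),
               length.out = n)
  core <- intersect(c("MLH1", "MSH2", "MSH6", "PMS2"),
                    vapply(panel, `[[`, character(1), "gene_symbol"))
  out <- list()
  for (k in seq_len(n)) {
    tx <- panel[[sample(seq_along(panel), 1)]]
    if (length(core) > 0 && k <= length(core)) {
      idx <- which(vapply(panel, `[[`, character(1), "gene_symbol") ==
                   core[k])
      tx <- panel[[idx]]
    }
    if (kinds[k] == "splice_canonical") {
      j <- sample(nrow(tx$exons) - 1L, 1)
      pos_vec <- .donor_window_pos(tx, j)
      gpos <- pos_vec[.DONOR_EXONIC + 1L]          # donor +1 (the G of GT)
      ref_g <- .base_at(tx, gpos)
      alt_t <- "A"                                  # GT -> AT kills the site
      alt_g <- if (tx$strand == "+") alt_t else unname(.COMP[alt_t])
      pn <- "p.(?)"
    } else {
      # find a codon one substitution away from TAA for stop gains, or any
      # missense-producing substitution
      mrna <- transcript_mrna(tx)
      span <- .tx_cds_span(tx)
      cds <- substr(mrna, span[1], span[2])
      n_cod <- nchar(cds) %/% 3L
      repeat {
        ci <- sample(10:(n_cod - 10), 1)
        codon <- substr(cds, 3 * ci - 2, 3 * ci)
        if (kinds[k] == "stop_gain") {
          hit <- switch(codon,
            "TAT" = c(3L, "A"), "TAC" = c(3L, "A"), "TCA" = c(2L, "A"),
            "TTA" = c(2L, "A"), "AAA" = c(1L, "T"), "CAA" = c(1L, "T"),
            "GAA" = c(1L, "T"), "TGA" = NULL, "TAG" = NULL, NULL)
          if (is.null(hit)) next
          cpos <- 3L * (ci - 1L) + as.integer(hit[1])
          alt_t <- hit[2]
        } else {
          if (codon %in% c("TAA", "TAG", "TGA")) next
          cpos <- 3L * (ci - 1L) + sample(1:3, 1)
          ref_t_try <- substr(cds, cpos, cpos)
          alt_t <- sample(setdiff(.BASES, ref_t_try), 1)
        }
        p <- parse_hgvs_c(sprintf("c.%d%s>%s", cpos,
                                  substr(cds, cpos, cpos), alt_t))
        cq <- call_consequence(tx, p)
        ok <- (kinds[k] == "stop_gain" && cq$kind == "nonsense") ||
              (kinds[k] == "missense_functional" && cq$kind == "missense")
        if (ok) { pn <- cq$protein_change; break }
      }
      gpos <- cdna_to_genomic(tx, "coding", cpos)
      ref_g <- .base_at(tx, gpos)
      alt_g <- if (tx$strand == "+") alt_t else unname(.COMP[alt_t])
    }
    out[[k]] <- data.frame(
      kind = kinds[k], gene_symbol = tx$gene_symbol,
      transcript_id = tx$transcript_id, chrom = tx$chrom,
      gpos = gpos, ref = ref_g, alt = alt_g,
      cnomen = .format_cnomen(tx, gpos, ref_g, alt_g), pnomen = pn,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic cohort call set and annotation table
#'
#' Draws `n_variants` unique variants over the panel with the configured
#' region mix and allele-frequency spectrum, injects
#' `n_injected_pathogenic` engineered variants (stop-gains, a canonical
#' donor +1 disruption, a functionally supported rare missense) with truth
#' labels, assigns carriers and heterozygous-band VAFs, and emits an
#' annotation table whose conservation and in-silico fields are correlated
#' with the truth labels.
#'
#' @param cfg A [sim_config()].
#' @param panel Panel from [generate_panel()] (same config).
#' @return list with `vcf_records` (per-carrier calls), `annotations`
#'   (per-variant table), `truth` (injected variants) and `panel`.
#' @export
generate_cohort <- function(cfg = sim_config(), panel = generate_panel(cfg)) {
  force(panel)               # panel generation has its own seed discipline
  set.seed(cfg$seed + 1L)
  tx_ids <- names(panel)
  pools <- lapply(panel, .region_pools)
  pool_len <- function(cls) vapply(pools, function(p)
    sum(p[[cls]][, 2] - p[[cls]][, 1] + 1L), numeric(1))

  n <- cfg$n_variants
  region <- sample(names(cfg$region_mix), n, replace = TRUE,
                   prob = cfg$region_mix)
  wl_by_cls <- lapply(stats::setNames(nm = names(cfg$region_mix)), pool_len)
  vars <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- region[i]
    ti <- sample.int(length(panel), 1, prob = wl_by_cls[[cls]])
    tx <- panel[[ti]]
    gpos <- .sample_position(pools[[ti]][[cls]])
    ref <- .base_at(tx, gpos)
    alt <- sample(setdiff(.BASES, ref), 1)
    vars[[i]] <- list(ti = ti, gpos = gpos, ref = ref, alt = alt,
                      truth = "neutral")
  }
  vars <- do.call(rbind, lapply(vars, as.data.frame))
  vars <- vars[!duplicated(paste(vars$ti, vars$gpos, vars$alt)), ]

  # allele-frequency spectrum
  m <- nrow(vars)
  is_common <- stats::runif(m) < cfg$af_common_prop
  af <- rep(NA_real_, m)
  af[is_common] <- 10^stats::runif(sum(is_common), log10(0.002), log10(0.5))
  rare <- which(!is_common)
  absent <- rare[stats::runif(length(rare)) < cfg$af_absent_prop]
  observed_rare <- setdiff(rare, absent)
  af[observed_rare] <- 10^stats::runif(length(observed_rare), -6, log10(5e-4))

  base <- data.frame(
    gene_symbol = vapply(vars$ti, function(i) panel[[i]]$gene_symbol,
                         character(1)),
    transcript_id = tx_ids[vars$ti],
    chrom = vapply(vars$ti, function(i) panel[[i]]$chrom, character(1)),
    gpos = vars$gpos, ref = as.character(vars$ref),
    alt = as.character(vars$alt), gnomad_af = af,
    truth = "neutral", stringsAsFactors = FALSE)
  base$cnomen <- vapply(seq_len(m), function(i)
    .format_cnomen(panel[[vars$ti[i]]], vars$gpos[i], base$ref[i],
                   base$alt[i]), character(1))

  # injected pathogenic truth set
  inj <- .inject_pathogenic(panel, cfg$n_injected_pathogenic)
  inj_rows <- data.frame(
    gene_symbol = inj$gene_symbol, transcript_id = inj$transcript_id,
    chrom = inj$chrom, gpos = inj$gpos, ref = inj$ref, alt = inj$alt,
    gnomad_af = rep(NA_real_, nrow(inj)),
    truth = rep("pathogenic", nrow(inj)), cnomen = inj$cnomen,
    stringsAsFactors = FALSE)
  # drop background collisions with injected sites
  clash <- paste(base$chrom, base$gpos) %in% paste(inj_rows$chrom,
                                                   inj_rows$gpos)
  base <- base[!clash, ]
  all_vars <- rbind(base, inj_rows)
  m <- nrow(all_vars)

  # pnomen for coding variants
  all_vars$pnomen <- "p.(?)"
  for (i in seq_len(m)) {
    p <- parse_hgvs_c(all_vars$cnomen[i])
    if (p$anchor_kind == "coding" && is.na(p$intron_offset)) {
      tx <- panel[[all_vars$transcript_id[i]]]
      cq <- tryCatch(call_consequence(tx, p), error = function(e) NULL)
      if (!is.null(cq)) all_vars$pnomen[i] <- cq$protein_change
    }
  }
  inj_idx <- which(all_vars$truth == "pathogenic")
  all_vars$pnomen[inj_idx] <- inj$pnomen   # keep engineered names

  # annotations correlated with truth
  path <- all_vars$truth == "pathogenic"
  all_vars$phastcons <- round(ifelse(path, stats::runif(m, 0.95, 1),
                                     stats::runif(m, 0, 1)), 3)
  all_vars$phylop <- round(ifelse(path, stats::runif(m, 3, 7),
                                  stats::runif(m, -2, 3)), 2)
  tools4 <- c("UMD", "PolyPhen", "SIFT", "MutationTaster")
  all_vars$insilico <- vapply(seq_len(m), function(i) {
    if (path[i]) return(paste(paste0(tools4, "=deleterious"), collapse = "|"))
    if (stats::runif(1) < 0.3) {
      k <- sample(1:4, 1)
      verdicts <- sample(c("deleterious", "tolerated"), k, replace = TRUE,
                         prob = c(0.3, 0.7))
      return(paste(paste0(sample(tools4, k), "=", verdicts), collapse = "|"))
    }
    ""
  }, character(1))
  common <- !is.na(all_vars$gnomad_af) & all_vars$gnomad_af > 0.002
  all_vars$clinvar <- vapply(seq_len(m), function(i) {
    if (path[i]) return("NIL")
    u <- stats::runif(1)
    noisy <- stats::runif(1) < cfg$clinvar_label_noise
    if (common[i]) {
      if (noisy) return(sprintf("%d X VUS", sample(1:5, 1)))
      if (u < 0.6) return(sprintf("%d X %s", sample(1:10, 1),
                                  sample(c("Benign", "Likely benign"), 1)))
      return("NIL")
    }
    if (u < 0.1) return(sprintf("%d X VUS", sample(1:6, 1)))
    "NIL"
  }, character(1))
  all_vars$gnomad <- ifelse(is.na(all_vars$gnomad_af), "NIL",
                            sprintf("%.4f%%", all_vars$gnomad_af * 100))
  all_vars$functional_evidence <-
    ifelse(path & grepl("missense", c(rep("", nrow(base)), inj$kind)),
           "supports_pathogenic", "none")

  # carriers and VAFs
  af_eff <- ifelse(is.na(all_vars$gnomad_af), 1 / (2 * cfg$n_samples),
                   all_vars$gnomad_af)
  sample_ids <- sprintf("S%04d", seq_len(cfg$n_samples))
  rec <- vector("list", m)
  for (i in seq_len(m)) {
    k <- max(1L, stats::rbinom(1, cfg$n_samples,
                               min(2 * af_eff[i], 0.9)))
    carriers <- sample(sample_ids, k)
    vaf <- ifelse(stats::runif(k) < cfg$vaf_outlier_prop,
                  stats::runif(k),
                  pmin(0.75, pmax(0.30, stats::rnorm(k, 0.5, 0.06))))
    rec[[i]] <- data.frame(
      sample_id = carriers, chrom = all_vars$chrom[i],
      gpos = all_vars$gpos[i], ref = all_vars$ref[i],
      alt = all_vars$alt[i], vaf = round(vaf, 3),
      depth = pmax(8L, as.integer(round(stats::rnorm(k, 60, 25)))),
      stringsAsFactors = FALSE)
  }
  vcf_records <- do.call(rbind, rec)

  truth <- all_vars[path, c("gene_symbol", "transcript_id", "chrom", "gpos",
                            "ref", "alt", "cnomen", "pnomen")]
  truth$kind <- inj$kind
  ann_cols <- c("sample_id", "chrom", "gpos", "ref", "alt")
  annotations <- all_vars[, c("chrom", "gpos", "ref", "alt", "gene_symbol",
                              "transcript_id", "cnomen", "pnomen", "gnomad",
                              "clinvar", "phastcons", "phylop", "insilico",
                              "functional_evidence")]
  names(annotations)[names(annotations) == "gene_symbol"] <- "gene"
  names(annotations)[names(annotations) == "transcript_id"] <- "transcript"
  rownames(annotations) <- rownames(truth) <- rownames(vcf_records) <- NULL
  list(vcf_records = vcf_records, annotations = annotations, truth = truth,
       panel = panel, config = cfg)
}

#' Write a generated cohort to plain-text files
#'
#' @param cohort From [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.tsv"),
             panel = file.path(dir, "panel.json"),
             fasta = file.path(dir, "panel.fa"))
  write_vcf(cohort$vcf_records, paths["vcf"],
            header_extra = sprintf("##mmrscreen_sim_seed=%d",
                                   cohort$config$seed))
  utils::write.table(cohort$annotations, paths["annotations"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_panel_json(cohort$panel, paths["panel"], fasta = paths["fasta"])
  paths
}
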
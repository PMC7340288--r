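# Readers/writers for VCF, annotation tables, panel models and the packaged
# 35-variant reference fixture.

# ---- small cell parsers ------------------------------------------------

#' Parse population-frequency cells
#'
#' Annotation exports print gnomAD frequencies as percentages
#' ("0.0787%"); internally frequencies are fractions. "NIL", "" and NA are
#' the explicit absent state (variant not observed in the database).
#'
#' @param x Character vector of frequency cells.
#' @return Numeric vector of fractions; NA where absent.
#' @examples
#' parse_gnomad_freq(c("0.0787%", "NIL"))  # 0.000787, NA
#' @export
parse_gnomad_freq <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_real_)
    s <- trimws(gsub("/", "", s))
    if (s == "" || toupper(s) == "NIL") return(NA_real_)
    if (grepl("%$", s)) return(as.numeric(sub("%$", "", s)) / 100)
    as.numeric(s)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Parse ClinVar assertion cells
#'
#' Cells of the form "6 x VUS" or "8 X Pathogenic" carry a submission count
#' and an assertion status; "NIL" means no ClinVar record.
#'
#' @param x Character vector of ClinVar cells.
#' @return data.frame with `clinvar_status` (none, benign, likely_benign,
#'   vus, likely_pathogenic, pathogenic) and `clinvar_n` (submission count).
#' @export
parse_clinvar_cell <- function(x) {
  status_map <- c(
    "vus" = "vus", "uncertain significance" = "vus",
    "pathogenic" = "pathogenic", "likely pathogenic" = "likely_pathogenic",
    "likely_pathogenic" = "likely_pathogenic",
    "benign" = "benign", "likely benign" = "likely_benign",
    "likely_benign" = "likely_benign", "none" = "none")
  out <- lapply(x, function(s) {
    if (is.na(s) || trimws(s) == "" || toupper(trimws(s)) == "NIL")
      return(list(status = "none", n = 0L))
    m <- regmatches(s, regexec("^\\s*([0-9]+)\\s*[xX]\\s*(.+?)\\s*$", s))[[1]]
    if (length(m) == 0) {
      key <- tolower(trimws(s))
      if (!key %in% names(status_map))
        stop("unparseable ClinVar cell: '", s, "'", call. = FALSE)
      return(list(status = unname(status_map[key]), n = 1L))
    }
    key <- tolower(trimws(m[3]))
    if (!key %in% names(status_map))
      stop("unknown ClinVar status: '", m[3], "'", call. = FALSE)
    list(status = unname(status_map[key]), n = as.integer(m[2]))
  })
  data.frame(clinvar_status = vapply(out, `[[`, character(1), "status"),
             clinvar_n = vapply(out, `[[`, integer(1), "n"),
             stringsAsFactors = FALSE)
}

# parse "SIFT=deleterious|PolyPhen=tolerated" strings into counts
.parse_insilico <- function(x) {
  res <- lapply(x, function(s) {
    if (is.na(s) || trimws(s) == "") return(c(del = 0L, tol = 0L))
    calls <- strsplit(s, "|", fixed = TRUE)[[1]]
    verdict <- sub("^[^=]*=", "", calls)
    c(del = sum(verdict == "deleterious"), tol = sum(verdict == "tolerated"))
  })
  data.frame(insilico_deleterious = vapply(res, `[[`, integer(1), "del"),
             insilico_tolerated = vapply(res, `[[`, integer(1), "tol"))
}

# ---- VCF ---------------------------------------------------------------

#' Read a VCF into per-sample variant records
#'
#' One record per sample-allele; multiallelic sites are decomposed. The
#' variant allele fraction is taken with the precedence FORMAT/AD ratio,
#' then FORMAT/AF, then INFO/AF.
#'
#' @param path Path to a VCF 4.x file.
#' @return data.frame with columns sample_id, chrom, gpos, ref, alt, vaf,
#'   depth.
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_site <- nrow(fix)
  if (n_site == 0)
    return(data.frame(sample_id = character(), chrom = character(),
                      gpos = integer(), ref = character(), alt = character(),
                      vaf = numeric(), depth = integer()))
  samples <- colnames(v@gt)[-1]
  gt <- vcfR::extract.gt(v, "GT")
  ad <- tryCatch(vcfR::extract.gt(v, "AD"), error = function(e) NULL)
  af_fmt <- tryCatch(vcfR::extract.gt(v, "AF"), error = function(e) NULL)
  dp <- tryCatch(vcfR::extract.gt(v, "DP"), error = function(e) NULL)
  info_af <- vcfR::extract.info(v, "AF")

  recs <- list()
  for (i in seq_len(n_site)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      g <- gt[i, s]
      if (is.na(g)) next
      alleles <- unique(as.integer(strsplit(g, "[/|]")[[1]]))
      alleles <- alleles[!is.na(alleles) & alleles > 0]
      for (a in alleles) {
        vaf <- NA_real_; depth <- NA_integer_
        if (!is.null(ad) && !is.na(ad[i, s])) {
          counts <- as.numeric(strsplit(ad[i, s], ",", fixed = TRUE)[[1]])
          tot <- sum(counts)
          if (tot > 0) vaf <- counts[a + 1] / tot
          depth <- as.integer(tot)
        } else if (!is.null(af_fmt) && !is.na(af_fmt[i, s])) {
          afv <- as.numeric(strsplit(af_fmt[i, s], ",", fixed = TRUE)[[1]])
          vaf <- afv[min(a, length(afv))]
        } else if (length(info_af) >= i && !is.na(info_af[i])) {
          afv <- as.numeric(strsplit(info_af[i], ",", fixed = TRUE)[[1]])
          vaf <- afv[min(a, length(afv))]
        }
        if (is.na(depth) && !is.null(dp) && !is.na(dp[i, s]))
          depth <- as.integer(dp[i, s])
        recs[[length(recs) + 1]] <- data.frame(
          sample_id = s, chrom = fix$CHROM[i], gpos = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = alts[a], vaf = vaf, depth = depth,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, recs)
}

#' Write per-sample variant records as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with one column per sample and GT/AF/DP FORMAT
#' fields, so that [read_vcf()] round-trips the records. Used by the
#' synthetic cohort generator.
#'
#' @param records data.frame as returned by [read_vcf()].
#' @param path Output path.
#' @param header_extra Optional character vector of extra `##` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, header_extra = character()) {
  samples <- sort(unique(records$sample_id))
  key <- paste(records$chrom, records$gpos, records$ref, records$alt)
  sites <- records[!duplicated(key), c("chrom", "gpos", "ref", "alt")]
  sites <- sites[order(sites$chrom, sites$gpos, sites$alt), ]
  hdr <- c("##fileformat=VCFv4.2",
           header_extra,
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele fraction">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    site <- sites[i, ]
    cols <- vapply(samples, function(s) {
      r <- records[records$sample_id == s & records$chrom == site$chrom &
                   records$gpos == site$gpos & records$alt == site$alt, ]
      if (nrow(r) == 0) return("./.:.:.")
      gt <- if (!is.na(r$vaf[1]) && r$vaf[1] > 0.9) "1/1" else "0/1"
      sprintf("%s:%s:%s", gt,
              ifelse(is.na(r$vaf[1]), ".", format(r$vaf[1], digits = 6)),
              ifelse(is.na(r$depth[1]), ".", r$depth[1]))
    }, character(1))
    paste(c(site$chrom, site$gpos, ".", site$ref, site$alt, ".", "PASS", ".",
            "GT:AF:DP", cols), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- annotation tables -------------------------------------------------

#' Default semantic-to-column mapping for annotation tables
#'
#' @return Named character vector mapping semantic field names to table
#'   column names; override entries to fit other table dialects.
#' @export
default_column_map <- function() {
  c(sample_id = "sample_id", chrom = "chrom", gpos = "gpos", ref = "ref",
    alt = "alt", gene_symbol = "gene", transcript_id = "transcript",
    cnomen = "cnomen", pnomen = "pnomen", vaf = "vaf", depth = "depth",
    gnomad = "gnomad", clinvar = "clinvar", phastcons = "phastcons",
    phylop = "phylop", grantham = "grantham",
    stability_score = "stability_score", insilico = "insilico",
    splice_events = "splice_events",
    functional_evidence = "functional_evidence")
}

#' Read an Alamut-batch-like annotation table
#'
#' Tab-separated table with a header; `column_map` maps semantic field names
#' (see [default_column_map()]) to the table's column names. Frequency cells
#' are parsed from percent strings, ClinVar cells from "N x STATUS" cells;
#' "NIL" becomes the explicit absent state.
#'
#' @param path Path to a TSV file.
#' @param column_map Named character vector; entries missing from the table
#'   for optional fields are skipped, but mapped columns that do not exist
#'   raise a configuration error.
#' @return data.frame of annotation records with normalized columns.
#' @export
read_annotation_table <- function(path, column_map = default_column_map()) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  present <- column_map[column_map %in% names(tab)]
  requested_absent <- setdiff(column_map, names(tab))
  required <- column_map[c("cnomen")]
  if (any(required %in% requested_absent))
    stop("annotation table '", path, "' lacks mapped column(s): ",
         paste(intersect(required, requested_absent), collapse = ", "),
         call. = FALSE)
  out <- data.frame(row.names = seq_len(nrow(tab)))
  for (f in names(present)) out[[f]] <- tab[[present[[f]]]]
  for (f in c("gpos", "depth", "grantham"))
    if (!is.null(out[[f]])) out[[f]] <- as.integer(out[[f]])
  for (f in c("vaf", "phastcons", "phylop", "stability_score"))
    if (!is.null(out[[f]])) out[[f]] <- as.numeric(out[[f]])
  if (!is.null(out$gnomad)) {
    out$gnomad_af <- parse_gnomad_freq(out$gnomad)
    out$gnomad <- NULL
  }
  if (!is.null(out$clinvar)) {
    out <- cbind(out, parse_clinvar_cell(out$clinvar))
    out$clinvar <- NULL
  }
  if (!is.null(out$insilico)) out <- cbind(out, .parse_insilico(out$insilico))
  if (is.null(out$functional_evidence)) out$functional_evidence <- "none"
  out$functional_evidence[is.na(out$functional_evidence) |
                          out$functional_evidence == ""] <- "none"
  out
}

#' Merge VCF records with annotation records
#'
#' @param vcf_records data.frame from [read_vcf()].
#' @param annotations data.frame from [read_annotation_table()].
#' @param by Join key: "position" joins on (chrom, gpos, ref, alt);
#'   "cnomen" joins on the HGVS c. name.
#' @return Annotated variant data.frame; VCF records without a matching
#'   annotation are carried with absent annotation fields.
#' @export
merge_annotations <- function(vcf_records, annotations,
                              by = c("position", "cnomen")) {
  by <- match.arg(by)
  if (by == "position") {
    key_v <- paste(vcf_records$chrom, vcf_records$gpos,
                   vcf_records$ref, vcf_records$alt)
    key_a <- paste(annotations$chrom, annotations$gpos,
                   annotations$ref, annotations$alt)
  } else {
    key_v <- vcf_records$cnomen
    key_a <- annotations$cnomen
  }
  idx <- match(key_v, key_a)
  n_miss <- sum(is.na(idx))
  if (n_miss > 0)
    message(n_miss, " variant record(s) had no annotation match; carried ",
            "with absent annotations")
  ann_cols <- setdiff(names(annotations),
                      c("sample_id", "chrom", "gpos", "ref", "alt", "vaf",
                        "depth"))
  out <- vcf_records
  for (f in ann_cols) {
    col <- annotations[[f]][idx]
    if (f == "clinvar_status") col[is.na(col)] <- "none"
    if (f == "clinvar_n") col[is.na(col)] <- 0L
    if (f == "functional_evidence") col[is.na(col)] <- "none"
    if (f %in% c("insilico_deleterious", "insilico_tolerated"))
      col[is.na(col)] <- 0L
    out[[f]] <- col
  }
  out
}

# ---- panel model IO ----------------------------------------------------

#' Read a gene-panel model from JSON
#'
#' Panel JSON is a list of objects `{gene, transcript_id, chrom, strand,
#' exons: [[start, end], ...], cds: [start, end]}`. Transcript sequences can
#' be attached from a FASTA keyed by transcript id.
#'
#' @param path Path to the panel JSON.
#' @param fasta Optional path to a FASTA of genomic span sequences whose
#'   names are transcript ids.
#' @return Named list of `mmr_transcript` objects (by transcript id).
#' @export
read_panel_json <- function(path, fasta = NULL) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  seqs <- NULL
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- stats::setNames(as.character(ss),
                            sub("\\s.*$", "", names(ss)))
  }
  txs <- lapply(spec, function(g) {
    exons <- do.call(rbind, lapply(g$exons, unlist))
    transcript(g$gene, g$transcript_id, g$chrom, g$strand, exons,
               g$cds[[1]], g$cds[[2]],
               seq = if (!is.null(seqs)) seqs[[g$transcript_id]] else NULL,
               seq_offset = if (!is.null(g$seq_offset)) g$seq_offset else NULL)
  })
  stats::setNames(txs, vapply(txs, `[[`, character(1), "transcript_id"))
}

#' Write a gene-panel model to JSON (and optionally FASTA)
#'
#' @param panel Named list of `mmr_transcript` objects.
#' @param path Output JSON path.
#' @param fasta Optional FASTA path for the genomic span sequences.
#' @return `path`, invisibly.
#' @export
write_panel_json <- function(panel, path, fasta = NULL) {
  spec <- lapply(panel, function(tx) list(
    gene = tx$gene_symbol, transcript_id = tx$transcript_id,
    chrom = tx$chrom, strand = tx$strand,
    exons = lapply(seq_len(nrow(tx$exons)),
                   function(i) c(tx$exons[i, 1], tx$exons[i, 2])),
    cds = c(tx$cds_start, tx$cds_end), seq_offset = tx$seq_offset))
  jsonlite::write_json(unname(spec), path, auto_unbox = TRUE)
  if (!is.null(fasta)) {
    seqs <- Biostrings::DNAStringSet(vapply(panel, `[[`, character(1), "seq"))
    names(seqs) <- vapply(panel, `[[`, character(1), "transcript_id")
    Biostrings::writeXStringSet(seqs, fasta)
  }
  invisible(path)
}

#' Read a gene-panel model from GFF3
#'
#' Expects exon and CDS features grouped by a `transcript_id` (or `Parent`)
#' attribute and a `gene` (or `gene_id`) attribute. Requires rtracklayer.
#'
#' @param path Path to a GFF3 file.
#' @param fasta Optional FASTA of genomic span sequences keyed by
#'   transcript id.
#' @return Named list of `mmr_transcript` objects.
#' @export
read_panel_gff3 <- function(path, fasta = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 panels requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  tx_col <- intersect(c("transcript_id", "Parent"), names(md))[1]
  gene_col <- intersect(c("gene", "gene_id", "Name"), names(md))[1]
  if (is.na(tx_col)) stop("GFF3 lacks transcript_id/Parent attributes")
  md$.tx <- as.character(md[[tx_col]])
  seqs <- NULL
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  txs <- lapply(split(md, md$.tx), function(d) {
    ex <- d[d$type == "exon", c("start", "end")]
    cds <- d[d$type == "CDS", c("start", "end")]
    transcript(gene_symbol = if (is.na(gene_col)) d$.tx[1] else
                 as.character(d[[gene_col]][1]),
               transcript_id = d$.tx[1],
               chrom = as.character(d$seqnames[1]),
               strand = as.character(d$strand[1]),
               exons = as.matrix(ex),
               cds_start = min(cds$start), cds_end = max(cds$end),
               seq = if (!is.null(seqs)) seqs[[d$.tx[1]]] else NULL)
  })
  stats::setNames(txs, vapply(txs, `[[`, character(1), "transcript_id"))
}

# ---- packaged reference fixture ---------------------------------------

# md5 of the packaged fixture TSV; guards against silent edits
.TABLE2_MD5 <- "4a2d90a978dcf38738a861321dc31643"

#' Load the packaged 35-variant reference fixture
#'
#' The fixture transcribes the study's aggregate result table: 35 distinct
#' prioritized variants over 33 patients with sample IDs, HGVS g./c./p.
#' names, VAF, ClinVar and gnomAD cells as printed, the expected 5-tier
#' class, deep-intronic splice-category flags, in-silico prediction calls
#' and the single functional-evidence flag (PMS2 c.137G>T, supported by
#' published functional studies). Variants carried by two patients appear
#' once, with comma-separated sample IDs and VAFs.
#'
#' @param check Verify the packaged file's md5 checksum (default TRUE).
#' @return data.frame of 35 annotated variant records with parsed columns
#'   (gnomad_af fraction, clinvar_status/clinvar_n, region,
#'   splice_distance, consequence, expected_class).
#' @export
load_table2_fixture <- function(check = TRUE) {
  path <- system.file("extdata", "table2_variants.tsv", package = "mmrscreen")
  if (path == "") stop("packaged fixture not found")
  if (check && !grepl("^@", .TABLE2_MD5)) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .TABLE2_MD5))
      stop("packaged fixture checksum mismatch: ", md5)
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  out <- data.frame(
    sample_id = tab$sample_ids,
    n_samples = lengths(strsplit(tab$sample_ids, ",")),
    gene_symbol = tab$gene, transcript_id = tab$transcript_id,
    gnomen = tab$gnomen, cnomen = tab$cnomen, pnomen = tab$pnomen,
    vaf = vapply(strsplit(tab$vafs, ","),
                 function(v) mean(as.numeric(v)), numeric(1)),
    vafs = tab$vafs,
    stringsAsFactors = FALSE)
  out$gnomad_af <- parse_gnomad_freq(tab$gnomad)
  cv <- parse_clinvar_cell(tab$clinvar)
  out$clinvar_status <- cv$clinvar_status
  out$clinvar_n <- cv$clinvar_n
  out$expected_class <- as.integer(tab$class)
  out$splice_delta <- suppressWarnings(as.numeric(tab$splice_delta))
  out$splice_events <- tab$splice_events
  ins <- .parse_insilico(tab$insilico)
  out$insilico_deleterious <- ins$insilico_deleterious
  out$insilico_tolerated <- ins$insilico_tolerated
  out$functional_evidence <- ifelse(tab$functional_evidence == "",
                                    "none", tab$functional_evidence)
  out$comment <- tab$comment
  rc <- classify_regions(out$cnomen)
  out$region <- rc$region
  out$splice_distance <- rc$splice_distance
  out$consequence <- consequence_from_pnomen(out$pnomen)
  out
}

#' Expand multi-patient fixture records to one row per patient
#'
#' @param fixture data.frame from [load_table2_fixture()].
#' @return data.frame with one row per (patient, variant) pair and numeric
#'   per-patient `vaf`.
#' @export
expand_fixture_samples <- function(fixture) {
  ids <- strsplit(fixture$sample_id, ",", fixed = TRUE)
  vafs <- strsplit(fixture$vafs, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fixture)), lengths(ids))
  out <- fixture[idx, ]
  out$sample_id <- unlist(ids)
  out$vaf <- as.numeric(unlist(vafs))
  rownames(out) <- NULL
  out
}
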
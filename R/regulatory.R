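# 5'UTR transcription-factor binding-site allele preference from position
# frequency matrices, and 3'UTR microRNA seed-site detection/disruption.

#' Parse one JASPAR-format position frequency matrix
#'
#' The JASPAR text layout: a `>ID name` header line followed by four rows
#' `A [ n1 n2 ... ]` (brackets optional) for A, C, G, T.
#'
#' @param lines Character vector holding one matrix record (header line
#'   optional).
#' @return Object of class `pfm`: `tf_name`, `counts` (4 x L), `freq`
#'   (column-normalized), `length`.
#' @export
parse_pfm <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  tf_name <- NA_character_
  if (length(lines) > 0 && startsWith(lines[1], ">")) {
    hdr <- strsplit(sub("^>\\s*", "", lines[1]), "\\s+")[[1]]
    tf_name <- hdr[length(hdr)]
    lines <- lines[-1]
  }
  if (length(lines) != 4)
    stop("a PFM record needs 4 base rows, got ", length(lines))
  rows <- lapply(lines, function(l) {
    l <- gsub("[][]", " ", l)
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    list(base = toupper(parts[1]), counts = as.numeric(parts[-1]))
  })
  bases <- vapply(rows, `[[`, character(1), "base")
  if (!setequal(bases, c("A", "C", "G", "T")))
    stop("PFM rows must be labelled A, C, G, T")
  lens <- vapply(rows, function(r) length(r$counts), integer(1))
  if (length(unique(lens)) != 1)
    stop("ragged PFM rows: lengths ", paste(lens, collapse = ", "))
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  rownames(counts) <- bases
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(counts < 0)) stop("negative PFM counts")
  if (any(colSums(counts) <= 0)) stop("PFM column with no positive count")
  freq <- sweep(counts, 2, colSums(counts), "/")
  structure(list(tf_name = tf_name, counts = counts, freq = freq,
                 length = ncol(counts)), class = "pfm")
}

#' Read a JASPAR-format PFM file (possibly several matrices)
#'
#' @param path Path to a JASPAR text file.
#' @return Named list of `pfm` objects (by TF name).
#' @export
read_pfm_file <- function(path) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  if (length(starts) == 0) return(stats::setNames(list(parse_pfm(lines)), "pfm1"))
  ends <- c(starts[-1] - 1L, length(lines))
  pfms <- lapply(seq_along(starts),
                 function(i) parse_pfm(lines[starts[i]:ends[i]]))
  stats::setNames(pfms, vapply(pfms, `[[`, character(1), "tf_name"))
}

#' Write PFMs in JASPAR text format
#'
#' @param pfms A `pfm` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm_file <- function(pfms, path) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  out <- unlist(lapply(pfms, function(p) {
    c(paste0(">", ifelse(is.na(p$tf_name), "PFM", p$tf_name)),
      vapply(c("A", "C", "G", "T"), function(b)
        sprintf("%s  [ %s ]", b,
                paste(format(p$counts[b, ], trim = TRUE), collapse = " ")),
        character(1)))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read TFBS intervals from a BED6 file
#'
#' BED is 0-based half-open; the name column carries the TF name.
#'
#' @param path Path to a BED file.
#' @return data.frame with chrom, start0, end0, tf_name, score, strand.
#' @export
read_tfbs_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start0", "end0",
                                         "tf_name", "score", "strand")[1:6],
                           fill = TRUE)
  if (is.null(tab$strand) || all(is.na(tab$strand))) tab$strand <- "+"
  tab$strand[!tab$strand %in% c("+", "-")] <- "+"
  tab
}

#' Annotate a variant with overlapping TFBS hits and allele preference
#'
#' For every interval overlapping the variant, the motif column at the
#' variant's offset gives the frequencies of the reference and alternate
#' alleles; their ratio (with a symmetric pseudocount) measures how
#' strongly the motif prefers the reference base. Minus-strand motifs are
#' handled by complementing the alleles and counting the offset from the
#' motif's 3' genomic end.
#'
#' @param chrom,gpos Variant location (1-based genomic).
#' @param ref,alt Plus-strand alleles (single nucleotides).
#' @param tfbs data.frame from [read_tfbs_bed()].
#' @param pfms Named list of `pfm` objects (by TF name).
#' @param eps Pseudocount added to both frequencies (default 0.01).
#' @param strong_ratio Ratio at or above which the preference is flagged
#'   strong (default 5).
#' @return data.frame of hits: tf_name, start0, end0, strand, motif_offset
#'   (0-based), ref_freq, alt_freq, preference_ratio, strong_preference.
#' @export
tfbs_annotate <- function(chrom, gpos, ref, alt, tfbs, pfms,
                          eps = 0.01, strong_ratio = 5) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- tfbs[tfbs$chrom == chrom & tfbs$start0 < gpos & gpos <= tfbs$end0, ,
               drop = FALSE]
  out <- data.frame(tf_name = character(), start0 = integer(),
                    end0 = integer(), strand = character(),
                    motif_offset = integer(), ref_freq = numeric(),
                    alt_freq = numeric(), preference_ratio = numeric(),
                    strong_preference = logical(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$strand == "+") {
      off <- (gpos - 1L) - h$start0
      r <- toupper(ref); a <- toupper(alt)
    } else {
      off <- h$end0 - gpos
      r <- unname(comp[toupper(ref)]); a <- unname(comp[toupper(alt)])
    }
    pfm <- pfms[[h$tf_name]]
    if (is.null(pfm)) {
      warning("no frequency matrix for TF '", h$tf_name,
              "'; hit emitted without allele preference")
      out[nrow(out) + 1L, ] <- list(h$tf_name, h$start0, h$end0, h$strand,
                                    as.integer(off), NA_real_, NA_real_,
                                    NA_real_, NA)
      next
    }
    if (off < 0L || off >= pfm$length)
      stop("variant offset ", off, " outside motif of length ", pfm$length)
    f_ref <- pfm$freq[r, off + 1L]
    f_alt <- pfm$freq[a, off + 1L]
    ratio <- (f_ref + eps) / (f_alt + eps)
    out[nrow(out) + 1L, ] <- list(h$tf_name, h$start0, h$end0, h$strand,
                                  as.integer(off), f_ref, f_alt, ratio,
                                  ratio >= strong_ratio)
  }
  out
}

# ---- microRNA seed sites ----------------------------------------------

.check_nt <- function(s, what) {
  if (grepl("[^ACGTUacgtu]", s))
    stop("non-ACGTU character in ", what)
  toupper(chartr("U", "T", s))
}

#' Scan a 3'UTR for canonical microRNA seed-match sites
#'
#' Sites are anchored on a Watson-Crick match to the miRNA seed core
#' (positions 2-7). Each core match is classified once, in this
#' precedence: 8mer (core plus a match to position 8 plus an A opposite
#' position 1), 7mer-m8 (core plus the position-8 match), 7mer-A1 (core
#' plus the A). A bare 6mer core is not reported. Both sequences are given
#' 5'->3'.
#'
#' @param utr_seq 3'UTR nucleotide string.
#' @param mirna_seq Mature miRNA sequence (U or T accepted).
#' @param mirna_name Optional name attached to the sites.
#' @return data.frame: mirna_name, site_type, start0, end0 (half-open UTR
#'   interval).
#' @export
mirna_scan <- function(utr_seq, mirna_seq, mirna_name = NA_character_) {
  utr <- .check_nt(utr_seq, "UTR sequence")
  mir <- .check_nt(mirna_seq, "miRNA sequence")
  if (nchar(mir) < 8) stop("miRNA shorter than 8 nt")
  core <- .revcomp(substr(mir, 2, 7))     # 6 nt opposite positions 2-7
  m8 <- .revcomp(substr(mir, 8, 8))       # 1 nt opposite position 8
  n <- nchar(utr)
  out <- data.frame(mirna_name = character(), site_type = character(),
                    start0 = integer(), end0 = integer(),
                    stringsAsFactors = FALSE)
  if (n < 7) return(out)
  for (s in 0:(n - 6)) {                  # 0-based core start
    if (substr(utr, s + 1, s + 6) != core) next
    has_m8 <- s >= 1 && substr(utr, s, s) == m8
    has_a1 <- s + 7 <= n && substr(utr, s + 7, s + 7) == "A"
    if (has_m8 && has_a1) {
      out[nrow(out) + 1L, ] <- list(mirna_name, "8mer", s - 1L, s + 7L)
    } else if (has_m8) {
      out[nrow(out) + 1L, ] <- list(mirna_name, "7mer_m8", s - 1L, s + 6L)
    } else if (has_a1) {
      out[nrow(out) + 1L, ] <- list(mirna_name, "7mer_A1", s, s + 7L)
    }
  }
  out
}

#' Scan a UTR against a set of miRNAs
#'
#' @param utr_seq 3'UTR nucleotide string.
#' @param mirnas Named character vector (or Biostrings set) of mature
#'   miRNA sequences.
#' @return Combined data.frame of sites from [mirna_scan()].
#' @export
mirna_scan_all <- function(utr_seq, mirnas) {
  mirnas <- stats::setNames(as.character(mirnas), names(mirnas))
  do.call(rbind, lapply(names(mirnas), function(nm)
    mirna_scan(utr_seq, mirnas[[nm]], nm)))
}

#' Flag seed sites disrupted by a UTR substitution
#'
#' A site is disrupted when the variant falls inside the site's seed-match
#' interval and the altered UTR no longer matches that site type at that
#' position.
#'
#' @param utr_seq Reference 3'UTR sequence.
#' @param pos0 0-based UTR position of the substitution.
#' @param alt Alternate base.
#' @param sites data.frame from [mirna_scan()] / [mirna_scan_all()], with a
#'   `mirna_seq` column or scanned from a single miRNA given in
#'   `mirna_seqs`.
#' @param mirna_seqs Named character vector of miRNA sequences (names
#'   matching `sites$mirna_name`).
#' @return `sites` with a logical `disrupted_by_variant` column.
#' @export
mirna_disruption <- function(utr_seq, pos0, alt, sites, mirna_seqs) {
  utr <- .check_nt(utr_seq, "UTR sequence")
  alt <- .check_nt(alt, "alternate allele")
  alt_utr <- utr
  substr(alt_utr, pos0 + 1L, pos0 + 1L) <- alt
  mirna_seqs <- stats::setNames(as.character(mirna_seqs), names(mirna_seqs))
  matches_type <- function(seq, s) {
    mir <- .check_nt(mirna_seqs[[s$mirna_name]], "miRNA sequence")
    seed78 <- .revcomp(substr(mir, 2, 8))
    seed27 <- .revcomp(substr(mir, 2, 7))
    w <- substr(seq, s$start0 + 1L, s$end0)
    switch(s$site_type,
           `8mer` = w == paste0(seed78, "A"),
           `7mer_m8` = w == seed78,
           `7mer_A1` = w == paste0(seed27, "A"))
  }
  disrupted <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- as.list(sites[i, ])
    inside <- pos0 >= s$start0 && pos0 < s$end0
    disrupted[i] <- inside && !matches_type(alt_utr, s)
  }
  sites$disrupted_by_variant <- disrupted
  sites
}
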
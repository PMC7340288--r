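# Transcript model, HGVS c.-notation parsing, region classification and
# coding-consequence calling.

#' Construct a transcript model
#'
#' A transcript carries the exon structure, strand and CDS bounds needed to
#' translate between genomic and HGVS c. coordinates, plus (optionally) the
#' genomic reference sequence of its span for splice scoring and consequence
#' calling.
#'
#' @param gene_symbol Gene symbol, e.g. "MLH1".
#' @param transcript_id Transcript accession, e.g. "NM_000249.3".
#' @param chrom Chromosome name.
#' @param strand "+" or "-".
#' @param exons Two-column matrix or data.frame of 1-based inclusive genomic
#'   exon intervals (start, end), in ascending genomic order.
#' @param cds_start,cds_end Genomic positions of the first and last CDS base
#'   (genomic orientation: cds_start < cds_end regardless of strand).
#' @param seq Optional genomic reference sequence (plus-strand) covering the
#'   transcript span, as a single character string.
#' @param seq_offset Genomic coordinate of the first base of `seq`
#'   (defaults to the transcript's first exon start).
#' @return An object of class `mmr_transcript`.
#' @export
transcript <- function(gene_symbol, transcript_id, chrom, strand, exons,
                       cds_start, cds_end, seq = NULL, seq_offset = NULL) {
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1]))
    stop("exon end before start in transcript ", transcript_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping exons in transcript ", transcript_id)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  in_exon <- function(p) any(p >= exons[, 1] & p <= exons[, 2])
  if (!in_exon(cds_start) || !in_exon(cds_end))
    stop("CDS bounds must fall inside exons (", transcript_id, ")")
  if (is.null(seq_offset)) seq_offset <- exons[1, 1]
  structure(list(
    gene_symbol = gene_symbol, transcript_id = transcript_id,
    chrom = chrom, strand = strand, exons = exons,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    seq = seq, seq_offset = as.integer(seq_offset)
  ), class = "mmr_transcript")
}

#' @export
print.mmr_transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%d-%d [%s] %d exon(s)>\n",
              x$transcript_id, x$gene_symbol, x$chrom,
              x$exons[1, 1], x$exons[nrow(x$exons), 2], x$strand,
              nrow(x$exons)))
  invisible(x)
}

# ---- HGVS c. parsing ---------------------------------------------------

.parse_c_position <- function(token) {
  m <- regmatches(token, regexec("^(\\*|-)?([0-9]+)([+-][0-9]+)?$", token))[[1]]
  if (length(m) == 0)
    stop("unparseable HGVS position token: '", token, "'", call. = FALSE)
  prefix <- m[2]
  n <- as.integer(m[3])
  kind <- if (prefix == "*") "utr3" else if (prefix == "-") "utr5" else "coding"
  pos <- if (kind == "utr5") -n else n
  off <- if (m[4] == "") NA_integer_ else as.integer(m[4])
  if (!is.na(off) && off == 0L)
    stop("intron offset of 0 is not valid: '", token, "'", call. = FALSE)
  list(kind = kind, pos = pos, offset = off)
}

.format_c_position <- function(kind, pos, offset) {
  base <- switch(kind,
    coding = as.character(pos),
    utr5   = as.character(pos),            # pos is negative, prints "-76"
    utr3   = paste0("*", pos))
  if (!is.na(offset)) base <- paste0(base, sprintf("%+d", offset))
  base
}

#' Parse an HGVS c. variant description
#'
#' Supports the c. grammar subset used for panel variants: plain coding
#' positions (`c.306`), intronic offsets (`c.306+4`, `c.628-7`), 5'UTR
#' (`c.-76`, `c.-1028+959`) and 3'UTR (`c.*84`) anchors, position ranges
#' (`c.3802-4_3825`) and the edits `REF>ALT`, `dup`, `del`, `ins`, `delins`.
#' A transcript prefix (`NM_000179.2:`) is accepted and stripped.
#'
#' @param text A single HGVS c. string.
#' @return An object of class `hgvs_c` with fields `anchor_kind`
#'   (coding/utr5/utr3), `anchor_pos` (negative for 5'UTR), `intron_offset`
#'   (NA when absent), optional `end_*` fields for ranges, `edit_kind`
#'   (substitution/duplication/deletion/insertion/delins), `ref`, `alt`.
#' @examples
#' p <- parse_hgvs_c("c.306+4A>G")
#' p$intron_offset   # 4
#' format(p)         # "c.306+4A>G"
#' @export
parse_hgvs_c <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- sub("^[A-Za-z0-9_.]+:", "", trimws(text))
  if (!startsWith(s, "c."))
    stop("not an HGVS c. description: '", text, "'", call. = FALSE)
  body <- substring(s, 3)

  m <- regmatches(body, regexec(
    "^([*-]?[0-9]+(?:[+-][0-9]+)?)(?:_([*-]?[0-9]+(?:[+-][0-9]+)?))?(.*)$",
    body))[[1]]
  if (length(m) == 0 || m[2] == "")
    stop("unparseable HGVS c. string: '", text, "'", call. = FALSE)
  start <- .parse_c_position(m[2])
  end <- if (m[3] != "") .parse_c_position(m[3]) else NULL
  edit <- m[4]

  res <- list(anchor_kind = start$kind, anchor_pos = start$pos,
              intron_offset = start$offset,
              end_anchor_kind = if (is.null(end)) NA_character_ else end$kind,
              end_anchor_pos = if (is.null(end)) NA_integer_ else end$pos,
              end_intron_offset = if (is.null(end)) NA_integer_ else end$offset)

  if (grepl("^[ACGTacgt]+>[ACGTacgt]+$", edit)) {
    nt <- strsplit(edit, ">", fixed = TRUE)[[1]]
    res$edit_kind <- "substitution"; res$ref <- toupper(nt[1]); res$alt <- toupper(nt[2])
  } else if (grepl("^delins[ACGTacgt]+$", edit)) {
    res$edit_kind <- "delins"; res$ref <- ""; res$alt <- toupper(sub("^delins", "", edit))
  } else if (grepl("^dup[ACGTacgt]*$", edit)) {
    res$edit_kind <- "duplication"; res$ref <- ""; res$alt <- toupper(sub("^dup", "", edit))
  } else if (grepl("^del[ACGTacgt]*$", edit)) {
    res$edit_kind <- "deletion"; res$ref <- toupper(sub("^del", "", edit)); res$alt <- ""
  } else if (grepl("^ins[ACGTacgt]+$", edit)) {
    res$edit_kind <- "insertion"; res$ref <- ""; res$alt <- toupper(sub("^ins", "", edit))
  } else {
    stop("unparseable HGVS edit token: '", edit, "' in '", text, "'",
         call. = FALSE)
  }
  structure(res, class = "hgvs_c")
}

#' @export
format.hgvs_c <- function(x, ...) {
  pos <- .format_c_position(x$anchor_kind, x$anchor_pos, x$intron_offset)
  if (!is.na(x$end_anchor_kind))
    pos <- paste0(pos, "_",
                  .format_c_position(x$end_anchor_kind, x$end_anchor_pos,
                                     x$end_intron_offset))
  edit <- switch(x$edit_kind,
    substitution = paste0(x$ref, ">", x$alt),
    duplication  = paste0("dup", x$alt),
    deletion     = paste0("del", x$ref),
    insertion    = paste0("ins", x$alt),
    delins       = paste0("delins", x$alt))
  paste0("c.", pos, edit)
}

#' @export
print.hgvs_c <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

# ---- Region classification --------------------------------------------

#' Classify a parsed variant into a genomic region category
#'
#' Variants partition into protein-coding exon, splice-neighbourhood intron
#' (within `splice_max` nt of the nearest junction, measured on the intronic
#' side), deep intron, 5'UTR and 3'UTR. An intronic offset dominates a UTR
#' anchor (a 5'UTR-anchored deep-intronic variant is intronic, not UTR), and
#' a ranged edit that touches at least one coding-exon base is exonic.
#'
#' @param parsed An `hgvs_c` object from [parse_hgvs_c()].
#' @param splice_max Splice-neighbourhood cut-off in nucleotides (default 10).
#' @return A list with `region` (one of "EXON", "INTRON_SPLICE",
#'   "INTRON_DEEP", "UTR5", "UTR3") and `splice_distance` (NA unless
#'   intronic).
#' @examples
#' classify_region(parse_hgvs_c("c.628-7C>A"))$region       # INTRON_SPLICE
#' classify_region(parse_hgvs_c("c.-1028+959C>A"))$region   # INTRON_DEEP
#' @export
classify_region <- function(parsed, splice_max = 10L) {
  stopifnot(inherits(parsed, "hgvs_c"))
  anchors <- list(list(kind = parsed$anchor_kind, off = parsed$intron_offset))
  if (!is.na(parsed$end_anchor_kind))
    anchors <- c(anchors, list(list(kind = parsed$end_anchor_kind,
                                    off = parsed$end_intron_offset)))
  # ranged (or plain) edits touching a coding-exon base are exonic
  touches_coding <- vapply(anchors, function(a)
    a$kind == "coding" && is.na(a$off), logical(1))
  if (any(touches_coding))
    return(list(region = "EXON", splice_distance = NA_integer_))

  offs <- vapply(anchors, function(a) a$off, integer(1))
  if (any(!is.na(offs))) {
    d <- min(abs(offs[!is.na(offs)]))
    region <- if (d <= splice_max) "INTRON_SPLICE" else "INTRON_DEEP"
    return(list(region = region, splice_distance = as.integer(d)))
  }
  region <- switch(parsed$anchor_kind, utr5 = "UTR5", utr3 = "UTR3",
                   coding = "EXON")
  list(region = region, splice_distance = NA_integer_)
}

#' Region-classify a vector of HGVS c. strings
#'
#' @param cnomen Character vector of HGVS c. strings.
#' @param splice_max Splice-neighbourhood cut-off (default 10 nt).
#' @return data.frame with columns `cnomen`, `region`, `splice_distance`.
#' @export
classify_regions <- function(cnomen, splice_max = 10L) {
  res <- lapply(cnomen, function(s) classify_region(parse_hgvs_c(s), splice_max))
  data.frame(
    cnomen = cnomen,
    region = vapply(res, `[[`, character(1), "region"),
    splice_distance = vapply(res, `[[`, integer(1), "splice_distance"),
    stringsAsFactors = FALSE
  )
}

# ---- Genomic <-> transcript coordinate projection ----------------------

# mRNA (spliced, 1-based from transcript 5' end) position of an exonic
# genomic position; NA if intronic.
.tx_mrna_pos <- function(tx, gpos) {
  ex <- tx$exons
  lens <- ex[, 2] - ex[, 1] + 1L
  hit <- which(gpos >= ex[, 1] & gpos <= ex[, 2])
  if (length(hit) == 0) return(NA_integer_)
  if (tx$strand == "+") {
    before <- if (hit > 1) sum(lens[seq_len(hit - 1)]) else 0L
    unname(before + (gpos - ex[hit, 1]) + 1L)
  } else {
    n <- nrow(ex)
    after <- if (hit < n) sum(lens[seq(hit + 1, n)]) else 0L
    unname(after + (ex[hit, 2] - gpos) + 1L)
  }
}

# mRNA positions of the CDS start/end in transcript orientation
.tx_cds_span <- function(tx) {
  a <- .tx_mrna_pos(tx, tx$cds_start)
  b <- .tx_mrna_pos(tx, tx$cds_end)
  c(cds_from = min(a, b), cds_to = max(a, b))
}

.mrna_to_anchor <- function(tx, n) {
  span <- unname(.tx_cds_span(tx))
  if (n < span[1]) list(kind = "utr5", pos = n - span[1])
  else if (n > span[2]) list(kind = "utr3", pos = n - span[2])
  else list(kind = "coding", pos = n - span[1] + 1L)
}

#' Project a genomic position into HGVS c. coordinates
#'
#' The strand-aware inverse of the c.-to-genomic mapping: exonic positions
#' get a plain coding/UTR anchor; intronic positions get the nearest exon
#' boundary as anchor plus a signed offset (+ from the donor side, - from
#' the acceptor side, HGVS convention, ties to the donor side).
#'
#' @param tx An `mmr_transcript`.
#' @param gpos Genomic position (1-based).
#' @return A list with `anchor_kind`, `anchor_pos`, `intron_offset` (NA for
#'   exonic positions).
#' @export
project_genomic <- function(tx, gpos) {
  ex <- tx$exons
  if (gpos < ex[1, 1] || gpos > ex[nrow(ex), 2])
    stop("position ", gpos, " outside transcript span of ", tx$transcript_id)
  n <- .tx_mrna_pos(tx, gpos)
  if (!is.na(n)) {
    a <- .mrna_to_anchor(tx, n)
    return(list(anchor_kind = a$kind, anchor_pos = a$pos,
                intron_offset = NA_integer_))
  }
  # intronic: flanking exons in genomic order
  i <- max(which(ex[, 2] < gpos))             # exon left of gpos
  left_end <- ex[i, 2]; right_start <- ex[i + 1, 1]
  d_left <- gpos - left_end                    # distance from left exon
  d_right <- right_start - gpos                # distance from right exon
  if (tx$strand == "+") {
    donor_d <- d_left; acceptor_d <- d_right
    donor_anchor_g <- left_end; acceptor_anchor_g <- right_start
  } else {
    donor_d <- d_right; acceptor_d <- d_left
    donor_anchor_g <- right_start; acceptor_anchor_g <- left_end
  }
  if (donor_d <= acceptor_d) {
    a <- .mrna_to_anchor(tx, .tx_mrna_pos(tx, donor_anchor_g))
    list(anchor_kind = a$kind, anchor_pos = a$pos,
         intron_offset = as.integer(donor_d))
  } else {
    a <- .mrna_to_anchor(tx, .tx_mrna_pos(tx, acceptor_anchor_g))
    list(anchor_kind = a$kind, anchor_pos = a$pos,
         intron_offset = as.integer(-acceptor_d))
  }
}

#' Map an HGVS c. anchor to its genomic position
#'
#' Inverse of [project_genomic()].
#'
#' @param tx An `mmr_transcript`.
#' @param anchor_kind "coding", "utr5" or "utr3".
#' @param anchor_pos Anchor coordinate (negative for 5'UTR).
#' @param intron_offset Signed intronic offset or NA.
#' @return Genomic position (integer).
#' @export
cdna_to_genomic <- function(tx, anchor_kind, anchor_pos,
                            intron_offset = NA_integer_) {
  span <- .tx_cds_span(tx)
  n <- switch(anchor_kind,
    coding = span[1] + anchor_pos - 1L,
    utr5   = span[1] + anchor_pos,          # anchor_pos negative
    utr3   = span[2] + anchor_pos,
    stop("unknown anchor kind: ", anchor_kind))
  n <- as.integer(n)
  tx_len <- sum(tx$exons[, 2] - tx$exons[, 1] + 1L)
  if (n < 1L || n > tx_len)
    stop("c. anchor outside transcript bounds (", tx$transcript_id, ")")
  # mRNA position -> genomic
  ex <- tx$exons
  lens <- ex[, 2] - ex[, 1] + 1L
  if (tx$strand == "+") {
    cum <- cumsum(lens); i <- which(n <= cum)[1]
    prev <- if (i > 1) cum[i - 1] else 0L
    g <- ex[i, 1] + (n - prev) - 1L
  } else {
    cum <- cumsum(rev(lens)); i_rev <- which(n <= cum)[1]
    prev <- if (i_rev > 1) cum[i_rev - 1] else 0L
    i <- nrow(ex) - i_rev + 1L
    g <- ex[i, 2] - (n - prev) + 1L
  }
  if (is.na(intron_offset)) return(as.integer(g))
  if (intron_offset == 0L) stop("intron offset of 0 is not valid")
  as.integer(if (tx$strand == "+") g + intron_offset else g - intron_offset)
}

# ---- mRNA / CDS sequence helpers --------------------------------------

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# spliced mRNA sequence in transcript orientation
transcript_mrna <- function(tx) {
  if (is.null(tx$seq)) stop("transcript ", tx$transcript_id, " has no sequence")
  ex <- tx$exons
  parts <- vapply(seq_len(nrow(ex)), function(i) {
    substr(tx$seq, ex[i, 1] - tx$seq_offset + 1L, ex[i, 2] - tx$seq_offset + 1L)
  }, character(1))
  m <- paste(parts, collapse = "")
  if (tx$strand == "-") m <- .revcomp(m)
  m
}

.aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "*")

.translate_cds <- function(cds) {
  n <- (nchar(cds) %/% 3) * 3
  if (n == 0) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

#' Call the coding consequence of a variant
#'
#' Builds the reference CDS from the transcript model, applies the edit in
#' transcript coordinates, translates both sequences and compares them.
#' Stop-loss variants report the extension length as the index of the first
#' in-frame stop codon in the 3' (downstream) transcript sequence.
#'
#' @param tx An `mmr_transcript` with sequence.
#' @param parsed An `hgvs_c` object. Edits fully inside the CDS are
#'   supported; variants anchored outside the CDS return kind "noncoding".
#' @return A list with `kind` (synonymous/missense/nonsense/stop_loss/
#'   frameshift/inframe/noncoding), `protein_change` (HGVS p. text) and
#'   `extension_aa` (stop-loss only, otherwise NA).
#' @export
call_consequence <- function(tx, parsed) {
  stopifnot(inherits(tx, "mmr_transcript"), inherits(parsed, "hgvs_c"))
  if (is.null(tx$seq)) stop("transcript sequence required for consequence calling")
  if (parsed$anchor_kind != "coding" || !is.na(parsed$intron_offset))
    return(list(kind = "noncoding", protein_change = "p.(?)",
                extension_aa = NA_integer_))
  mrna <- transcript_mrna(tx)
  span <- .tx_cds_span(tx)
  cds <- substr(mrna, span[1], span[2])
  downstream <- substr(mrna, span[2] + 1L, nchar(mrna))

  pos <- parsed$anchor_pos
  end_pos <- if (!is.na(parsed$end_anchor_pos) &&
                 identical(parsed$end_anchor_kind, "coding") &&
                 is.na(parsed$end_intron_offset)) parsed$end_anchor_pos else pos
  if (pos < 1 || end_pos > nchar(cds))
    stop("edit extends outside the CDS; unsupported for consequence calling")

  alt_cds <- switch(parsed$edit_kind,
    substitution = {
      if (nzchar(parsed$ref) &&
          substr(cds, pos, pos + nchar(parsed$ref) - 1L) != parsed$ref)
        warning("reference allele mismatch at c.", pos, " (",
                tx$transcript_id, ")")
      paste0(substr(cds, 1, pos - 1L), parsed$alt,
             substr(cds, pos + nchar(parsed$ref), nchar(cds)))
    },
    deletion = paste0(substr(cds, 1, pos - 1L),
                      substr(cds, end_pos + 1L, nchar(cds))),
    duplication = {
      seg <- substr(cds, pos, end_pos)
      paste0(substr(cds, 1, end_pos), seg,
             substr(cds, end_pos + 1L, nchar(cds)))
    },
    insertion = paste0(substr(cds, 1, pos), parsed$alt,
                       substr(cds, pos + 1L, nchar(cds))),
    delins = paste0(substr(cds, 1, pos - 1L), parsed$alt,
                    substr(cds, end_pos + 1L, nchar(cds)))
  )

  len_change <- nchar(alt_cds) - nchar(cds)
  ref_prot <- .translate_cds(cds)

  if (len_change %% 3 != 0) {
    aa_pos <- (pos - 1L) %/% 3L + 1L
    return(list(kind = "frameshift",
                protein_change = sprintf("p.(%s%dfs)",
                  .aa3[[substr(ref_prot, aa_pos, aa_pos)]], aa_pos),
                extension_aa = NA_integer_))
  }

  alt_prot <- .translate_cds(paste0(alt_cds, downstream))
  ref_full <- .translate_cds(paste0(cds, downstream))
  # compare over the reference CDS frame
  n_ref <- nchar(ref_prot)

  if (len_change != 0) {
    return(list(kind = "inframe", protein_change = "p.(?)",
                extension_aa = NA_integer_))
  }

  diffs <- which(strsplit(ref_prot, "")[[1]] != strsplit(substr(alt_prot, 1, n_ref), "")[[1]])
  if (length(diffs) == 0)
    { # synonymous: first affected codon
      aa_pos <- (pos - 1L) %/% 3L + 1L
      aa <- substr(ref_prot, aa_pos, aa_pos)
      return(list(kind = "synonymous",
                  protein_change = sprintf("p.(%s%d=)", .aa3[[aa]], aa_pos),
                  extension_aa = NA_integer_)) }
  i <- diffs[1]
  ref_aa <- substr(ref_prot, i, i)
  alt_aa <- substr(substr(alt_prot, 1, n_ref), i, i)
  if (ref_aa == "*" && alt_aa != "*") {
    # stop loss: first in-frame stop in the downstream sequence
    down_prot <- .translate_cds(downstream)
    k <- regexpr("*", down_prot, fixed = TRUE)
    ext <- if (k > 0) as.integer(k) else NA_integer_
    pc <- if (is.na(ext)) sprintf("p.(*%d%sext*?)", i, .aa3[[alt_aa]])
          else sprintf("p.(*%d%sext*%d)", i, .aa3[[alt_aa]], ext)
    return(list(kind = "stop_loss", protein_change = pc, extension_aa = ext))
  }
  if (alt_aa == "*")
    return(list(kind = "nonsense",
                protein_change = sprintf("p.(%s%d*)", .aa3[[ref_aa]], i),
                extension_aa = NA_integer_))
  list(kind = "missense",
       protein_change = sprintf("p.(%s%d%s)", .aa3[[ref_aa]], i, .aa3[[alt_aa]]),
       extension_aa = NA_integer_)
}

#' Interpret an HGVS p. string as a consequence kind
#'
#' Used when per-variant annotation carries a protein change but no
#' transcript sequence (annotation-table and fixture workflows). The p.
#' string is otherwise treated as opaque text.
#'
#' @param pnomen Character vector of HGVS p. strings.
#' @return Character vector: missense/nonsense/stop_loss/synonymous/unknown.
#' @export
consequence_from_pnomen <- function(pnomen) {
  vapply(pnomen, function(p) {
    p <- trimws(p)
    if (p %in% c("", "p.(?)", "p.?")) return("unknown")
    body <- sub("^p\\.\\(?", "", sub("\\)$", "", p))
    if (grepl("ext", body)) return("stop_loss")
    if (grepl("fs", body)) return("frameshift")
    if (grepl("\\*$", body)) return("nonsense")
    if (grepl("=\\s*$", body)) return("synonymous")
    if (grepl("^[A-Z][a-z]{2}[0-9]+[A-Z][a-z]{2}$", body)) return("missense")
    "unknown"
  }, character(1), USE.NAMES = FALSE)
}
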
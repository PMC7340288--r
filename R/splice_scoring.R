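# Donor/acceptor position-weight-matrix scoring (percent-score convention),
# normalized change scores and splice-event calls.

.DONOR_EXONIC <- 3L; .DONOR_INTRONIC <- 6L      # window -3..+6
.ACC_INTRONIC <- 14L; .ACC_EXONIC <- 1L          # window -14..+1
.BASES <- c("A", "C", "G", "T")

#' Construct a splice-site frequency matrix
#'
#' @param kind "donor" (window of 3 exonic + 6 intronic nt) or "acceptor"
#'   (14 intronic + 1 exonic nt).
#' @param counts 4 x L numeric matrix of base counts, rows A,C,G,T, with L
#'   equal to the window length for `kind`.
#' @param pseudocount Added to every count before normalization (default 1).
#' @return Object of class `splice_matrix` with per-position frequencies
#'   summing to 1.
#' @export
splice_matrix <- function(kind = c("donor", "acceptor"), counts,
                          pseudocount = 1) {
  kind <- match.arg(kind)
  L <- if (kind == "donor") .DONOR_EXONIC + .DONOR_INTRONIC
       else .ACC_INTRONIC + .ACC_EXONIC
  counts <- as.matrix(counts)
  if (nrow(counts) != 4 || ncol(counts) != L)
    stop(kind, " matrix must be 4 x ", L)
  rownames(counts) <- .BASES
  counts <- counts + pseudocount
  freq <- sweep(counts, 2, colSums(counts), "/")
  structure(list(kind = kind, freq = freq, length = L,
                 smin = sum(apply(freq, 2, min)),
                 smax = sum(apply(freq, 2, max))),
            class = "splice_matrix")
}

# exons in transcript (5'->3') order
.tx_exons <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

# genomic position vector (transcript orientation) of the donor window at
# transcript-order junction i, and of the acceptor window
.donor_window_pos <- function(tx, i) {
  ex <- .tx_exons(tx)
  if (tx$strand == "+") {
    e <- ex[i, 2]; seq(e - .DONOR_EXONIC + 1L, e + .DONOR_INTRONIC)
  } else {
    e <- ex[i, 1]; seq(e + .DONOR_EXONIC - 1L, e - .DONOR_INTRONIC)
  }
}

.acceptor_window_pos <- function(tx, i) {
  ex <- .tx_exons(tx)
  if (tx$strand == "+") {
    a <- ex[i + 1L, 1]; seq(a - .ACC_INTRONIC, a)
  } else {
    a <- ex[i + 1L, 2]; seq(a + .ACC_INTRONIC, a)
  }
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# transcript-strand bases at genomic positions, from a plus-strand sequence
.strand_bases <- function(tx, gpos_vec, seq = tx$seq) {
  idx <- gpos_vec - tx$seq_offset + 1L
  if (any(idx < 1L | idx > nchar(seq)))
    stop("window extends outside the stored sequence of ", tx$transcript_id)
  b <- vapply(idx, function(i) substr(seq, i, i), character(1))
  if (tx$strand == "-") b <- unname(.COMP[toupper(b)])
  paste(toupper(b), collapse = "")
}

#' Estimate donor/acceptor matrices from a panel's annotated junctions
#'
#' Counts bases in the donor and acceptor windows of every internal
#' exon-intron junction of every transcript that carries a sequence.
#'
#' @param panel Named list of `mmr_transcript` objects with sequences.
#' @param pseudocount Pseudocount for [splice_matrix()] (default 1).
#' @return list(donor = , acceptor = ) of `splice_matrix` objects.
#' @export
estimate_splice_matrices <- function(panel, pseudocount = 1) {
  dc <- matrix(0, 4, .DONOR_EXONIC + .DONOR_INTRONIC, dimnames = list(.BASES))
  ac <- matrix(0, 4, .ACC_INTRONIC + .ACC_EXONIC, dimnames = list(.BASES))
  for (tx in panel) {
    if (is.null(tx$seq)) next
    n_j <- nrow(tx$exons) - 1L
    if (n_j < 1) next
    for (i in seq_len(n_j)) {
      dw <- strsplit(.strand_bases(tx, .donor_window_pos(tx, i)), "")[[1]]
      aw <- strsplit(.strand_bases(tx, .acceptor_window_pos(tx, i)), "")[[1]]
      for (p in seq_along(dw))
        if (dw[p] %in% .BASES) dc[dw[p], p] <- dc[dw[p], p] + 1
      for (p in seq_along(aw))
        if (aw[p] %in% .BASES) ac[aw[p], p] <- ac[aw[p], p] + 1
    }
  }
  list(donor = splice_matrix("donor", dc, pseudocount),
       acceptor = splice_matrix("acceptor", ac, pseudocount))
}

#' Percent-score a sequence window against a splice matrix
#'
#' The min-max normalized matrix sum: (S - S_min) / (S_max - S_min), where
#' S sums the per-position frequencies of the observed bases and S_min/S_max
#' sum the column minima/maxima. 1 is the best-possible window, 0 the worst.
#'
#' @param matrix A `splice_matrix`.
#' @param window_seq Character string of length matching the matrix window.
#' @return Score in [0, 1].
#' @export
score_site <- function(matrix, window_seq) {
  stopifnot(inherits(matrix, "splice_matrix"))
  b <- strsplit(toupper(window_seq), "")[[1]]
  if (length(b) != matrix$length)
    stop("window length ", length(b), " != matrix window ", matrix$length)
  if (!all(b %in% .BASES))
    stop("non-ACGT base in window: ", window_seq)
  s <- sum(matrix$freq[cbind(match(b, .BASES), seq_along(b))])
  (s - matrix$smin) / (matrix$smax - matrix$smin)
}

# effective site score: the percent score gated on the invariant GT / AG
# dinucleotide -- a window without the canonical dinucleotide is not a
# splice site at all, so a substitution destroying it is complete site loss
# (delta -1) however well the rest of the window matches
.eff_score <- function(matrix, window_seq) {
  b <- strsplit(toupper(window_seq), "")[[1]]
  intact <- if (matrix$kind == "donor")
    b[.DONOR_EXONIC + 1L] == "G" && b[.DONOR_EXONIC + 2L] == "T"
  else
    b[.ACC_INTRONIC - 1L] == "A" && b[.ACC_INTRONIC] == "G"
  if (!intact) return(0)
  score_site(matrix, window_seq)
}

#' Splice-event thresholds
#'
#' @param deactivation_delta Canonical-site relative change at or below
#'   which a deactivation is called (default -0.1).
#' @param new_site_tau Percent-score threshold a non-canonical site must
#'   reach (from below) to be called a new donor/acceptor (default 0.70).
#' @param cryptic_gain Minimum relative score gain for a cryptic-site
#'   strong-activation call (default 0.15).
#' @param cryptic_canonical_frac Fraction of the nearest canonical site's
#'   score a cryptic site must reach (default 0.8).
#' @return list of thresholds.
#' @export
splice_config <- function(deactivation_delta = -0.1, new_site_tau = 0.70,
                          cryptic_gain = 0.15, cryptic_canonical_frac = 0.8) {
  list(deactivation_delta = deactivation_delta, new_site_tau = new_site_tau,
       cryptic_gain = cryptic_gain,
       cryptic_canonical_frac = cryptic_canonical_frac)
}

#' Evaluate the splice impact of a substitution
#'
#' Scores every canonical donor/acceptor window that overlaps the variant
#' (reference vs alternate) and reports the nearest-splice-site change
#' `delta = (alt - ref) / ref`, floored at -1; additionally scans all
#' non-canonical windows overlapping the variant for new-site creation and
#' strong cryptic activation.
#'
#' Events: `deactivation` (canonical site, delta at or below the
#' deactivation threshold), `new_donor`/`new_acceptor` (non-canonical window
#' crossing the new-site threshold from below), `cryptic_strong_activation`
#' (non-canonical window gaining at least the configured relative score and
#' reaching the configured fraction of the nearest canonical site's score).
#'
#' @param tx An `mmr_transcript` with sequence.
#' @param parsed An `hgvs_c` substitution (other edit kinds return an empty
#'   evaluation).
#' @param matrices list(donor=, acceptor=) of `splice_matrix` objects.
#' @param cfg A [splice_config()].
#' @return list with `ref_score`, `alt_score`, `delta`, `events`
#'   (character vector).
#' @export
evaluate_variant <- function(tx, parsed, matrices, cfg = splice_config()) {
  if (is.null(tx$seq)) stop("transcript sequence required for splice scoring")
  empty <- list(ref_score = NA_real_, alt_score = NA_real_, delta = 0,
                events = character())
  if (parsed$edit_kind != "substitution") return(empty)
  gpos <- cdna_to_genomic(tx, parsed$anchor_kind, parsed$anchor_pos,
                          parsed$intron_offset)
  # plus-strand alleles
  ref_g <- if (tx$strand == "+") parsed$ref else unname(.COMP[parsed$ref])
  alt_g <- if (tx$strand == "+") parsed$alt else unname(.COMP[parsed$alt])
  idx <- gpos - tx$seq_offset + 1L
  obs <- toupper(substr(tx$seq, idx, idx))
  if (nzchar(ref_g) && obs != ref_g)
    warning("reference allele mismatch at ", tx$chrom, ":", gpos,
            " (expected ", ref_g, ", sequence has ", obs, ")")
  alt_seq <- tx$seq
  substr(alt_seq, idx, idx) <- alt_g

  n_j <- nrow(tx$exons) - 1L
  canon <- list()
  if (n_j >= 1) for (i in seq_len(n_j)) {
    canon[[length(canon) + 1]] <- list(kind = "donor",
                                       pos = .donor_window_pos(tx, i))
    canon[[length(canon) + 1]] <- list(kind = "acceptor",
                                       pos = .acceptor_window_pos(tx, i))
  }

  events <- character()
  delta <- 0; ref_best <- NA_real_; alt_best <- NA_real_

  # canonical sites overlapping the variant: nearest-SS-change
  hit <- Filter(function(s) gpos %in% s$pos, canon)
  if (length(hit) > 0) {
    deltas <- vapply(hit, function(s) {
      m <- matrices[[s$kind]]
      r <- .eff_score(m, .strand_bases(tx, s$pos))
      a <- .eff_score(m, .strand_bases(tx, s$pos, seq = alt_seq))
      max((a - r) / max(r, 1e-9), -1)
    }, numeric(1))
    k <- which.max(abs(deltas))
    s <- hit[[k]]
    m <- matrices[[s$kind]]
    ref_best <- .eff_score(m, .strand_bases(tx, s$pos))
    alt_best <- .eff_score(m, .strand_bases(tx, s$pos, seq = alt_seq))
    delta <- deltas[k]
    if (delta <= cfg$deactivation_delta) events <- c(events, "deactivation")
  }

  # non-canonical windows overlapping the variant
  canon_keys <- vapply(canon, function(s)
    paste(s$kind, paste(s$pos, collapse = ",")), character(1))
  seq_lo <- tx$seq_offset; seq_hi <- tx$seq_offset + nchar(tx$seq) - 1L
  for (kind in c("donor", "acceptor")) {
    m <- matrices[[kind]]
    L <- m$length
    # ref score of the nearest canonical site of this kind
    same <- Filter(function(s) s$kind == kind, canon)
    canon_score <- if (length(same) == 0) NA_real_ else {
      d <- vapply(same, function(s) min(abs(s$pos - gpos)), numeric(1))
      s <- same[[which.min(d)]]
      .eff_score(m, .strand_bases(tx, s$pos))
    }
    for (k in seq_len(L)) {           # variant at window position k
      pos <- if (tx$strand == "+") seq(gpos - k + 1L, gpos - k + L)
             else seq(gpos + k - 1L, gpos + k - L)
      if (min(pos) < seq_lo || max(pos) > seq_hi) next
      key <- paste(kind, paste(pos, collapse = ","))
      if (key %in% canon_keys) next
      r <- .eff_score(m, .strand_bases(tx, pos))
      a <- .eff_score(m, .strand_bases(tx, pos, seq = alt_seq))
      if (r < cfg$new_site_tau && a >= cfg$new_site_tau) {
        events <- c(events, paste0("new_", kind))
      } else if ((a - r) / max(r, 1e-9) >= cfg$cryptic_gain &&
                 !is.na(canon_score) &&
                 a >= cfg$cryptic_canonical_frac * canon_score) {
        events <- c(events, "cryptic_strong_activation")
      }
    }
  }

  list(ref_score = ref_best, alt_score = alt_best, delta = delta,
       events = unique(events))
}
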
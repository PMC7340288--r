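# Shared toy objects: a deterministic 3-exon transcript with canonical
# junctions, sharp splice matrices, and small oracle helpers.

# transcript-space layout:
#   exon1 1-60 | intron1 61-140 | exon2 141-200 | intron2 201-280 | exon3 281-340
#   CDS t21..t309 (ATG at 21, TAA at 307), canonical junction windows planted,
#   one broken donor window planted deep in intron2 (t230-238, GT missing)
toy_tx <- function(strand = "+") {
  L <- 340L
  s <- paste(rep(c("A", "C", "G", "T"), length.out = L), collapse = "")
  substr(s, 21, 23) <- "ATG"
  substr(s, 307, 309) <- "TAA"
  substr(s, 58, 66) <- "CAGGTAAGT"          # donor 1 (-3..+6)
  substr(s, 127, 141) <- "TTTTTTCCTTTCAGG"  # acceptor 1 (-14..+1)
  substr(s, 198, 206) <- "CAGGTAAGT"        # donor 2
  substr(s, 267, 281) <- "TTTTTTCCTTTCAGG"  # acceptor 2
  substr(s, 230, 238) <- "CAGGAAAGT"        # broken donor, +2 T missing
  exons_t <- rbind(c(1L, 60L), c(141L, 200L), c(281L, 340L))
  cds_t <- c(21L, 309L)
  offset <- 1001L
  if (strand == "+") {
    g_seq <- s
    g_ex <- exons_t + offset - 1L
    cds <- cds_t + offset - 1L
  } else {
    g_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    g_ex <- cbind(offset + (L - exons_t[, 2]), offset + (L - exons_t[, 1]))
    g_ex <- g_ex[rev(seq_len(nrow(g_ex))), ]
    cds <- sort(offset + (L - cds_t))
  }
  transcript("TOY", paste0("NM_TOY", strand, ".1"), "chrT", strand, g_ex,
             cds[1], cds[2], seq = g_seq, seq_offset = offset)
}

# sharp donor/acceptor matrices: consensus count 90, others 2
toy_matrices <- function() {
  mk <- function(consensus) {
    counts <- matrix(2, 4, nchar(consensus),
                     dimnames = list(c("A", "C", "G", "T")))
    b <- strsplit(consensus, "")[[1]]
    counts[cbind(match(b, rownames(counts)), seq_along(b))] <- 90
    counts
  }
  list(donor = splice_matrix("donor", mk("CAGGTAAGT")),
       acceptor = splice_matrix("acceptor", mk("TTTTTTCCTTTCAGG")))
}

# independent reverse-complement (no Biostrings)
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(s)), "")[[1]]),
        collapse = "")
}

# random annotated-variant table for cascade property tests
random_variant_table <- function(n) {
  regions <- c("EXON", "INTRON_SPLICE", "INTRON_DEEP", "UTR5", "UTR3")
  af <- ifelse(stats::runif(n) < 0.3, NA_real_,
               10^stats::runif(n, -6, -0.5))
  data.frame(
    cnomen = sprintf("c.%d%s>%s", seq_len(n),
                     sample(c("A", "C", "G", "T"), n, TRUE),
                     sample(c("A", "C", "G", "T"), n, TRUE)),
    region = sample(regions, n, TRUE),
    gnomad_af = af,
    clinvar_status = sample(c("none", "vus", "benign", "likely_benign",
                              "pathogenic"), n, TRUE,
                            prob = c(0.5, 0.25, 0.1, 0.1, 0.05)),
    splice_events = sample(c("", "new_donor", "new_acceptor",
                             "cryptic_strong_activation", "deactivation"),
                           n, TRUE, prob = c(0.6, 0.1, 0.1, 0.1, 0.1)),
    stringsAsFactors = FALSE)
}

# one-pass brute-force filter equivalent to the staged cascade
brute_force_filter <- function(variants, cfg = filter_config()) {
  thr <- c(EXON = cfg$freq_max_exonic, INTRON_DEEP = cfg$freq_max_intronic,
           INTRON_SPLICE = cfg$freq_max_splice, UTR5 = cfg$freq_max_utr,
           UTR3 = cfg$freq_max_utr)
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    f_ok <- if (is.na(v$gnomad_af)) cfg$keep_missing_frequency
            else v$gnomad_af < thr[[v$region]]
    c_ok <- !(v$region %in% cfg$clinvar_prefilter_regions &&
              v$clinvar_status %in% cfg$clinvar_drop)
    ev <- if (is.na(v$splice_events) || v$splice_events == "") character()
          else strsplit(v$splice_events, "[,;|]")[[1]]
    s_ok <- if (v$region == "INTRON_DEEP")
      any(ev %in% cfg$splice_categories_required) else TRUE
    keep[i] <- f_ok && c_ok && s_ok
  }
  variants$cnomen[keep]
}
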
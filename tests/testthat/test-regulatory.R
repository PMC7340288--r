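# TFBS allele preference from PFMs; miRNA seed-site detection/disruption.

test_that("JASPAR-format PFMs parse and round-trip", {
  lines <- c(">MA0000.1 TOYTF",
             "A  [ 7 0 ]", "C  [ 1 0 ]", "G  [ 1 9 ]", "T  [ 1 1 ]")
  p <- parse_pfm(lines)
  expect_equal(p$tf_name, "TOYTF")
  expect_equal(p$length, 2L)
  expect_equal(colSums(p$freq), c(1, 1), ignore_attr = TRUE)
  expect_equal(p$freq["A", 1], 0.7, ignore_attr = TRUE)

  path <- tempfile(fileext = ".pfm")
  write_pfm_file(p, path)
  back <- read_pfm_file(path)[["TOYTF"]]
  expect_equal(back$counts, p$counts)

  expect_error(parse_pfm(c("A 1 2", "C 1", "G 1 2", "T 1 2")), "ragged")
  expect_error(parse_pfm(c("A 1", "C 1", "G 1")), "4 base rows")
})

test_that("TFBS hits report allele preference from the motif column", {
  # CTCF-like column at the variant: ref G 0.90, alt T 0.02
  counts <- rbind(A = c(10, 4, 4), C = c(10, 4, 4), G = c(10, 90, 4),
                  T = c(70, 2, 88))
  pfm <- parse_pfm(c(">M1 CTCF", paste(rownames(counts), apply(counts, 1,
                     paste, collapse = " "))))
  tfbs <- data.frame(chrom = "chr2", start0 = 99L, end0 = 102L,
                     tf_name = "CTCF", score = 0, strand = "+",
                     stringsAsFactors = FALSE)
  hits <- tfbs_annotate("chr2", 101L, "G", "T", tfbs, list(CTCF = pfm))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif_offset, 1L)
  expect_equal(hits$preference_ratio, (0.90 + 0.01) / (0.02 + 0.01),
               tolerance = 1e-9)
  expect_true(hits$strong_preference)

  # equal frequencies: ratio 1, not strong
  eq <- parse_pfm(c(">M2 EQ", "A 25 25", "C 25 25", "G 25 25", "T 25 25"))
  tfbs2 <- data.frame(chrom = "chr2", start0 = 99L, end0 = 101L,
                      tf_name = "EQ", score = 0, strand = "+")
  h2 <- tfbs_annotate("chr2", 100L, "A", "C", tfbs2, list(EQ = eq))
  expect_equal(h2$preference_ratio, 1)
  expect_false(h2$strong_preference)

  # no overlapping interval: empty result
  h3 <- tfbs_annotate("chr2", 5000L, "A", "C", tfbs2, list(EQ = eq))
  expect_equal(nrow(h3), 0L)

  # missing matrix: hit emitted without ratio, with a warning
  tfbs3 <- data.frame(chrom = "chr2", start0 = 99L, end0 = 101L,
                      tf_name = "NOPFM", score = 0, strand = "+")
  expect_warning(h4 <- tfbs_annotate("chr2", 100L, "A", "C", tfbs3,
                                     list()), "no frequency matrix")
  expect_true(is.na(h4$preference_ratio))
})

test_that("preference ratios are reciprocal under allele swap", {
  set.seed(3)
  for (i in 1:20) {
    counts <- matrix(sample(0:50, 12, TRUE) + 1, 4,
                     dimnames = list(c("A", "C", "G", "T")))
    pfm <- structure(list(tf_name = "R", counts = counts,
                          freq = sweep(counts, 2, colSums(counts), "/"),
                          length = 3L), class = "pfm")
    tfbs <- data.frame(chrom = "c", start0 = 0L, end0 = 3L, tf_name = "R",
                       score = 0, strand = "+")
    al <- sample(c("A", "C", "G", "T"), 2)
    r1 <- tfbs_annotate("c", 2L, al[1], al[2], tfbs, list(R = pfm))
    r2 <- tfbs_annotate("c", 2L, al[2], al[1], tfbs, list(R = pfm))
    expect_equal(r1$preference_ratio * r2$preference_ratio, 1,
                 tolerance = 1e-9)
    expect_true(r1$motif_offset >= 0 && r1$motif_offset < pfm$length)
  }
})

test_that("minus-strand motifs complement alleles and mirror the offset", {
  # motif on the minus strand: genomic G at the last genomic base is a C in
  # motif orientation at offset 0
  counts <- rbind(A = c(1, 1), C = c(90, 1), G = c(1, 90), T = c(1, 1))
  pfm <- parse_pfm(c(">M3 MINUS", paste(rownames(counts),
                                        apply(counts, 1, paste,
                                              collapse = " "))))
  tfbs <- data.frame(chrom = "c", start0 = 10L, end0 = 12L,
                     tf_name = "MINUS", score = 0, strand = "-")
  h <- tfbs_annotate("c", 12L, "G", "A", tfbs, list(MINUS = pfm))
  expect_equal(h$motif_offset, 0L)
  # ref G complements to C (freq ~0.90+eps), alt A to T (~0.011+eps)
  expect_gt(h$preference_ratio, 5)
})

test_that("seed-site detection matches the canonical type definitions", {
  mir <- "UGGAAGACUAGUGAUUUUGUUGU"   # positions 2-8: GGAAGAC
  target78 <- rc_oracle(substr(mir, 2, 8))   # GTCTTCC
  utr8 <- paste0("AAAA", target78, "A", "AAAA")
  s <- mirna_scan(utr8, mir, "toy-miR")
  expect_equal(nrow(s), 1L)
  expect_equal(s$site_type, "8mer")
  expect_equal(s$start0, 4L); expect_equal(s$end0, 12L)

  utr7 <- paste0("AAAA", target78, "G")
  expect_equal(mirna_scan(utr7, mir)$site_type, "7mer_m8")

  utr7a1 <- paste0("CCCC", rc_oracle(substr(mir, 2, 7)), "A")
  expect_equal(mirna_scan(utr7a1, mir)$site_type, "7mer_A1")

  # no complementary 6mer anywhere
  expect_equal(nrow(mirna_scan(strrep("A", 60), mir)), 0L)
  expect_error(mirna_scan("ACGTNACGT", mir), "non-ACGTU")
})

test_that("site detection is invariant under appending non-matching flanks", {
  mir <- "UAGCUUAUCAGACUGAUGUUGA"    # miR-21-like
  core <- paste0(rc_oracle(substr(mir, 2, 8)), "A")
  utr <- paste0("GGGG", core, "GGGG")
  s1 <- mirna_scan(utr, mir)
  s2 <- mirna_scan(paste0("GCGCGC", utr, "CGCGCG"), mir)
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(s2$start0, s1$start0 + 6L)
})

test_that("disruption requires a seed hit that breaks the match", {
  mir <- "UGGAAGACUAGUGAUUUUGUUGU"
  site <- paste0(rc_oracle(substr(mir, 2, 8)), "A")
  utr <- paste0("AAAA", site, "CCCC")
  sites <- mirna_scan(utr, mir, "toy-miR")
  # substitution inside the seed-pairing positions destroys the 8mer
  d <- mirna_disruption(utr, 6L, "A", sites,
                        c("toy-miR" = mir))
  expect_true(d$disrupted_by_variant)
  # variant outside the site leaves it intact
  d2 <- mirna_disruption(utr, 14L, "G", sites, c("toy-miR" = mir))
  expect_false(d2$disrupted_by_variant)
  # a substitution inside the interval that preserves the match type:
  # 7mer-m8 site followed by the variant changing the downstream base
  utr7 <- paste0("AAAA", rc_oracle(substr(mir, 2, 8)), "G")
  s7 <- mirna_scan(utr7, mir, "toy-miR")
  expect_equal(s7$site_type, "7mer_m8")
  d3 <- mirna_disruption(utr7, 11L, "C", s7, c("toy-miR" = mir))
  expect_false(d3$disrupted_by_variant)   # position 11 is past the 7mer
})

test_that("seed scan equals a brute-force substring oracle on random cases", {
  set.seed(99)
  for (i in 1:100) {
    utr <- paste(sample(c("A", "C", "G", "T"), 300, TRUE,
                        prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
    mir <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
    # plant a site half the time so matches are not vanishingly rare
    if (i %% 2 == 0) {
      site <- paste0(rc_oracle(substr(chartr("U", "T", mir), 2, 8)), "A")
      pos <- sample(0:(300 - 8), 1)
      substr(utr, pos + 1, pos + 8) <- site
    }
    got <- mirna_scan(utr, mir, "m")
    want <- mirna_scan_brute(utr, mir, "m")
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      wantdf <- as.data.frame(do.call(rbind, want))
      expect_equal(got$site_type, as.character(wantdf$V2))
      expect_equal(got$start0, as.integer(as.character(wantdf$V3)))
    }
  }
})
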
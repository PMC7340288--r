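# HGVS c. parsing, region classification, coordinate projection and
# consequence calling.

test_that("HGVS c. strings parse into the expected anchors and edits", {
  p <- parse_hgvs_c("c.306+4A>G")
  expect_equal(p$anchor_kind, "coding")
  expect_equal(p$anchor_pos, 306L)
  expect_equal(p$intron_offset, 4L)
  expect_equal(p$edit_kind, "substitution")
  expect_equal(p$ref, "A"); expect_equal(p$alt, "G")

  p <- parse_hgvs_c("NM_002947.4:c.-1028+959C>A")
  expect_equal(p$anchor_kind, "utr5")
  expect_equal(p$anchor_pos, -1028L)
  expect_equal(p$intron_offset, 959L)

  p <- parse_hgvs_c("c.*84T>G")
  expect_equal(p$anchor_kind, "utr3")
  expect_equal(p$anchor_pos, 84L)
  expect_true(is.na(p$intron_offset))

  p <- parse_hgvs_c("c.3802-4_3825dup")
  expect_equal(p$edit_kind, "duplication")
  expect_equal(p$anchor_pos, 3802L)
  expect_equal(p$intron_offset, -4L)
  expect_equal(p$end_anchor_pos, 3825L)
  expect_true(is.na(p$end_intron_offset))
})

test_that("unparseable strings raise errors naming the offending token", {
  expect_error(parse_hgvs_c("c.306+4A>"), "unparseable")
  expect_error(parse_hgvs_c("g.12345A>G"), "not an HGVS c")
  expect_error(parse_hgvs_c("c.foo"), "unparseable")
  expect_error(parse_hgvs_c("c.10+0A>G"), "offset of 0")
})

test_that("parse/format round-trips on the supported grammar", {
  strings <- c("c.306+4A>G", "c.-1028+959C>A", "c.*84T>G",
               "c.3802-4_3825dup", "c.-76G>T", "c.628-7C>A", "c.453G>A",
               "c.100_102del", "c.55_56insTTA", "c.10delinsGG",
               "c.-757-15069A>G")
  for (s in strings) expect_identical(format(parse_hgvs_c(s)), s)
})

test_that("region classification partitions variants as expected", {
  expect_equal(classify_region(parse_hgvs_c("c.628-7C>A"))$region,
               "INTRON_SPLICE")
  expect_equal(classify_region(parse_hgvs_c("c.628-7C>A"))$splice_distance, 7L)
  expect_equal(classify_region(parse_hgvs_c("c.208+972T>G"))$region,
               "INTRON_DEEP")
  expect_equal(classify_region(parse_hgvs_c("c.208+972T>G"))$splice_distance,
               972L)
  expect_equal(classify_region(parse_hgvs_c("c.-76G>T"))$region, "UTR5")
  expect_equal(classify_region(parse_hgvs_c("c.*84T>G"))$region, "UTR3")
  # boundary-spanning edit touching a coding base is exonic
  expect_equal(classify_region(parse_hgvs_c("c.3802-4_3825dup"))$region,
               "EXON")
  # UTR-anchored intronic offsets dominate the UTR anchor
  expect_equal(classify_region(parse_hgvs_c("c.-1028+959C>A"))$region,
               "INTRON_DEEP")
  # the cut-off is configurable
  expect_equal(classify_region(parse_hgvs_c("c.100+12A>G"),
                               splice_max = 20)$region, "INTRON_SPLICE")
})

test_that("projection and c.->genomic mapping are mutual inverses on every base", {
  for (strand in c("+", "-")) {
    tx <- toy_tx(strand)
    span <- c(tx$exons[1, 1], tx$exons[nrow(tx$exons), 2])
    for (g in span[1]:span[2]) {
      a <- project_genomic(tx, g)
      g2 <- cdna_to_genomic(tx, a$anchor_kind, a$anchor_pos, a$intron_offset)
      expect_identical(g2, g)
    }
  }
})

test_that("projection anchors follow the HGVS conventions", {
  tx <- toy_tx("+")
  # first CDS base is c.1
  a <- project_genomic(tx, tx$cds_start)
  expect_equal(a$anchor_kind, "coding")
  expect_equal(a$anchor_pos, 1L)
  # 4 nt into intron 1 from the donor side
  a <- project_genomic(tx, 1000L + 64L)   # t64 = donor + 4
  expect_equal(a$intron_offset, 4L)
  expect_equal(a$anchor_pos, 40L)         # exon 1 ends at c.40
  # position outside the span errors
  expect_error(project_genomic(tx, 99L), "outside")
})

test_that("consequence calling compares reference and altered translations", {
  tx <- toy_tx("+")
  # codon 2 is TAC (Tyr): c.6C>A makes TAA, a premature stop
  cq <- call_consequence(tx, parse_hgvs_c("c.6C>A"))
  expect_equal(cq$kind, "nonsense")
  expect_equal(cq$protein_change, "p.(Tyr2*)")
  # codon 4 CGT -> CGC is synonymous
  cq <- call_consequence(tx, parse_hgvs_c("c.12T>C"))
  expect_equal(cq$kind, "synonymous")
  expect_equal(cq$protein_change, "p.(Arg4=)")
  # codon 3 GTA -> GCA is missense
  cq <- call_consequence(tx, parse_hgvs_c("c.8T>C"))
  expect_equal(cq$kind, "missense")
  expect_equal(cq$protein_change, "p.(Val3Ala)")
  # intronic anchor is noncoding
  cq <- call_consequence(tx, parse_hgvs_c("c.40+4A>G"))
  expect_equal(cq$kind, "noncoding")
  # same calls on the minus-strand version of the same transcript
  txm <- toy_tx("-")
  expect_equal(call_consequence(txm, parse_hgvs_c("c.6C>A"))$kind, "nonsense")
  expect_equal(call_consequence(txm, parse_hgvs_c("c.8T>C"))$protein_change,
               "p.(Val3Ala)")
})

test_that("stop-loss reports the extension to the next in-frame stop", {
  # single-exon transcript: 3 nt 5'UTR, 12 nt CDS ending TAA, then a 3'UTR
  # whose first in-frame stop sits 15 codons downstream
  utr3 <- paste0(strrep("AAA", 14), "TAA", "GGG")
  s <- paste0("GGG", "ATGAAACCCTAA", utr3)
  tx <- transcript("TOY1", "NM_TOYSL.1", "chrT", "+",
                   rbind(c(1L, nchar(s))), cds_start = 4L, cds_end = 15L,
                   seq = s, seq_offset = 1L)
  cq <- call_consequence(tx, parse_hgvs_c("c.10T>G"))  # TAA -> GAA
  expect_equal(cq$kind, "stop_loss")
  expect_equal(cq$extension_aa, 15L)
  expect_equal(cq$protein_change, "p.(*4Gluext*15)")
})

test_that("pnomen interpretation covers the fixture's protein-change shapes", {
  expect_equal(consequence_from_pnomen(
    c("p.(Ser470*)", "p.(*1149Argext*15)", "p.(Thr151=)", "p.(Lys670Arg)",
      "p.(?)", "p.(Glu1276*)")),
    c("nonsense", "stop_loss", "synonymous", "missense", "unknown",
      "nonsense"))
})

test_that("transcript construction validates its invariants", {
  expect_error(transcript("G", "T", "chr1", "+", rbind(c(10, 5)), 10, 12),
               "end before start")
  expect_error(transcript("G", "T", "chr1", "*", rbind(c(1, 10)), 2, 8),
               "strand")
  expect_error(transcript("G", "T", "chr1", "+",
                          rbind(c(1, 10), c(5, 20)), 2, 8), "overlapping")
  expect_error(transcript("G", "T", "chr1", "+",
                          rbind(c(1, 10), c(20, 30)), 2, 15), "CDS")
})
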
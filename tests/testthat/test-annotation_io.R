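# Cell parsers, VCF round-trip, annotation-table reading/merging and the
# packaged fixture loader.

test_that("frequency cells parse percent strings and explicit absence", {
  expect_equal(parse_gnomad_freq("0.0787%"), 0.000787)
  expect_equal(parse_gnomad_freq("0.0012%"), 0.000012)
  expect_true(is.na(parse_gnomad_freq("NIL")))
  expect_true(is.na(parse_gnomad_freq("")))
  expect_equal(parse_gnomad_freq("0.0005"), 0.0005)   # plain fraction
})

test_that("ClinVar cells parse counts, statuses and absence", {
  r <- parse_clinvar_cell(c("6 x VUS", "8 X Pathogenic", "NIL",
                            "3 X Likely benign"))
  expect_equal(r$clinvar_status, c("vus", "pathogenic", "none",
                                   "likely_benign"))
  expect_equal(r$clinvar_n, c(6L, 8L, 0L, 3L))
  expect_error(parse_clinvar_cell("6 x Banana"), "unknown ClinVar status")
})

test_that("VCF records round-trip through write and read", {
  recs <- data.frame(
    sample_id = rep(c("S1", "S2"), each = 3),
    chrom = rep("chr1", 6),
    gpos = rep(c(100L, 200L, 300L), 2),
    ref = rep(c("A", "C", "G"), 2),
    alt = rep(c("T", "G", "A"), 2),
    vaf = c(0.5, 0.4, 0.55, 0.45, 0.6, 0.35),
    depth = c(40L, 55L, 60L, 30L, 80L, 45L),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_vcf(recs, path)
  back <- read_vcf(path)
  # a 2-sample, 3-site VCF decomposes into 6 records
  expect_equal(nrow(back), 6L)
  key <- function(d) order(d$sample_id, d$gpos)
  back <- back[key(back), ]; recs <- recs[key(recs), ]
  for (f in c("sample_id", "chrom", "gpos", "ref", "alt", "depth"))
    expect_equal(back[[f]], recs[[f]])
  expect_equal(back$vaf, recs$vaf, tolerance = 1e-6)
})

test_that("VAF comes from the AD ratio when AD is present", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    paste(c("chr1", "500", ".", "A", "G", ".", "PASS", ".", "GT:AD",
            "0/1:30,30"), collapse = "\t"),
    # multiallelic site decomposes into one record per carried allele
    paste(c("chr1", "600", ".", "C", "G,T", ".", "PASS", ".", "GT:AD",
            "1/2:10,20,10"), collapse = "\t")), path)
  r <- read_vcf(path)
  expect_equal(r$vaf[r$gpos == 500], 0.5)
  expect_equal(nrow(r[r$gpos == 600, ]), 2L)
  expect_equal(sort(r$alt[r$gpos == 600]), c("G", "T"))
  expect_equal(r$vaf[r$gpos == 600 & r$alt == "G"], 0.5)
  expect_equal(r$vaf[r$gpos == 600 & r$alt == "T"], 0.25)
})

test_that("annotation tables respect the column map and flag missing columns", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tgpos\tref\talt\tcnomen\tgnomad\tclinvar",
               "chr1\t100\tA\tT\tc.10A>T\t0.050%\t2 X VUS",
               "chr1\t200\tC\tG\tc.20C>G\tNIL\tNIL"), path)
  ann <- read_annotation_table(path)
  expect_equal(ann$gnomad_af, c(0.0005, NA))
  expect_equal(ann$clinvar_status, c("vus", "none"))
  expect_equal(ann$clinvar_n, c(2L, 0L))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tgpos", "chr1\t100"), bad)
  expect_error(read_annotation_table(bad), "lacks mapped column")
})

test_that("merging carries unmatched variants with absent annotations", {
  vcf <- data.frame(sample_id = c("S1", "S1"), chrom = "chr1",
                    gpos = c(100L, 999L), ref = "A", alt = "T",
                    vaf = 0.5, depth = 40L, stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "chr1", gpos = 100L, ref = "A", alt = "T",
                    cnomen = "c.10A>T", gnomad_af = 0.0001,
                    clinvar_status = "vus", clinvar_n = 2L,
                    stringsAsFactors = FALSE)
  expect_message(m <- merge_annotations(vcf, ann), "no annotation match")
  expect_equal(m$cnomen, c("c.10A>T", NA))
  expect_equal(m$clinvar_status, c("vus", "none"))  # explicit absent state
  expect_equal(m$clinvar_n, c(2L, 0L))
})

test_that("the packaged fixture satisfies its documented invariants", {
  fix <- load_table2_fixture()
  expect_equal(nrow(fix), 35L)
  expect_equal(as.integer(table(factor(fix$expected_class, levels = 3:5))),
               c(31L, 1L, 3L))
  # one PMS2 variant carried by two patients
  pms2 <- fix[fix$gene_symbol == "PMS2", ]
  expect_equal(nrow(pms2), 1L)
  expect_equal(pms2$n_samples, 2L)
  expect_setequal(strsplit(pms2$sample_id, ",")[[1]], c("051179", "051300"))
  # the 5'UTR variant with no frequency and no ClinVar record
  utr <- fix[fix$cnomen == "c.-76G>T", ]
  expect_true(is.na(utr$gnomad_af))
  expect_equal(utr$clinvar_status, "none")
  # per-patient expansion yields 37 rows over 33 patients
  exp <- expand_fixture_samples(fix)
  expect_equal(nrow(exp), 37L)
  expect_equal(length(unique(exp$sample_id)), 33L)
  expect_equal(exp$vaf[exp$sample_id == "051300"], 0.47)
})

test_that("panel models round-trip through JSON + FASTA", {
  panel <- list(toy_tx("+"), toy_tx("-"))
  names(panel) <- vapply(panel, `[[`, character(1), "transcript_id")
  json <- tempfile(fileext = ".json"); fa <- tempfile(fileext = ".fa")
  write_panel_json(panel, json, fasta = fa)
  back <- read_panel_json(json, fasta = fa)
  expect_equal(names(back), names(panel))
  for (nm in names(panel)) {
    expect_equal(back[[nm]]$exons, panel[[nm]]$exons)
    expect_equal(back[[nm]]$strand, panel[[nm]]$strand)
    expect_equal(back[[nm]]$cds_start, panel[[nm]]$cds_start)
    expect_equal(back[[nm]]$seq, panel[[nm]]$seq)
  }
})
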
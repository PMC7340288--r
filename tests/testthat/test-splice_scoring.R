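# PWM percent scoring and splice-event calls.

# direct arithmetic oracle for the percent score of a small matrix
pct_oracle <- function(freq, window) {
  b <- strsplit(window, "")[[1]]
  s <- sum(vapply(seq_along(b), function(i)
    freq[b[i], i], numeric(1)))
  smin <- sum(apply(freq, 2, min)); smax <- sum(apply(freq, 2, max))
  (s - smin) / (smax - smin)
}

# a 2-position toy matrix assembled directly (score_site only requires the
# splice_matrix fields)
toy2_matrix <- function() {
  freq <- cbind(c(A = 0.7, C = 0.1, G = 0.1, T = 0.1),
                c(A = 1 / 30, C = 1 / 30, G = 0.9, T = 1 / 30))
  structure(list(kind = "donor", freq = freq, length = 2L,
                 smin = sum(apply(freq, 2, min)),
                 smax = sum(apply(freq, 2, max))),
            class = "splice_matrix")
}

test_that("percent score equals the exhaustive oracle on all 16 toy windows", {
  m <- toy2_matrix()
  bases <- c("A", "C", "G", "T")
  for (b1 in bases) for (b2 in bases) {
    w <- paste0(b1, b2)
    expect_equal(score_site(m, w), pct_oracle(m$freq, w), tolerance = 1e-12)
  }
  # hand-computed case: "CG" = (0.1 + 0.9 - Smin) / (Smax - Smin)
  expect_equal(score_site(m, "CG"),
               (1.0 - (0.1 + 1 / 30)) / (1.6 - (0.1 + 1 / 30)),
               tolerance = 1e-12)
})

test_that("best and worst windows score exactly 1 and 0", {
  m <- toy2_matrix()
  expect_equal(score_site(m, "AG"), 1)
  expect_equal(score_site(m, "CA"), 0)   # C ties min col1; A ties min col2
  mats <- toy_matrices()
  expect_equal(score_site(mats$donor, "CAGGTAAGT"), 1)
})

test_that("score_site validates window length and alphabet", {
  mats <- toy_matrices()
  expect_error(score_site(mats$donor, "ACGT"), "length")
  expect_error(score_site(mats$donor, "CAGGTANGT"), "non-ACGT")
})

test_that("panel-estimated matrices make canonical junctions score high", {
  panel <- list(toy_tx("+"), toy_tx("-"))
  names(panel) <- vapply(panel, `[[`, character(1), "transcript_id")
  mats <- estimate_splice_matrices(panel)
  expect_equal(sum(mats$donor$freq[, 1]), 1)      # columns normalized
  expect_equal(sum(mats$acceptor$freq[, 8]), 1)
  for (tx in panel) for (i in 1:2) {
    dw <- mmrscreen:::.strand_bases(tx, mmrscreen:::.donor_window_pos(tx, i))
    expect_gte(score_site(mats$donor, dw), 0.7)
  }
})

test_that("destroying the invariant AG at acceptor -1 is complete site loss", {
  mats <- toy_matrices()
  for (strand in c("+", "-")) {
    tx <- toy_tx(strand)
    ev <- evaluate_variant(tx, parse_hgvs_c("c.41-1G>T"), mats)
    expect_equal(ev$delta, -1)
    expect_true("deactivation" %in% ev$events)
  }
})

test_that("destroying the invariant GT at donor +1 is complete site loss", {
  mats <- toy_matrices()
  tx <- toy_tx("+")
  ev <- evaluate_variant(tx, parse_hgvs_c("c.40+1G>A"), mats)
  expect_equal(ev$delta, -1)
  expect_true("deactivation" %in% ev$events)
})

test_that("a variant away from any canonical window has delta 0, no events", {
  mats <- toy_matrices()
  tx <- toy_tx("+")
  ev <- evaluate_variant(tx, parse_hgvs_c("c.40+40T>A"), mats)
  expect_equal(ev$delta, 0)
  expect_length(ev$events, 0)
})

test_that("a deep-intronic substitution completing a donor motif is a new site", {
  mats <- toy_matrices()
  cfg <- splice_config()
  tx <- toy_tx("+")
  # the planted broken donor CAGGAAAGT sits at t230-238; t234 (c.100+34) A>T
  # restores CAGGTAAGT
  ev <- evaluate_variant(tx, parse_hgvs_c("c.100+34A>T"), mats, cfg)
  expect_true("new_donor" %in% ev$events)

  # brute-force oracle: rescan every donor window in the altered intron 2
  alt_seq <- tx$seq
  idx <- (1000L + 234L) - tx$seq_offset + 1L
  substr(alt_seq, idx, idx) <- "T"
  gained <- FALSE
  for (st in 1202:1272) {       # genomic window starts within intron 2
    w_ref <- substr(tx$seq, st - 1000L, st - 1000L + 8L)
    w_alt <- substr(alt_seq, st - 1000L, st - 1000L + 8L)
    eff <- function(w) if (substr(w, 4, 5) == "GT")
      score_site(mats$donor, w) else 0
    if (eff(w_ref) < cfg$new_site_tau && eff(w_alt) >= cfg$new_site_tau)
      gained <- TRUE
  }
  expect_true(gained)
})

test_that("evaluating a site against itself yields delta 0 and no events", {
  mats <- toy_matrices()
  tx <- toy_tx("+")
  # same-base "substitution": alt equals the reference base at c.40+1 (G)
  ev <- evaluate_variant(tx, parse_hgvs_c("c.40+1G>G"), mats)
  expect_equal(ev$delta, 0)
  expect_length(ev$events, 0)
})

test_that("non-substitution edits return an empty evaluation", {
  mats <- toy_matrices()
  ev <- evaluate_variant(toy_tx("+"), parse_hgvs_c("c.30_32del"), mats)
  expect_equal(ev$delta, 0)
  expect_length(ev$events, 0)
})
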
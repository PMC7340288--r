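# Independent oracles shared by the unit and acceptance suites: a literal
# transliteration of the published evidence-combining table, and a
# brute-force seed-site scanner.

# independent oracle: literal row-by-row lookup in the combining table
combining_table_oracle <- function(codes) {
  vs <- sum(codes == "PVS1")
  st <- sum(grepl("^PS", codes)); mo <- sum(grepl("^PM", codes))
  su <- sum(grepl("^PP", codes))
  ba <- any(codes == "BA1")
  bst <- sum(grepl("^BS", codes)); bsu <- sum(grepl("^BP", codes))
  P <- (vs >= 1 && st >= 1) || (vs >= 1 && mo >= 2) ||
       (vs >= 1 && mo == 1 && su == 1) || (vs >= 1 && su >= 2) ||
       (st >= 2) ||
       (st == 1 && mo >= 3) || (st == 1 && mo == 2 && su >= 2) ||
       (st == 1 && mo == 1 && su >= 4)
  LP <- (vs == 1 && mo == 1) ||
        (st == 1 && (mo == 1 || mo == 2)) ||
        (st == 1 && su >= 2) ||
        (mo >= 3) || (mo == 2 && su >= 2) || (mo == 1 && su >= 4)
  B <- ba || bst >= 2
  LB <- (bst == 1 && bsu >= 1) || bsu >= 2
  if ((P || LP) && (B || LB)) return(3L)
  if (P) return(5L)
  if (LP) return(4L)
  if (B) return(1L)
  if (LB) return(2L)
  3L
}

mirna_scan_brute <- function(utr, mir, nm) {
  mirT <- chartr("U", "T", toupper(mir))
  core <- rc_oracle(substr(mirT, 2, 7))
  m8 <- rc_oracle(substr(mirT, 8, 8))
  res <- list()
  n <- nchar(utr)
  for (s in 0:(n - 6)) {
    if (substr(utr, s + 1, s + 6) != core) next
    hm8 <- s >= 1 && substr(utr, s, s) == m8
    ha1 <- s + 7 <= n && substr(utr, s + 7, s + 7) == "A"
    if (hm8 && ha1) res[[length(res) + 1]] <- c(nm, "8mer", s - 1, s + 7)
    else if (hm8) res[[length(res) + 1]] <- c(nm, "7mer_m8", s - 1, s + 6)
    else if (ha1) res[[length(res) + 1]] <- c(nm, "7mer_A1", s, s + 7)
  }
  res
}
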
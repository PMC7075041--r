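# Published sequence-based alleles of the 9947A control DNA sample:
# per-locus sequence structure, the two allele decompositions observed,
# their CE-compatible designations, the supporting read depths, and the
# stutter-corrected genotype at the default 0.5 ratio ("-" = no
# correction). Loci whose panel annotation is known to disagree with the
# CE nomenclature (shifted by whole repeat units) are not included.
golden_9947A <- function() {
  rows <- list(
    list("D1S1677", "[TTCC]n", "[TTCC]13", "13", "[TTCC]14", "14", 592, 498, NA),
    list("D1S1656", "CCTA [TCTA]n",
         "CCTA [TCTA]13 TCATCTATCTATCTATCTA", "18.3",
         "CCTA [TCTA]13 TCATCTATCTATCTATCTACA", "19.1", 1182, 378, "18.3,18.3"),
    list("TPOX", "[AATG]n", "[AATG]8", "8", "[AATG]7", "7", 2554, 95, "8,8"),
    list("D2S441", "[TCTA]n", "[TCTA]8 TCTGTCTA", "10",
         "[TCTA]11 TTTATCTATCTA", "14", 1007, 874, NA),
    list("D2S1776", "[AGAT]n", "[AGAT]10", "10", "[AGAT]9", "9", 2825, 172, "10,10"),
    list("D2S1338", "[GGAA]n GGAC [GGAA]n [GGCA]n",
         "[GGAA]12 [GGCA]7", "19", "[GGAA]2 GGAC [GGAA]13 [GGCA]7", "23",
         718, 715, NA),
    list("D3S1358", "[TCTA]n [TCTG]n [TCTA]n",
         "[TCTA]1 [TCTG]2 [TCTA]12", "15", "[TCTA]1 [TCTG]2 [TCTA]11", "14",
         2052, 1916, NA),
    list("D3S4529", "[GATA]n AATA [GATA]n",
         "[GATA]4 AATA [GATA]7", "12", "[GATA]4 AATA [GATA]6", "11",
         1886, 65, "12,12"),
    list("D4S2408", "[ATCT]n", "[ATCT]10", "10", "[ATCT]9", "9", 98, 56, NA),
    list("D5S2800", "[GGTA]n [GACA]n [GATA]n [GATT]n",
         "[GGTA]3 [GACA]6 [GATA]2 [GATT]3", "14",
         "[GGTA]9 [GACA]6 [GATA]3 [GATT]5", "23", 1130, 876, NA),
    list("D5S818", "[ATCT]n", "[ATCT]11", "11", NA, NA, 2373, 295, "11,11"),
    list("CSF1PO", "[ATCT]n", "[ATCT]10", "10", "[ATCT]12", "12", 1348, 1178, NA),
    list("D6S1043", "[ATCT]n", "[ATCT]12", "12",
         "ATCTATCTATCTATCTATCTATGT [ATCT]12", "18", 1693, 1263, NA),
    list("D6S474", "[AGAT]n [GATA]n", "[AGAT]5 [GATA]9", "14",
         "[AGAT]5 [GATA]13", "18", 1898, 1304, NA),
    list("D7S820", "[TATC]n", "[TATC]10", "10", "[TATC]11", "11", 1133, 823, NA),
    list("D8S1179", "[TCTA]n [TCTG]n [TCTA]n",
         "[TCTA]1 [TCTG]1 [TCTA]11", "13", "[TCTA]13", "13", 1382, 998, NA),
    list("D10S1248", "[GGAA]n", "[GGAA]13", "13", "[GGAA]15", "15", 815, 811, NA),
    list("TH01", "[AATG]n ATG [AATG]n", "[AATG]8", "8",
         "[AATG]6 ATG [AATG]3", "9.3", 1728, 1527, NA),
    list("vWA", "[TAGA]n [CAGA]n TAGA", "[TAGA]12 [CAGA]4 TAGA", "17",
         "[TAGA]13 [CAGA]4 TAGA", "18", 1330, 952, NA),
    list("D12S391", "[AGAT]n GAT [AGAT]n [AGAC]n AGAT",
         "[AGAT]11 [AGAC]6 AGAT", "18", "[AGAT]12 [AGAC]7 AGAT", "20",
         1171, 846, NA),
    list("D12ATA63", "[TTG]n [TTA]n", "[TTG]3 [TTA]10", "13",
         "[TTG]3 [TTA]9", "12", 1697, 214, "13,13"),
    list("D13S317", "[TATC]n", "[TATC]11", "11", "[TATC]10", "10",
         2216, 177, "11,11"),
    list("D14S1434", "[CTGT]n [CTAT]n", "[CTGT]3 [CTAT]8", "11",
         "[CTGT]3 [CTAT]10", "13", 1418, 1094, NA),
    list("PentaE", "[TCTTT]n", "[TCTTT]12", "12", "[TCTTT]13", "13",
         443, 425, NA),
    list("D16S539", "[GATA]n", "[GATA]11", "11", "[GATA]12", "12",
         2293, 1661, NA),
    list("D21S11",
         "[TCTA]n [TCTG]n [TCTA]n ta [TCTA]n tca [TCTA]n tccata [TCTA]n TA [TCTA]n",
         "[TCTA]6 [TCTG]5 [TCTA]3 ta [TCTA]3 tca [TCTA]2 tccata [TCTA]11", "30",
         "[TCTA]6 [TCTG]5 [TCTA]3 ta [TCTA]3 tca [TCTA]2 tccata [TCTA]10", "29",
         1450, 166, "30,30"),
    list("D22S1045", "[ATT]n ACT [ATT]n", "[ATT]8 ACT [ATT]2", "11",
         "[ATT]11 ACT [ATT]2", "14", 1033, 616, NA)
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(marker = r[[1]], structure = r[[2]],
               seq1 = r[[3]], allele1 = r[[4]],
               seq2 = r[[5]], allele2 = r[[6]],
               depth1 = r[[7]], depth2 = r[[8]],
               corrected = r[[9]], stringsAsFactors = FALSE)
  }))
}

# Expand a decomposition-style string ("[TCTA]6 ta TCA ...") into the
# raw region sequence it denotes.
region_from_decomposition <- function(text) {
  tokens <- strsplit(trimws(text), " ", fixed = TRUE)[[1]]
  paste(vapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^\\[([ACGT]+)\\]([0-9]+)$", tok))[[1]]
    if (length(m) == 3L) strrep(m[2], as.integer(m[3])) else toupper(tok)
  }, ""), collapse = "")
}

golden_structures <- function() {
  unique(golden_9947A()$structure)
}
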
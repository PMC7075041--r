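fake_call <- function(designation, decomposition = NULL) {
  d <- as_des(designation)
  structure(
    list(read_id = "r", designation = d,
         decomposition = decomposition %||% paste0("[SEQ]", format(d)),
         dist_5p = 5L, dist_3p = 20L, mean_region_quality = 35),
    class = "read_allele_call"
  )
}

as_des <- function(x) if (inherits(x, "str_designation")) x else parse_designation(x)

fake_calls <- function(...) {
  spec <- list(...)
  unlist(lapply(spec, function(s) {
    rep(list(fake_call(s$allele, s$decomposition %||% NULL)), s$n)
  }), recursive = FALSE)
}

test_that("tallies count calls by designation and decomposition, deterministically ordered", {
  calls <- fake_calls(list(allele = "8", n = 3), list(allele = "7", n = 1))
  t <- tally_alleles(calls)
  expect_equal(t$total, 4L)
  expect_equal(t$entries$count, c(3L, 1L))
  expect_equal(t$entries$designation, c("8", "7"))

  empty <- tally_alleles(list())
  expect_equal(empty$total, 0L)
  expect_equal(nrow(empty$entries), 0L)

  # sequence variants of one CE allele remain separate tally entries
  calls2 <- c(
    rep(list(fake_call("18.3", "[TCTA]18 TCA")), 5),
    rep(list(fake_call("18.3", "[TCTA]17 ACAT TCA")), 2)
  )
  t2 <- tally_alleles(calls2)
  expect_equal(nrow(t2$entries), 2L)
  expect_equal(sum(t2$entries$count), 7L)
})

test_that("noise removal drops alleles at or below the threshold and conserves read mass", {
  calls <- fake_calls(list(allele = "10", n = 980), list(allele = "9", n = 10),
                      list(allele = "8", n = 10))
  t <- filter_noise(tally_alleles(calls))
  # entries at exactly 1% of 1000 reads are noise ("no more than 1%")
  expect_equal(nrow(t$entries), 1L)
  expect_equal(t$removed_reads + sum(t$entries$count), t$total)

  calls2 <- fake_calls(list(allele = "10", n = 989), list(allele = "9", n = 11))
  t2 <- filter_noise(tally_alleles(calls2))
  expect_equal(t2$entries$designation, c("10", "9"))   # 11/1000 survives

  t3 <- filter_noise(tally_alleles(fake_calls(list(allele = "5", n = 2),
                                              list(allele = "4", n = 2))),
                     noise_frac = 0.6)
  expect_equal(nrow(t3$entries), 0L)
  gt3 <- call_genotype(t3, "diploid")
  expect_equal(gt3$status, "NA")
})

test_that("stutter-ratio filtering reproduces the 9947A worked genotypes", {
  # TPOX: (8, 7) at (2554, 95), ratio 0.037 -> corrected homozygote (8, 8)
  tpox <- tally_alleles(fake_calls(list(allele = "8", n = 2554),
                                   list(allele = "7", n = 95)))
  gt <- call_genotype(tpox, "diploid")
  expect_equal(c(gt$allele1, gt$allele2), c("8", "8"))
  expect_true(gt$correction_applied)
  expect_equal(gt$depth2, 95L)

  # D2S441: (10, 14) at (1007, 874), ratio 0.868 -> heterozygote kept
  d2 <- tally_alleles(fake_calls(list(allele = "10", n = 1007),
                                 list(allele = "14", n = 874)))
  gt2 <- call_genotype(d2, "diploid")
  expect_equal(c(gt2$allele1, gt2$allele2), c("10", "14"))
  expect_false(gt2$correction_applied)
  expect_equal(gt2$stutter_ratio, 874 / 1007)

  # D1S1656: (18.3, 19.1) at (1182, 378), ratio 0.32 -> corrected (18.3, 18.3)
  d1 <- tally_alleles(fake_calls(list(allele = "18.3", n = 1182),
                                 list(allele = "19.1", n = 378)))
  gt3 <- call_genotype(d1, "diploid")
  expect_equal(c(gt3$allele1, gt3$allele2), c("18.3", "18.3"))
  expect_true(gt3$correction_applied)
})

test_that("a ratio exactly at the threshold stays heterozygous", {
  t <- tally_alleles(fake_calls(list(allele = "12", n = 200),
                                list(allele = "11", n = 100)))
  gt <- call_genotype(t, "diploid", stutter_threshold = 0.5)
  expect_equal(c(gt$allele1, gt$allele2), c("12", "11"))
  expect_false(gt$correction_applied)
})

test_that("sequence variants pool their depth under one CE designation before ranking", {
  calls <- c(
    rep(list(fake_call("18.3", "varA")), 300),
    rep(list(fake_call("18.3", "varB")), 300),
    rep(list(fake_call("17", "varC")), 400)
  )
  gt <- call_genotype(tally_alleles(calls), "diploid")
  expect_equal(gt$allele1, "18.3")      # 600 pooled reads beat 400
  expect_equal(gt$allele2, "17")
  expect_equal(gt$depth1, 600L)
})

test_that("depth ties prefer the longer allele as the heterozygote partner", {
  t <- tally_alleles(fake_calls(list(allele = "13", n = 500),
                                list(allele = "12", n = 400),
                                list(allele = "14", n = 400)))
  gt <- call_genotype(t, "diploid")
  expect_equal(c(gt$allele1, gt$allele2), c("13", "14"))
})

test_that("haploid loci report the modal allele and everything else as stutter", {
  t <- tally_alleles(fake_calls(list(allele = "12", n = 900),
                                list(allele = "11", n = 90)))
  gt <- call_genotype(t, "haploid")
  expect_equal(gt$allele1, "12")
  expect_true(is.na(gt$allele2))
  expect_equal(gt$stutter_ratio, 0.1)

  rows <- strcaller:::multi_allele_rows("DYS1", filter_noise(t), gt)
  expect_equal(rows$role[rows$allele == "12"], "allele")
  expect_equal(rows$role[rows$allele == "11"], "stutter")
})

test_that("correction and the stutter dichotomy hold over random tallies", {
  set.seed(23)
  for (i in 1:50) {
    d1 <- sample(100:2000, 1)
    d2 <- sample(10:d1, 1)
    t <- tally_alleles(fake_calls(list(allele = "10", n = d1),
                                  list(allele = "9", n = d2)))
    gt <- call_genotype(t, "diploid")
    expect_equal(gt$correction_applied, (d2 / d1) < 0.5)
    if (gt$correction_applied) expect_equal(gt$allele2, gt$allele1)
    expect_gte(gt$depth1, gt$depth2)
    expect_lte(gt$stutter_ratio, 1)
  }
})

test_that("report files are deterministic and keep NA loci as rows", {
  gt1 <- call_genotype(tally_alleles(fake_calls(list(allele = "8", n = 90),
                                                list(allele = "7", n = 10))),
                       "diploid")
  gt1$marker <- "M1"
  gt2 <- strcaller:::na_genotype("M2")
  tl1 <- filter_noise(tally_alleles(fake_calls(list(allele = "8", n = 90),
                                               list(allele = "7", n = 10))))
  tl2 <- tally_alleles(list())
  qc <- rbind(
    compute_qc("M1", new_reads("r", "ACGT", list(rep(30L, 4))), list(),
               c(no_motif = 1L), gt1),
    compute_qc("M2", new_reads(), list(), integer(0), gt2)
  )
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  p1 <- write_reports(list(gt1, gt2), list(tl1, tl2), qc, out1)
  p2 <- write_reports(list(gt1, gt2), list(tl1, tl2), qc, out2)
  expect_identical(readLines(p1["genotypes"]), readLines(p2["genotypes"]))
  expect_identical(readLines(p1["multiple_alleles"]), readLines(p2["multiple_alleles"]))

  g <- utils::read.delim(p1["genotypes"], na.strings = "")
  expect_equal(g$marker, c("M1", "M2"))
  expect_equal(g$status, c("called", "NA"))
  expect_true(is.na(g$allele1[2]))

  # empty panel -> header-only files
  p0 <- write_reports(list(), list(), qc[0, ], withr::local_tempdir())
  expect_length(readLines(p0["genotypes"]), 1L)
  expect_length(readLines(p0["multiple_alleles"]), 1L)
  expect_length(readLines(p0["qc_matrix"]), 1L)
})
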
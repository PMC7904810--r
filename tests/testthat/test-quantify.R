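cfg <- neotel_config()

mapped_bg <- function(n, prefix = "b") {
  alignment_records(read_id = sprintf("%s%d", prefix, seq_len(n)),
                    chrom = rep("chr1", n), pos = seq_len(n),
                    mapq = rep(60L, n), strand = rep("+", n),
                    cigar = rep("100M", n), seq = rep(BG100, n))
}
unmapped_tel <- function(n, prefix = "t") {
  alignment_records(read_id = sprintf("%s%d", prefix, seq_len(n)),
                    seq = rep(TEL100, n))
}

test_that("TERRA normalization is exact on constructed counts", {
  rec <- rbind(unmapped_tel(5), mapped_bg(9995))
  tr <- terra_quantify(rec, "s1", cfg)
  expect_equal(tr$terra_reads, 5L)
  expect_equal(tr$terra_per_million, 500)     # 5 / 10^4 reads, per million
  # mapped and unmapped qualifying reads count alike
  rec2 <- rbind(
    alignment_records("mt", "chr7", 10L, 60L, "+", "100M", TEL100),
    unmapped_tel(1, "ut"), mapped_bg(2))
  expect_equal(terra_quantify(rec2, cfg = cfg)$terra_reads, 2L)
  expect_error(terra_quantify(mapped_bg(0), cfg = cfg), "empty")
})

test_that("enrichment identities hold exactly on constructed fixtures", {
  ip <- rbind(unmapped_tel(100), mapped_bg(10000))
  inp <- rbind(unmapped_tel(50), mapped_bg(10000))
  r <- repeat_enrichment(ip, inp, "telomere", cfg = cfg)
  expect_equal(r$log2_enrichment, 1)          # exact 2:1 fixture
  same <- repeat_enrichment(ip, ip, "telomere", cfg = cfg)
  expect_equal(same$log2_enrichment, 0)
  # antisymmetry under IP/input swap
  rswap <- repeat_enrichment(inp, ip, "telomere", cfg = cfg)
  expect_equal(rswap$log2_enrichment, -r$log2_enrichment)
  # scale invariance: duplicating every read changes nothing
  r2 <- repeat_enrichment(rbind(ip, within(ip, read_id <- paste0(read_id, "x"))),
                          rbind(inp, within(inp, read_id <- paste0(read_id, "x"))),
                          "telomere", cfg = cfg)
  expect_equal(r2$log2_enrichment, r$log2_enrichment)
  # zero repeat reads in input is undefined, with a reason
  r0 <- repeat_enrichment(ip, mapped_bg(1000), "telomere", cfg = cfg)
  expect_true(is.na(r0$log2_enrichment))
  expect_match(attr(r0, "reason"), "input")
})

test_that("satellite classes are computed independently of the telomere class", {
  sat_read <- paste0(strrep("A", 40), cfg$satII_canonical, strrep("A", 40))
  rec <- rbind(
    alignment_records("s1", "chr1", 1L, 60L, "+", "100M", sat_read),
    mapped_bg(99, "bb"))
  r_sat <- repeat_enrichment(rec, rec, "satII", cfg = cfg)
  expect_equal(r_sat$ip_repeat_reads, 1L)
  r_tel <- repeat_enrichment(rec, rec, "telomere", cfg = cfg)
  expect_equal(r_tel$ip_repeat_reads, 0L)
})

test_that("FRiP exclusion uses the 1% threshold with inclusive keep", {
  r <- repeat_enrichment(rbind(unmapped_tel(10), mapped_bg(100)),
                         rbind(unmapped_tel(10), mapped_bg(100)),
                         "telomere", cfg = cfg)
  expect_true(frip_filter(r, 0.005, cfg)$excluded)
  expect_false(frip_filter(r, 0.02, cfg)$excluded)
  expect_false(frip_filter(r, 0.01, cfg)$excluded)
})

test_that("simulated repeat read sets recover configured fractions", {
  rec <- simulate_repeat_readset(200000, telomeric_fraction = 1e-4,
                                 satII_fraction = 5e-4, seed = 99)
  n_tel <- sum(is_telomeric_per100bp(rec$seq, cfg$rna_rt_per_100bp))
  # expected 20 telomeric reads; allow 4 binomial standard deviations
  expect_true(abs(n_tel - 20) <= 4 * sqrt(20))
  n_sat <- sum(is_satellite(rec$seq, cfg$satII_canonical))
  expect_true(abs(n_sat - 100) <= 4 * sqrt(100))
  none <- simulate_repeat_readset(5000, 0, seed = 1)
  expect_equal(sum(is_telomeric_per100bp(none$seq, 14)), 0L)
})
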
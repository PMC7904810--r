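cfg <- neotel_config()

test_that("hexamer counting matches the examples and is strand-independent", {
  expect_equal(unname(count_hexamers(strrep("TTAGGG", 6))[1, ]), c(6L, 0L))
  expect_equal(unname(count_hexamers(strrep("CCCTAA", 6))[1, ]), c(0L, 6L))
  mixed <- paste0("TTAGGGTCAGGGTGAGGGTTGGGG", strrep("A", 76))
  expect_equal(unname(count_hexamers(mixed)[1, ]), c(4L, 0L))
  # N bases never match
  expect_equal(unname(count_hexamers("TTANGGTTAGGG")[1, ]), c(1L, 0L))
})

test_that("hexamer counts agree with a naive scan oracle on random reads", {
  set.seed(42)
  seqs <- random_seq(10000, 60, alphabet = c("A", "C", "G", "T", "N",
                                             "T", "G"))
  got <- count_hexamers(seqs, cfg$hexamers)
  exp_fwd <- vapply(seqs, naive_hexamer_count, integer(1),
                    patterns = cfg$hexamers, USE.NAMES = FALSE)
  exp_rev <- vapply(seqs, naive_hexamer_count, integer(1),
                    patterns = naive_revcomp(cfg$hexamers), USE.NAMES = FALSE)
  expect_equal(unname(got[, "fwd"]), exp_fwd)
  expect_equal(unname(got[, "rev"]), exp_rev)
})

test_that("fixed-count rule thresholds at six instances of any repeat type", {
  six <- paste0(strrep("TTAGGG", 6), strrep("A", 64))
  five <- paste0(strrep("TTAGGG", 5), strrep("A", 70))
  expect_true(is_telomeric_fixed(six))
  expect_false(is_telomeric_fixed(five))
  # mixed repeat types with spacers count together
  mixed <- paste0("TTAGGG", "AA", "TGAGGG", "AA", "TTAGGG", "AA",
                  "TGAGGG", "AA", "TTAGGG", "AA", "TGAGGG")
  expect_true(is_telomeric_fixed(mixed))
  # forward and reverse counts are not summed
  chimera <- paste0(strrep("TTAGGG", 3), strrep("CCCTAA", 3))
  expect_false(is_telomeric_fixed(chimera))
})

test_that("per-100bp rule scales the required count with read length", {
  r14 <- paste0(strrep("TTAGGG", 14), strrep("A", 16))
  r13 <- paste0(strrep("TTAGGG", 13), "A", strrep("CA", 10), "A")
  expect_true(is_telomeric_per100bp(r14, 14))
  expect_false(is_telomeric_per100bp(r13, 14))
  # 50-mer at rt = 8 requires ceil(8 * 0.5) = 4 occurrences
  r50 <- paste0(strrep("TTAGGG", 4), strrep("A", 26))
  expect_true(is_telomeric_per100bp(r50, 8))
  expect_false(is_telomeric_per100bp(paste0(strrep("TTAGGG", 3),
                                            strrep("A", 32)), 8))
})

test_that("satellite rule finds the canonical motif on either strand", {
  hit <- paste0(strrep("A", 30), cfg$satII_canonical, strrep("T", 30))
  expect_true(is_satellite(hit, cfg$satII_canonical))
  rc <- paste0(strrep("G", 20), naive_revcomp(cfg$satIII_canonical),
               strrep("C", 20))
  expect_true(is_satellite(rc, cfg$satIII_canonical))
  set.seed(1)
  expect_false(any(is_satellite(random_seq(50, 100), cfg$satII_canonical)))
})

test_that("classification is strand-symmetric and monotone", {
  set.seed(7)
  seqs <- c(random_seq(200, 100),
            vapply(1:50, function(i) paste0(
              paste(sample(cfg$hexamers, sample(3:10, 1), TRUE),
                    collapse = ""), strrep("A", 10)), ""))
  rc <- revcomp(seqs)
  expect_equal(is_telomeric_fixed(seqs), is_telomeric_fixed(rc))
  expect_equal(is_satellite(seqs, cfg$satII_canonical),
               is_satellite(rc, cfg$satII_canonical))
  # appending one more telomeric hexamer never turns a telomeric read
  # non-telomeric
  before <- is_telomeric_fixed(seqs)
  after <- is_telomeric_fixed(paste0(seqs, "TTAGGG"))
  expect_true(all(after[before]))
})

test_that("classify_reads applies the mode-specific rule", {
  seqs <- c(paste0(strrep("TTAGGG", 6), strrep("A", 64)),   # 6 copies
            paste0(strrep("TTAGGG", 10), strrep("A", 40)),  # 10 copies
            TEL100)                                          # 16 copies
  wgs <- classify_reads(seqs, mode = "wgs")
  expect_equal(wgs$is_telomeric, c(TRUE, TRUE, TRUE))
  rna <- classify_reads(seqs, mode = "rna")
  expect_equal(rna$is_telomeric, c(FALSE, FALSE, TRUE))
  chip <- classify_reads(seqs, mode = "chip")
  expect_equal(chip$is_telomeric, c(FALSE, TRUE, TRUE))
  expect_equal(rna$rule[1], "per_100bp")
  expect_equal(wgs$rule[1], "fixed_count")
})
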
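cfg <- neotel_config()

test_that("generated genomes hit the target GC and are seed-deterministic", {
  sc <- sim_scenario(seed = 31, contigs = c(chrA = 200000L), events = NULL)
  g <- make_genome(sc)
  freq <- Biostrings::letterFrequency(
    Biostrings::DNAString(g$contigs[["chrA"]]), c("C", "G"))
  expect_lt(abs(sum(freq) / 200000 - 0.5), 0.01)
  g2 <- make_genome(sc)
  expect_identical(g$contigs, g2$contigs)
  sc2 <- sim_scenario(seed = 32, contigs = c(chrA = 200000L), events = NULL)
  expect_false(identical(make_genome(sc2)$contigs, g$contigs))
})

test_that("engineered flanks continue the repeat for exactly the requested bases", {
  sc <- sim_scenario(seed = 33, contigs = c(chrA = 10000L),
                     events = data.frame(chrom = "chrA", type = "tel_right",
                                         junction = 5000L,
                                         junction2 = NA_integer_,
                                         microhomology_bp = 4L,
                                         microhomology2_bp = 0L))
  g <- make_genome(sc)
  # phase-0 tract: the four bases left of the junction must read ...ATTA+GGG
  flank <- substr(g$contigs[["chrA"]], 4997, 5000)
  expect_equal(flank, "AGGG")            # expected continuation, reversed walk
  fifth <- substr(g$contigs[["chrA"]], 4996, 4996)
  expect_false(fifth == "T")             # the 5th base breaks the run
})

test_that("event-free simulations contain no clips or discordant pairs", {
  sc <- sim_scenario(seed = 34, contigs = c(chrA = 100000L), events = NULL,
                     coverage = 10)
  sim <- simulate_tumor_alignments(sc)
  expect_null(sim$truth)
  expect_false(any(grepl("S", sim$records$cigar, fixed = TRUE)))
  expect_true(all(sim$records$is_proper_pair))
  expect_equal(nrow(find_discordant_anchors(sim$records, cfg)), 0L)
})

test_that("default-condition events reach the caller's support thresholds", {
  sc <- sim_scenario(seed = 35, contigs = c(chrA = 120000L),
                     events = data.frame(chrom = "chrA", type = "tel_right",
                                         junction = 60000L,
                                         junction2 = NA_integer_,
                                         microhomology_bp = 2L,
                                         microhomology2_bp = 0L))
  sim <- simulate_tumor_alignments(sc)
  expect_gte(sim$truth$n_discordant, 4L)
  expect_gte(sim$truth$n_split, 3L)
  # ground truth identifies the supporting reads
  expect_equal(lengths(sim$truth$discordant_ids), sim$truth$n_discordant)
  expect_equal(lengths(sim$truth$split_ids), sim$truth$n_split)
})

test_that("distal loss removes coverage beyond the junction", {
  sc <- sim_scenario(seed = 36, contigs = c(chrA = 100000L),
                     events = data.frame(chrom = "chrA", type = "tel_right",
                                         junction = 50000L,
                                         junction2 = NA_integer_,
                                         microhomology_bp = 0L,
                                         microhomology2_bp = 0L))
  sim <- simulate_tumor_alignments(sc)
  mapped <- sim$records[!is.na(sim$records$chrom), ]
  expect_true(all(mapped$pos < 50000L))
})

test_that("simulated cohort tables carry their generating parameters", {
  tab <- simulate_cohort_table(500, odds_ratio = 5, seed = 21)
  expect_equal(nrow(tab), 500L)
  expect_equal(attr(tab, "params")$odds_ratio, 5)
  expect_error(simulate_cohort_table(0), "positive")
  # strong effects at moderate n are detected with high power
  rej <- vapply(1:200, function(i) {
    d <- simulate_cohort_table(600, odds_ratio = 5, seed = 7000 + i)
    t <- table(factor(d$group, 0:1), factor(d$outcome, 0:1))
    fisher_exact_two_sided(t)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("repeat read sets are deterministic and respect zero fractions", {
  a <- simulate_repeat_readset(2000, 0.01, seed = 5)
  b <- simulate_repeat_readset(2000, 0.01, seed = 5)
  expect_identical(a, b)
  none <- simulate_repeat_readset(2000, 0, 0, 0, seed = 5)
  expect_equal(sum(is.na(none$chrom)), 0L)
})
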
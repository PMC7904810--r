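cfg <- neotel_config()

test_that("discordant anchors require mapq > 30, non-telomeric self, telomeric mate", {
  rec <- rbind(
    make_pair("good", "chr1", 1000L, 60L, BG100, TEL100),
    make_pair("mq30", "chr1", 2000L, 30L, BG100, TEL100),
    make_pair("mq31", "chr1", 3000L, 31L, BG100, TEL100),
    make_pair("bothtel", "chr1", 4000L, 60L, TEL100, TEL100),
    make_pair("nontelmate", "chr1", 5000L, 60L, BG100, BG100),
    make_pair("proper", "chr1", 6000L, 60L, BG100, TEL100, proper = TRUE),
    make_pair("dupanchor", "chr1", 7000L, 60L, BG100, TEL100,
              anchor_dup = TRUE))
  a <- find_discordant_anchors(rec, cfg)
  expect_setequal(a$read_id, c("good", "mq31"))
  # orphan mates are skipped silently
  orphan <- alignment_records("solo", "chr1", 10L, 60L, "+", "100M", BG100)
  expect_equal(nrow(find_discordant_anchors(orphan, cfg)), 0L)
})

test_that("candidate regions need 4 tumor anchors and a clean control", {
  anc <- function(pos, prefix = "a") data.frame(
    read_id = paste0(prefix, seq_along(pos)), chrom = "chr1", pos = pos,
    mapq = 60L, strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_regions(anc(c(100, 300, 500, 700)), NULL, cfg)), 1L)
  expect_equal(nrow(cluster_regions(anc(c(100, 300, 500)), NULL, cfg)), 0L)
  # one control anchor inside the padded span kills the region
  expect_equal(nrow(cluster_regions(anc(c(100, 300, 500, 700)),
                                    anc(400, "c"), cfg)), 0L)
  expect_equal(nrow(cluster_regions(anc(c(100, 300, 500, 700)),
                                    anc(5000, "c"), cfg)), 1L)
  # anchors separated by more than 1 kb split into clusters
  r <- cluster_regions(anc(c(1, 2, 3, 4, 5000, 5001, 5002, 5003)), NULL, cfg)
  expect_equal(nrow(r), 2L)
})

test_that("panel-of-normals exclusion counts distinct samples, not reads", {
  region <- data.frame(chrom = "chr1", start = 1000L, end = 1500L,
                       tumor_discordant = 6L, control_discordant = 0L,
                       pon_hit_samples = NA_integer_)
  hit <- data.frame(read_id = "x", chrom = "chr1", pos = 1200L, mapq = 60L,
                    strand = "+", stringsAsFactors = FALSE)
  miss <- data.frame(read_id = "x", chrom = "chr2", pos = 1200L, mapq = 60L,
                     strand = "+", stringsAsFactors = FALSE)
  pon15 <- c(rep(list(hit), 15), list(miss))
  expect_equal(nrow(filter_panel_of_normals(region, pon15, cfg)), 0L)
  pon14 <- c(rep(list(hit), 14), rep(list(miss), 2))
  kept <- filter_panel_of_normals(region, pon14, cfg)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$pon_hit_samples, 14L)
  # 30 anchors from a single sample still count as one sample
  hit30 <- hit[rep(1, 30), ]
  pon_single <- c(list(hit30), rep(list(miss), 15))
  expect_equal(nrow(filter_panel_of_normals(region, pon_single, cfg)), 1L)
  # an undersized panel warns and filters nothing
  expect_warning(out <- filter_panel_of_normals(region, rep(list(hit), 5),
                                                cfg), "inert")
  expect_equal(nrow(out), 1L)
})

split_read <- function(id, p, clip_seq, side = "right", mapped_len = 70L) {
  ref_part <- strrep("A", mapped_len)
  if (side == "right") {
    alignment_records(id, "chr1", p - mapped_len, 60L, "+",
                      paste0(mapped_len, "M", nchar(clip_seq), "S"),
                      paste0(ref_part, clip_seq))
  } else {
    alignment_records(id, "chr1", p, 60L, "+",
                      paste0(nchar(clip_seq), "S", mapped_len, "M"),
                      paste0(clip_seq, ref_part))
  }
}

test_that("junction refinement demands 3 exactly agreeing repeat-bearing clips", {
  region <- data.frame(chrom = "chr1", start = 9500L, end = 10500L,
                       tumor_discordant = 5L, control_discordant = 0L,
                       pon_hit_samples = NA_integer_)
  p <- 10000L
  tel_clip <- strrep("TTAGGG", 5)
  rec3 <- rbind(split_read("s1", p, tel_clip), split_read("s2", p, tel_clip),
                split_read("s3", p, tel_clip))
  locus <- refine_junction(region, rec3, cfg)
  expect_equal(locus$junction, p)
  expect_equal(locus$orientation, "tel_right")
  expect_equal(locus$n_split, 3L)
  expect_equal(locus$repeat_phase, 0L)
  # two agreeing reads are not enough
  expect_null(refine_junction(region, rec3[1:2, ], cfg))
  # three clips without a telomeric repeat do not qualify
  recx <- rbind(split_read("x1", p, strrep("ACGTA", 6)),
                split_read("x2", p, strrep("ACGTA", 6)),
                split_read("x3", p, strrep("ACGTA", 6)))
  expect_null(refine_junction(region, recx, cfg))
  # disagreeing positions do not stack up
  recd <- rbind(split_read("d1", p, tel_clip), split_read("d2", p + 5L, tel_clip),
                split_read("d3", p + 9L, tel_clip))
  expect_null(refine_junction(region, recd, cfg))
  # left clips with C-strand repeats give tel_left at the clip start
  cl <- strrep("CCCTAA", 5)
  recl <- rbind(split_read("l1", p, cl, "left"), split_read("l2", p, cl, "left"),
                split_read("l3", p, cl, "left"))
  locusl <- refine_junction(region, recl, cfg)
  expect_equal(locusl$orientation, "tel_left")
  expect_equal(locusl$junction, p)
  expect_equal(locusl$repeat_phase, 5L)
})

test_that("split-read phase voting recovers off-phase clips", {
  region <- data.frame(chrom = "chr1", start = 9500L, end = 10500L,
                       tumor_discordant = 4L, control_discordant = 0L,
                       pon_hit_samples = NA_integer_)
  p <- 10000L
  # tract begins mid-hexamer: AGGG then full repeats -> phase 2
  clip <- paste0("AGGG", strrep("TTAGGG", 4))
  rec <- rbind(split_read("p1", p, clip), split_read("p2", p, clip),
               split_read("p3", p, clip))
  expect_equal(refine_junction(region, rec, cfg)$repeat_phase, 2L)
})

test_that("microhomology scoring matches engineered flanks", {
  # spec-style worked example: flank ...AATTAG against a phase-4 tract
  ref <- list(chr1 = paste0(strrep("C", 10), "AATTAG"))
  locus <- data.frame(chrom = "chr1", junction = 16L,
                      orientation = "tel_right", repeat_phase = 4L)
  expect_equal(microhomology(locus, ref), 4L)
  # flank ending in a full expected hexamer scores 6
  ref6 <- list(chr1 = paste0(strrep("C", 10), "TTAGGG"))
  locus6 <- data.frame(chrom = "chr1", junction = 16L,
                       orientation = "tel_right", repeat_phase = 0L)
  expect_equal(microhomology(locus6, ref6), 6L)
  # no microhomology when the adjacent base differs
  ref0 <- list(chr1 = paste0(strrep("C", 16)))
  expect_equal(microhomology(locus6, ref0), 0L)
  # junction too close to the contig edge is unknown
  locus_edge <- data.frame(chrom = "chr1", junction = 3L,
                           orientation = "tel_right", repeat_phase = 0L)
  expect_true(is.na(microhomology(locus_edge, ref0)))
  # engineered genomes score exactly k for k in 0..6, both orientations
  for (k in 0:6) {
    for (type in c("tel_right", "tel_left")) {
      sc <- sim_scenario(seed = 400 + k, contigs = c(chrE = 5000L),
                         events = data.frame(chrom = "chrE", type = type,
                                             junction = 2500L,
                                             junction2 = NA_integer_,
                                             microhomology_bp = min(k, 6L),
                                             microhomology2_bp = 0L))
      g <- make_genome(sc)
      lc <- data.frame(chrom = "chrE", junction = 2500L, orientation = type,
                       repeat_phase = if (type == "tel_right") 0L else 5L)
      expect_equal(microhomology(lc, g$contigs), k,
                   info = paste(type, "k =", k))
    }
  }
})

test_that("two-sided pairing requires opposite orientation within 10 kb", {
  base <- data.frame(chrom = "chr1", n_split = 5L, n_discordant = 8L,
                     microhomology_bp = 0L, repeat_phase = 0L,
                     cn_class = "unknown", sidedness = "one_sided",
                     stringsAsFactors = FALSE)
  mk <- function(j, ori) cbind(base, junction = j, orientation = ori)
  near <- rbind(mk(100000L, "tel_right"), mk(105000L, "tel_left"))
  r <- pair_two_sided(near, cfg)
  expect_equal(nrow(r$events), 1L)
  expect_equal(r$events$gap_bp, 5000L)
  expect_true(all(r$loci$sidedness == "two_sided_member"))
  far <- rbind(mk(100000L, "tel_right"), mk(115000L, "tel_left"))
  rf <- pair_two_sided(far, cfg)
  expect_equal(nrow(rf$events), 0L)
  expect_true(all(rf$loci$sidedness == "one_sided"))
  same <- rbind(mk(100000L, "tel_right"), mk(105000L, "tel_right"))
  expect_equal(nrow(pair_two_sided(same, cfg)$events), 0L)
  # each locus joins at most one event; the nearest pair wins
  trio <- rbind(mk(100000L, "tel_right"), mk(103000L, "tel_left"),
                mk(104000L, "tel_right"))
  rt <- pair_two_sided(trio, cfg)
  expect_equal(nrow(rt$events), 1L)
  expect_equal(rt$events$gap_bp, 1000L)
})

test_that("insertion evidence needs a pair spanning both junctions", {
  event <- data.frame(chrom = "chr1", junction_a = 10000L,
                      junction_b = 15000L)
  spanning <- make_pair("sp", "chr1", 9800L, 60L, BG100, BG100,
                        mate_unmapped = FALSE)
  spanning$pos[2] <- 15200L; spanning$mate_pos[1] <- 15200L
  expect_true(insertion_evidence(event, spanning, cfg))
  inside <- make_pair("in", "chr1", 9800L, 60L, BG100, BG100,
                      mate_unmapped = FALSE)
  inside$pos[2] <- 12000L; inside$mate_pos[1] <- 12000L
  expect_false(insertion_evidence(event, inside, cfg))
  expect_false(insertion_evidence(event, spanning[0, ], cfg))
})

test_that("copy-number association compares the telomeric with the retained side", {
  seg_drop <- data.frame(chrom = "chr1", start = c(0L, 200000L),
                         end = c(200000L, 400000L), total_cn = c(2, 1),
                         minor_cn = c(1, 0))
  locus <- data.frame(chrom = "chr1", junction = 200000L,
                      orientation = "tel_right", repeat_phase = 0L)
  expect_equal(associate_copy_number(locus, seg_drop, NULL, cfg), "loss")
  # the same boundary seen from a tel_left junction is a gain
  locus_l <- locus; locus_l$orientation <- "tel_left"
  expect_equal(associate_copy_number(locus_l, seg_drop, NULL, cfg), "gain")
  # boundary outside the 50 kb tolerance: neutral
  locus_far <- locus; locus_far$junction <- 290000L
  expect_equal(associate_copy_number(locus_far, seg_drop, NULL, cfg),
               "neutral_no_SV")
  # flat profile with a nearby SV breakpoint
  seg_flat <- data.frame(chrom = "chr1", start = 0L, end = 400000L,
                         total_cn = 2, minor_cn = 1)
  sv <- data.frame(chrom = "chr1", pos = 204000L)
  expect_equal(associate_copy_number(locus, seg_flat, sv, cfg),
               "neutral_with_SV")
  expect_equal(associate_copy_number(locus, seg_flat, NULL, cfg),
               "neutral_no_SV")
  expect_equal(associate_copy_number(
    data.frame(chrom = "chrZ", junction = 1L, orientation = "tel_right",
               repeat_phase = 0L), seg_flat, NULL, cfg), "unknown")
})

test_that("hotspots merge junctions across samples within 1 Mb", {
  # six samples spanning 1.063 Mb, mirroring a recurrent 1q42.2-style cluster
  loci <- data.frame(
    sample_id = paste0("s", 1:6), chrom = "chr1",
    junction = c(230370000L, 230550000L, 230800000L, 231000000L,
                 231200000L, 231433000L))
  h <- call_hotspots(loci, cfg)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 230370000L)
  expect_equal(h$end, 231433000L)
  expect_equal(h$n_samples, 6L)
  # two samples fall below the recurrence threshold
  expect_equal(nrow(call_hotspots(loci[1:2, ], cfg)), 0L)
  # junctions 2 Mb apart form separate clusters (each below threshold here)
  spread <- data.frame(sample_id = paste0("s", 1:4), chrom = "chr2",
                       junction = c(1e6, 3.1e6, 5.2e6, 7.3e6))
  expect_equal(nrow(call_hotspots(spread, cfg)), 0L)
  # recurrence in one tight cluster plus a distant singleton
  mix <- rbind(loci[1:3, ],
               data.frame(sample_id = "s9", chrom = "chr1",
                          junction = 234000000L))
  hm <- call_hotspots(mix, cfg)
  expect_equal(nrow(hm), 1L)
  expect_equal(hm$n_samples, 3L)
})
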
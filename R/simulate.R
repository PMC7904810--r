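# Deterministic simulator for the ALT detection pipeline.
#
# Emits aligner-style records directly (soft clips, mates, mapping qualities
# set by construction) instead of running an external aligner: the caller
# consumes alignment semantics, not raw reads, and direct emission keeps the
# simulation desk-scale and fully deterministic.  Every stochastic artifact
# is accompanied by ground truth sufficient to compute expected support
# counts without re-simulation.

#' Define a simulation scenario
#'
#' A scenario bundles the study conditions emulated by the simulator:
#' contig sizes, sequencing parameters (paired-end, 100 bp reads, 350 bp
#' inserts, 30x coverage - typical tumor WGS), and the implanted
#' neo-telomere events.  Event types:
#' \describe{
#'   \item{tel_right}{terminal break at \code{junction}; the distal segment
#'     is lost and a telomeric tract is appended (G-strand repeats read
#'     left-to-right from the junction).}
#'   \item{tel_left}{mirror image: the proximal segment is lost, C-strand
#'     repeats end at \code{junction}.}
#'   \item{insertion}{the segment [junction, junction2) is replaced by a
#'     head-to-head telomeric tract, producing two opposite-orientation
#'     junctions \code{junction2 - junction} apart with fragments spanning
#'     the insert.}
#'   \item{fragment}{an isolated fragment [junction, junction2) healed by
#'     neo-telomeres on both sides (tel_left at \code{junction}, tel_right
#'     at \code{junction2}).}
#' }
#'
#' @param seed integer master seed (< 2^31 - 10^6); all randomness in the
#'   simulator derives from it.
#' @param contigs named integer vector of contig lengths.
#' @param events data.frame with columns chrom, type, junction, junction2
#'   (NA for one-sided types), microhomology_bp (engineered at the
#'   first/left junction, 0-6) and microhomology2_bp (second junction).
#' @param read_length,insert_mean,insert_sd,coverage sequencing parameters.
#' @param gc genome GC content.
#' @param error_rate uniform substitution rate applied to fully mapped
#'   reads; junction-spanning and telomeric reads are left error-free so
#'   junction positions stay exact in the ground truth.
#' @param tract_bp telomeric tract length (multiple of 6).
#' @param pure_bp junction-proximal tract bases kept as pure TTAGGG/CCCTAA
#'   (the remainder is a 90/10 mixture of the four repeat types).
#' @param telomeric_read_fraction spiked telomeric fraction for repeat read
#'   sets.
#' @param n_pon_samples,pon_coverage,control_coverage panel and control
#'   sequencing parameters.
#' @return list of class \code{"sim_scenario"}.
#' @export
sim_scenario <- function(seed = 1L,
                         contigs = c(chr1 = 340000L, chr2 = 330000L,
                                     chr3 = 330000L),
                         events = data.frame(
                           chrom = c("chr1", "chr2", "chr3"),
                           type = c("tel_right", "tel_left", "tel_right"),
                           junction = c(200000L, 150000L, 250000L),
                           junction2 = NA_integer_,
                           microhomology_bp = c(0L, 2L, 4L),
                           microhomology2_bp = 0L,
                           stringsAsFactors = FALSE),
                         read_length = 100L, insert_mean = 350,
                         insert_sd = 30, coverage = 30, gc = 0.5,
                         error_rate = 0.001, tract_bp = 1500L,
                         pure_bp = 210L, telomeric_read_fraction = 1e-4,
                         n_pon_samples = 16L, pon_coverage = 2,
                         control_coverage = NULL) {
  stopifnot(seed < 2^31 - 1e6, tract_bp %% 6 == 0)
  if (!is.null(events) && nrow(events)) {
    stopifnot(all(events$chrom %in% names(contigs)),
              all(events$microhomology_bp %in% 0:6),
              !anyDuplicated(events$chrom))
    stopifnot(all(events$junction >= 1000),
              all(events$junction <= contigs[events$chrom] - 1000))
  }
  structure(list(seed = as.integer(seed), contigs = contigs, events = events,
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage = coverage, gc = gc, error_rate = error_rate,
                 tract_bp = as.integer(tract_bp),
                 pure_bp = as.integer(pure_bp),
                 telomeric_read_fraction = telomeric_read_fraction,
                 n_pon_samples = as.integer(n_pon_samples),
                 pon_coverage = pon_coverage,
                 control_coverage = if (is.null(control_coverage)) coverage
                                    else control_coverage),
            class = "sim_scenario")
}

# random DNA of total length n*len split into n strings
random_dna <- function(n, len, gc = 0.5) {
  if (n == 0) return(character(0))
  bases <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  all <- paste(bases, collapse = "")
  substring(all, seq(1L, by = len, length.out = n),
            seq(len, by = len, length.out = n))
}

# G-strand tract: pure TTAGGG for the first pure_bp, 90/10 repeat-type
# mixture beyond.  Phase of the first base is 0.
tract_g <- function(total_bp, pure_bp, hexamers = neotel_config()$hexamers) {
  pure_bp <- min(pure_bp, total_bp)
  pure <- strrep("TTAGGG", ceiling(pure_bp / 6))
  rest_bp <- total_bp - nchar(pure)
  rest <- if (rest_bp > 0) {
    hx <- sample(hexamers, ceiling(rest_bp / 6), replace = TRUE,
                 prob = c(0.9, 0.1 / 3, 0.1 / 3, 0.1 / 3))
    paste(hx, collapse = "")
  } else ""
  substr(paste0(pure, rest), 1L, total_bp)
}

# C-strand tract ending in full CCCTAA hexamers at the junction side (the
# phase of the last base is 5).
tract_c <- function(total_bp, pure_bp, hexamers = neotel_config()$hexamers) {
  g <- tract_g(total_bp, pure_bp, hexamers)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
}

#' Build the reference genome of a scenario
#'
#' Random sequence at the scenario's GC content, with an engineered flank at
#' each event junction whose bases continue the telomeric repeat (in the
#' tract's phase) for exactly \code{microhomology_bp} bases into the retained
#' side, the next base differing.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @return list with \code{contigs} (named character vector) and the
#'   scenario.  Deterministic given the scenario seed.
#' @export
make_genome <- function(scenario) {
  set.seed(scenario$seed)
  contigs <- vapply(names(scenario$contigs), function(cc)
    random_dna(1L, scenario$contigs[[cc]], scenario$gc), character(1))
  ev <- scenario$events
  for (i in seq_len(NROW(ev))) {
    cc <- ev$chrom[i]
    contigs[[cc]] <- switch(ev$type[i],
      tel_right = engineer_flank(contigs[[cc]], ev$junction[i], "tel_right",
                                 ev$microhomology_bp[i]),
      tel_left = engineer_flank(contigs[[cc]], ev$junction[i], "tel_left",
                                ev$microhomology_bp[i]),
      insertion = engineer_flank(
        engineer_flank(contigs[[cc]], ev$junction[i], "tel_right",
                       ev$microhomology_bp[i]),
        ev$junction2[i], "tel_left", ev$microhomology2_bp[i]),
      fragment = engineer_flank(
        engineer_flank(contigs[[cc]], ev$junction[i], "tel_left",
                       ev$microhomology_bp[i]),
        ev$junction2[i], "tel_right", ev$microhomology2_bp[i]),
      stop("unknown event type: ", ev$type[i]))
  }
  list(contigs = contigs, scenario = scenario)
}

# write exactly m bases of repeat continuation into the retained flank.
# tel_right: tract starts at phase 0, expected bases leftwards of the
# junction are G,G,G,A,T,T,...; tel_left: tract ends at phase 5, expected
# bases rightwards are C,C,C,T,A,A,...
engineer_flank <- function(refseq, junction, orientation, m) {
  if (orientation == "tel_right") {
    hex <- c("T", "T", "A", "G", "G", "G")
    for (i in seq_len(m)) {
      expected <- hex[(((-i) %% 6)) + 1L]
      substr(refseq, junction - i + 1L, junction - i + 1L) <- expected
    }
    brk <- junction - m                        # 1-based position of breaker
    expected <- hex[(((-(m + 1L)) %% 6)) + 1L]
    if (brk >= 1L && substr(refseq, brk, brk) == expected)
      substr(refseq, brk, brk) <- setdiff(c("A", "C", "G", "T"), expected)[1]
  } else {
    hex <- c("C", "C", "C", "T", "A", "A")
    for (i in seq_len(m)) {
      expected <- hex[(((5L + i) %% 6)) + 1L]
      substr(refseq, junction + i, junction + i) <- expected
    }
    brk <- junction + m + 1L
    expected <- hex[(((5L + m + 1L) %% 6)) + 1L]
    if (brk <= nchar(refseq) && substr(refseq, brk, brk) == expected)
      substr(refseq, brk, brk) <- setdiff(c("A", "C", "G", "T"), expected)[1]
  }
  refseq
}

# derivative chromosome + segment map for one contig.  Segments are 1-based
# intervals of the derivative; ref_start is the 0-based reference coordinate
# of the segment start (NA for telomeric tracts).
build_derivative <- function(refseq, event, scenario) {
  L <- nchar(refseq); TT <- scenario$tract_bp; pb <- scenario$pure_bp
  if (is.null(event)) {
    return(list(seq = refseq,
                segments = data.frame(d_start = 1L, d_end = L, ref_start = 0L)))
  }
  j <- event$junction
  switch(event$type,
    tel_right = {
      tr <- tract_g(TT, pb)
      list(seq = paste0(substr(refseq, 1L, j), tr),
           segments = data.frame(d_start = c(1L, j + 1L),
                                 d_end = c(j, j + TT),
                                 ref_start = c(0L, NA)))
    },
    tel_left = {
      tr <- tract_c(TT, pb)
      list(seq = paste0(tr, substring(refseq, j + 1L)),
           segments = data.frame(d_start = c(1L, TT + 1L),
                                 d_end = c(TT, TT + (L - j)),
                                 ref_start = c(NA, j)))
    },
    insertion = {
      j2 <- event$junction2
      half <- TT / 2
      tr <- paste0(tract_g(half, half), tract_c(half, half))
      list(seq = paste0(substr(refseq, 1L, j), tr, substring(refseq, j2 + 1L)),
           segments = data.frame(d_start = c(1L, j + 1L, j + TT + 1L),
                                 d_end = c(j, j + TT, j + TT + (L - j2)),
                                 ref_start = c(0L, NA, j2)))
    },
    fragment = {
      j2 <- event$junction2
      trc <- tract_c(TT, pb); trg <- tract_g(TT, pb)
      list(seq = paste0(trc, substr(refseq, j + 1L, j2), trg),
           segments = data.frame(d_start = c(1L, TT + 1L, TT + (j2 - j) + 1L),
                                 d_end = c(TT, TT + (j2 - j),
                                           2L * TT + (j2 - j)),
                                 ref_start = c(NA, j, NA)))
    })
}

# classify read intervals [a, b] (1-based, derivative coords) against the
# segment map, vectorized.  Segments are contiguous from position 1 and all
# wider than a read, so a read overlaps at most two adjacent segments.
classify_read_intervals <- function(a, b, segments, min_anchor) {
  stopifnot(all(segments$d_end - segments$d_start + 1L > max(b - a + 1L, 0L)))
  ia <- findInterval(a, segments$d_start)
  ib <- findInterval(b, segments$d_start)
  ref_a <- segments$ref_start[ia]; ref_b <- segments$ref_start[ib]
  n <- length(a)
  mapped <- logical(n); pos <- rep(NA_integer_, n)
  cigar <- rep("*", n); junction <- rep(NA_integer_, n)
  rl <- b - a + 1L
  same <- ia == ib
  # fully inside one reference segment
  full <- same & !is.na(ref_a)
  mapped[full] <- TRUE
  pos[full] <- ref_a[full] + (a[full] - segments$d_start[ia[full]])
  cigar[full] <- paste0(rl[full], "M")
  # reference then tract: right-clipped if enough anchor
  rt <- !same & !is.na(ref_a) & is.na(ref_b)
  if (any(rt)) {
    mlen <- segments$d_end[ia[rt]] - a[rt] + 1L
    ok <- mlen >= min_anchor
    i <- which(rt)[ok]; m <- mlen[ok]
    mapped[i] <- TRUE
    pos[i] <- ref_a[i] + (a[i] - segments$d_start[ia[i]])
    cigar[i] <- paste0(m, "M", rl[i] - m, "S")
    junction[i] <- pos[i] + m
  }
  # tract then reference: left-clipped if enough anchor
  lt <- !same & is.na(ref_a) & !is.na(ref_b)
  if (any(lt)) {
    mlen <- b[lt] - segments$d_start[ib[lt]] + 1L
    ok <- mlen >= min_anchor
    i <- which(lt)[ok]; m <- mlen[ok]
    mapped[i] <- TRUE
    pos[i] <- ref_b[i]
    cigar[i] <- paste0(rl[i] - m, "S", m, "M")
    junction[i] <- pos[i]
  }
  data.frame(mapped = mapped, pos = as.integer(pos), cigar = cigar,
             junction = as.integer(junction))
}

#' Simulate tumor alignments with implanted neo-telomere junctions
#'
#' Draws paired-end fragments uniformly from each contig's derivative
#' chromosome.  Reads fully inside a telomeric tract are emitted as unmapped
#' telomeric records whose mates anchor uniquely (mapping quality 60);
#' junction-spanning reads become soft-clipped records clipped exactly at
#' the junction; everything else is an ordinary proper pair.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param genome output of \code{\link{make_genome}} (rebuilt when omitted).
#' @return list with \code{records} (alignment records) and \code{truth}:
#'   one row per implanted junction with its expected position, orientation,
#'   engineered microhomology, achieved discordant/split support and the
#'   supporting read ids (list columns).
#' @export
simulate_tumor_alignments <- function(scenario, genome = NULL) {
  if (is.null(genome)) genome <- make_genome(scenario)
  set.seed(scenario$seed + 1L)
  recs <- list(); truth <- list()
  for (cc in names(genome$contigs)) {
    event <- NULL
    if (!is.null(scenario$events) && NROW(scenario$events)) {
      i <- which(scenario$events$chrom == cc)
      if (length(i)) event <- scenario$events[i, ]
    }
    deriv <- build_derivative(genome$contigs[[cc]], event, scenario)
    sim <- emit_contig_reads(deriv, cc, scenario, scenario$coverage,
                             id_prefix = paste0("t_", cc))
    recs[[cc]] <- sim$records
    if (!is.null(event)) {
      truth[[cc]] <- junction_truth(event, sim, scenario)
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  if (!is.null(truth)) rownames(truth) <- NULL
  list(records = records, truth = truth)
}

# draw fragments and classify both reads of every pair against the map
emit_contig_reads <- function(deriv, chrom, scenario, coverage, id_prefix) {
  L <- nchar(deriv$seq); rl <- scenario$read_length
  n_pairs <- max(1L, round(L * coverage / (2 * rl)))
  isize <- pmax(2L * rl, pmin(
    as.integer(round(stats::rnorm(n_pairs, scenario$insert_mean,
                                  scenario$insert_sd))), L))
  s <- floor(stats::runif(n_pairs) * (L - isize + 1)) + 1L
  a1 <- s; b1 <- s + rl - 1L
  a2 <- s + isize - rl; b2 <- s + isize - 1L
  cl1 <- classify_read_intervals(a1, b1, deriv$segments, 20L)
  cl2 <- classify_read_intervals(a2, b2, deriv$segments, 20L)
  seq1 <- substring(deriv$seq, a1, b1)
  seq2fwd <- substring(deriv$seq, a2, b2)
  seq2rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq2fwd)))
  m1 <- cl1$mapped; m2 <- cl2$mapped
  pos1 <- cl1$pos; pos2 <- cl2$pos
  cg1 <- cl1$cigar; cg2 <- cl2$cigar
  clipped1 <- m1 & cg1 != paste0(rl, "M")
  clipped2 <- m2 & cg2 != paste0(rl, "M")
  # base errors on plain fully-mapped reads only: junction-spanning and
  # telomeric reads stay error-free so ground truth stays exact
  if (scenario$error_rate > 0) {
    seq1[m1 & !clipped1] <- mutate_seqs(seq1[m1 & !clipped1],
                                        scenario$error_rate)
    seq2fwd[m2 & !clipped2] <- mutate_seqs(seq2fwd[m2 & !clipped2],
                                           scenario$error_rate)
  }
  ids <- sprintf("%s_%06d", id_prefix, seq_len(n_pairs))
  proper <- m1 & m2
  r1 <- alignment_records(
    read_id = ids, chrom = ifelse(m1, chrom, NA), pos = pos1,
    mapq = ifelse(m1, 60L, 0L), strand = "+", cigar = cg1, seq = seq1,
    mate_chrom = ifelse(m2, chrom, NA), mate_pos = pos2,
    mate_strand = ifelse(m2, "-", NA), is_proper_pair = proper,
    validate = FALSE)
  r2 <- alignment_records(
    read_id = ids, chrom = ifelse(m2, chrom, NA), pos = pos2,
    mapq = ifelse(m2, 60L, 0L), strand = "-",
    cigar = cg2, seq = ifelse(m2, seq2fwd, seq2rc),
    mate_chrom = ifelse(m1, chrom, NA), mate_pos = pos1,
    mate_strand = ifelse(m1, "+", NA), is_proper_pair = proper,
    validate = FALSE)
  list(records = rbind(r1, r2), ids = ids, m1 = m1, m2 = m2,
       cl1 = cl1, cl2 = cl2, clipped1 = clipped1, clipped2 = clipped2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mutate_seqs <- function(seqs, rate) {
  if (!length(seqs)) return(seqs)
  nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(nerr > 0)) {
    pos <- sample.int(nchar(seqs[i]), nerr[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }
  seqs
}

# ground truth per implanted junction: achieved discordant/split support
junction_truth <- function(event, sim, scenario) {
  jx <- switch(event$type,
    tel_right = data.frame(junction = event$junction,
                           orientation = "tel_right",
                           microhomology_bp = event$microhomology_bp),
    tel_left = data.frame(junction = event$junction,
                          orientation = "tel_left",
                          microhomology_bp = event$microhomology_bp),
    insertion = data.frame(junction = c(event$junction, event$junction2),
                           orientation = c("tel_right", "tel_left"),
                           microhomology_bp = c(event$microhomology_bp,
                                                event$microhomology2_bp)),
    fragment = data.frame(junction = c(event$junction, event$junction2),
                          orientation = c("tel_left", "tel_right"),
                          microhomology_bp = c(event$microhomology_bp,
                                               event$microhomology2_bp)))
  jx$chrom <- event$chrom
  # discordant pairs: one end unmapped telomeric, the other plainly mapped
  disc1 <- which(!sim$m1 & sim$m2 & !sim$clipped2)   # read1 telomeric
  disc2 <- which(!sim$m2 & sim$m1 & !sim$clipped1)
  anchor_pos <- c(sim$cl2$pos[disc1], sim$cl1$pos[disc2])
  anchor_ids <- c(sim$ids[disc1], sim$ids[disc2])
  split_j1 <- sim$cl1$junction
  split_j2 <- sim$cl2$junction
  out <- lapply(seq_len(nrow(jx)), function(i) {
    j <- jx$junction[i]
    near <- abs(anchor_pos - j) <= 1000L
    sp1 <- which(!is.na(split_j1) & split_j1 == j)
    sp2 <- which(!is.na(split_j2) & split_j2 == j)
    data.frame(chrom = jx$chrom[i], junction = j,
               orientation = jx$orientation[i],
               microhomology_bp = jx$microhomology_bp[i],
               n_discordant = sum(near),
               n_split = length(sp1) + length(sp2),
               discordant_ids = I(list(anchor_ids[near])),
               split_ids = I(list(sim$ids[unique(c(sp1, sp2))])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate the matched control and a panel of normals
#'
#' Event-free read sets drawn from the unmodified reference.  In
#' recurrent-artifact mode a shared artifact (discordant telomeric-mate
#' pairs at a fixed region) is implanted into the first
#' \code{artifact_samples} panel samples, to exercise the panel filter.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param genome output of \code{\link{make_genome}}.
#' @param artifact optional list(chrom, pos, n_pairs) describing the shared
#'   artifact.
#' @param artifact_samples number of panel samples carrying the artifact.
#' @return list(control = records, pon = list of record sets).
#' @export
simulate_control_and_pon <- function(scenario, genome = NULL,
                                     artifact = NULL, artifact_samples = 0L) {
  if (is.null(genome)) genome <- make_genome(scenario)
  set.seed(scenario$seed + 2L)
  plain <- function(coverage, prefix) {
    recs <- lapply(names(genome$contigs), function(cc) {
      deriv <- build_derivative(genome$contigs[[cc]], NULL, scenario)
      emit_contig_reads(deriv, cc, scenario, coverage,
                        id_prefix = paste0(prefix, "_", cc))$records
    })
    out <- do.call(rbind, recs); rownames(out) <- NULL; out
  }
  control <- plain(scenario$control_coverage, "c")
  pon <- vector("list", scenario$n_pon_samples)
  for (k in seq_len(scenario$n_pon_samples)) {
    set.seed(scenario$seed + 100L + k)
    pon[[k]] <- plain(scenario$pon_coverage, sprintf("p%02d", k))
    if (!is.null(artifact) && k <= artifact_samples) {
      pon[[k]] <- rbind(pon[[k]],
        simulate_artifact_pairs(artifact$chrom, artifact$pos,
                                artifact$n_pairs %||% 6L,
                                sprintf("art_p%02d", k), scenario))
    }
  }
  list(control = control, pon = pon)
}

#' Implant recurrent-artifact discordant pairs
#'
#' Emits \code{n_pairs} read pairs whose mapped end (mapping quality 60)
#' anchors near \code{pos} and whose mate is an unmapped pure-telomeric
#' read - the signature of a recurrent alignment artifact shared across
#' unrelated samples.
#'
#' @param chrom,pos artifact anchor location (0-based).
#' @param n_pairs number of pairs.
#' @param id_prefix read id prefix.
#' @param scenario a \code{\link{sim_scenario}} (read length; randomness
#'   uses the current RNG state).
#' @return Alignment records (2 rows per pair).
#' @export
simulate_artifact_pairs <- function(chrom, pos, n_pairs, id_prefix,
                                    scenario) {
  rl <- scenario$read_length
  offs <- sample.int(300L, n_pairs, replace = TRUE) - 1L
  ids <- sprintf("%s_%03d", id_prefix, seq_len(n_pairs))
  anchor <- alignment_records(
    read_id = ids, chrom = chrom, pos = pos + offs, mapq = 60L, strand = "+",
    cigar = paste0(rl, "M"), seq = random_dna(n_pairs, rl),
    is_proper_pair = FALSE, validate = FALSE)
  mate <- alignment_records(
    read_id = ids, seq = rep(substr(strrep("TTAGGG", ceiling(rl / 6) + 1),
                                    1, rl), n_pairs),
    mate_chrom = chrom, mate_pos = pos + offs, mate_strand = "+",
    is_proper_pair = FALSE, validate = FALSE)
  rbind(anchor, mate)
}

#' Simulate a repeat-enriched read set (ChIP / RNA)
#'
#' Telomeric reads are concatenated repeat hexamers (qualifying under both
#' the fixed-count and the per-100-bp rules); satellite reads contain the
#' canonical motif; the remainder is random sequence at 50\% GC.  Telomeric
#' reads are emitted unmapped; background and satellite reads are mapped, so
#' mapped-read totals behave like a real library.
#'
#' @param n_reads total reads.
#' @param telomeric_fraction,satII_fraction,satIII_fraction expected
#'   fractions (sum at most 1).
#' @param read_length read length.
#' @param seed integer seed.
#' @param cfg a \code{\link{neotel_config}}.
#' @return Alignment records.
#' @export
simulate_repeat_readset <- function(n_reads, telomeric_fraction,
                                    satII_fraction = 0, satIII_fraction = 0,
                                    read_length = 100L, seed = 1L,
                                    cfg = neotel_config()) {
  stopifnot(telomeric_fraction + satII_fraction + satIII_fraction <= 1)
  set.seed(seed)
  comp <- sample(c("tel", "satII", "satIII", "bg"), n_reads, replace = TRUE,
                 prob = c(telomeric_fraction, satII_fraction, satIII_fraction,
                          1 - telomeric_fraction - satII_fraction -
                            satIII_fraction))
  seqs <- random_dna(n_reads, read_length)
  tel_i <- which(comp == "tel")
  if (length(tel_i)) {
    nh <- ceiling(read_length / 6)
    seqs[tel_i] <- vapply(tel_i, function(i)
      substr(paste(sample(cfg$hexamers, nh + 1, replace = TRUE,
                          prob = c(0.9, 0.1 / 3, 0.1 / 3, 0.1 / 3)),
                   collapse = ""), 1, read_length), character(1))
  }
  for (cls in c("satII", "satIII")) {
    ci <- which(comp == cls)
    if (!length(ci)) next
    motif <- if (cls == "satII") cfg$satII_canonical else cfg$satIII_canonical
    off <- sample.int(read_length - nchar(motif) + 1L, length(ci),
                      replace = TRUE)
    for (k in seq_along(ci)) {
      substr(seqs[ci[k]], off[k], off[k] + nchar(motif) - 1L) <- motif
    }
  }
  mapped <- comp != "tel"
  alignment_records(
    read_id = sprintf("rr_%07d", seq_len(n_reads)),
    chrom = ifelse(mapped, "chrBG", NA),
    pos = ifelse(mapped, seq_len(n_reads) * read_length, NA),
    mapq = ifelse(mapped, 60L, 0L), strand = "+",
    cigar = ifelse(mapped, paste0(read_length, "M"), "*"), seq = seqs,
    validate = FALSE)
}

#' Simulate a cohort table with a configurable group/outcome association
#'
#' Per-sample binary group membership and outcome drawn under a logistic
#' model: \code{logit P(outcome) = logit(base_rate) + log(odds_ratio) *
#' group}.  The generating parameters are attached as attributes.
#'
#' @param n samples (> 0).
#' @param group_fraction expected fraction in group 1.
#' @param base_rate outcome probability in group 0.
#' @param odds_ratio group odds ratio (1 = no association).
#' @param seed integer seed.
#' @return data.frame(sample_id, group, outcome) with attribute
#'   \code{params}.
#' @export
simulate_cohort_table <- function(n, group_fraction = 0.5, base_rate = 0.5,
                                  odds_ratio = 1, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  g <- stats::rbinom(n, 1L, group_fraction)
  p <- stats::plogis(stats::qlogis(base_rate) + log(odds_ratio) * g)
  y <- stats::rbinom(n, 1L, p)
  out <- data.frame(sample_id = sprintf("s%04d", seq_len(n)), group = g,
                    outcome = y, stringsAsFactors = FALSE)
  attr(out, "params") <- list(n = n, group_fraction = group_fraction,
                              base_rate = base_rate, odds_ratio = odds_ratio,
                              seed = seed)
  out
}
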
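# Telomeric repeat locus (neo-telomere junction) caller.
#
# Detection proceeds in stages: discordant telomeric-mate anchors -> 1 kb
# candidate regions (tumor-only) -> panel-of-normals exclusion -> split-read
# junction refinement -> microhomology scoring -> two-sided pairing ->
# copy-number association.  All positions are 0-based; a junction is the
# boundary after the last reference-matching base.

# index of each record's mate row (NA when the mate record is absent)
mate_index <- function(read_id) {
  n <- length(read_id)
  idx <- rep(NA_integer_, n)
  if (n < 2) return(idx)
  o <- order(read_id)
  so <- read_id[o]
  i <- which(so[-n] == so[-1])
  idx[o[i]] <- o[i + 1L]
  idx[o[i + 1L]] <- o[i]
  idx
}

#' Find discordant telomeric-mate anchors
#'
#' An anchor is a non-telomeric read uniquely mapped to a chromosome (mapping
#' quality above \code{cfg$anchor_min_mapq}, default > 30) whose mate is a
#' telomeric read under the fixed-count rule.  Proper pairs and duplicates
#' are excluded; orphan mates (no partner record) are skipped.
#'
#' @param rec alignment records of one sample.
#' @param cfg a \code{\link{neotel_config}}.
#' @return data.frame: read_id, chrom, pos (0-based), mapq, strand.
#' @export
find_discordant_anchors <- function(rec, cfg = neotel_config()) {
  empty <- data.frame(read_id = character(), chrom = character(),
                      pos = integer(), mapq = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (nrow(rec) == 0) return(empty)
  mi <- mate_index(rec$read_id)
  cand <- which(!is.na(rec$chrom) & rec$mapq > cfg$anchor_min_mapq &
                  !rec$is_proper_pair & !rec$is_duplicate & !is.na(mi))
  if (!length(cand)) return(empty)
  need <- unique(c(cand, mi[cand]))
  tel <- logical(nrow(rec))
  tel[need] <- is_telomeric_fixed(rec$seq[need], cfg$wgs_min_hexamers,
                                  cfg$hexamers)
  keep <- cand[!tel[cand] & tel[mi[cand]] & !rec$is_duplicate[mi[cand]]]
  if (!length(keep)) return(empty)
  out <- data.frame(read_id = rec$read_id[keep], chrom = rec$chrom[keep],
                    pos = rec$pos[keep], mapq = rec$mapq[keep],
                    strand = rec$strand[keep], stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Cluster discordant anchors into candidate regions
#'
#' Single-linkage clustering of tumor anchors with inter-anchor gap at most
#' \code{cfg$region_size_bp} (1 kb), trimmed so the region span does not
#' exceed that size (for over-long clusters the densest window is kept).
#' Regions are emitted when they contain at least \code{cfg$min_discordant}
#' tumor anchors (4) and at most \code{cfg$max_control_discordant} (0)
#' matched-control anchors inside the region padded by one region size.
#'
#' @param anchors tumor anchors from \code{\link{find_discordant_anchors}}.
#' @param control_anchors matched-control anchors (may be empty / NULL).
#' @param cfg a \code{\link{neotel_config}}.
#' @return data.frame: chrom, start, end (anchor span, 0-based),
#'   tumor_discordant, control_discordant, pon_hit_samples (NA until the
#'   panel filter runs).
#' @export
cluster_regions <- function(anchors, control_anchors = NULL,
                            cfg = neotel_config()) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      tumor_discordant = integer(),
                      control_discordant = integer(),
                      pon_hit_samples = integer(), stringsAsFactors = FALSE)
  if (is.null(anchors) || nrow(anchors) == 0) return(empty)
  size <- cfg$region_size_bp
  out <- list()
  for (cc in unique(anchors$chrom)) {
    pos <- sort(anchors$pos[anchors$chrom == cc])
    grp <- cumsum(c(1L, diff(pos) > size))
    for (g in split(pos, grp)) {
      if (max(g) - min(g) <= size) {
        win <- c(min(g), max(g)); cnt <- length(g)
      } else {
        # densest window of one region size within an over-long cluster
        counts <- vapply(g, function(s) sum(g >= s & g <= s + size),
                         integer(1))
        s <- g[which.max(counts)]
        inw <- g[g >= s & g <= s + size]
        win <- c(min(inw), max(inw)); cnt <- length(inw)
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start = win[1], end = win[2], tumor_discordant = cnt,
        stringsAsFactors = FALSE)
    }
  }
  reg <- do.call(rbind, out)
  reg$control_discordant <- 0L
  if (!is.null(control_anchors) && nrow(control_anchors)) {
    reg$control_discordant <- vapply(seq_len(nrow(reg)), function(i) {
      sum(control_anchors$chrom == reg$chrom[i] &
            control_anchors$pos >= reg$start[i] - size &
            control_anchors$pos <= reg$end[i] + size)
    }, integer(1))
  }
  reg$pon_hit_samples <- NA_integer_
  reg <- reg[reg$tumor_discordant >= cfg$min_discordant &
               reg$control_discordant <= cfg$max_control_discordant, ,
             drop = FALSE]
  rownames(reg) <- NULL
  reg
}

#' Panel-of-normals region exclusion
#'
#' A region is excluded when at least \code{cfg$pon_min_samples} (15)
#' \emph{distinct} panel samples have one or more discordant anchors inside
#' the region padded by one region size.  Counting is per sample, not per
#' read.  With a panel smaller than the threshold the filter warns and
#' becomes inert (counts are still recorded).
#'
#' @param regions candidate regions from \code{\link{cluster_regions}}.
#' @param pon_anchors list (one element per panel sample) of anchor
#'   data.frames.
#' @param cfg a \code{\link{neotel_config}}.
#' @return \code{regions} with \code{pon_hit_samples} filled in and excluded
#'   rows dropped.
#' @export
filter_panel_of_normals <- function(regions, pon_anchors,
                                    cfg = neotel_config()) {
  if (nrow(regions) == 0) return(regions)
  pad <- cfg$region_size_bp
  regions$pon_hit_samples <- vapply(seq_len(nrow(regions)), function(i) {
    sum(vapply(pon_anchors, function(a) {
      !is.null(a) && nrow(a) > 0 &&
        any(a$chrom == regions$chrom[i] &
              a$pos >= regions$start[i] - pad &
              a$pos <= regions$end[i] + pad)
    }, logical(1)))
  }, integer(1))
  if (length(pon_anchors) < cfg$pon_min_samples) {
    warning("panel of normals has fewer than ", cfg$pon_min_samples,
            " samples; the panel filter is inert")
    return(regions)
  }
  regions[regions$pon_hit_samples < cfg$pon_min_samples, , drop = FALSE]
}

#' Refine a candidate region to an exact junction with split reads
#'
#' Candidate split reads are soft-clipped alignments in the (padded) region
#' whose clipped segment contains at least one TTAGGG (right clip: telomere
#' downstream, orientation \code{tel_right}) or CCCTAA (left clip:
#' \code{tel_left}).  The junction is the clip boundary supported by at least
#' \code{cfg$min_split_reads} (3) split reads agreeing exactly
#' (\code{cfg$junction_tol_bp} allows positional slack for noisy data).  The
#' repeat phase - the offset of the first clipped base within the hexamer -
#' is taken by majority vote of the supporting reads.
#'
#' @param region one row of the candidate-region table.
#' @param rec tumor alignment records.
#' @param cfg a \code{\link{neotel_config}}.
#' @return One-row locus data.frame, or NULL when no junction reaches the
#'   split-read threshold.
#' @export
refine_junction <- function(region, rec, cfg = neotel_config()) {
  pad <- cfg$region_size_bp
  # coarse positional prefilter (reads are shorter than one region size)
  # before the exact CIGAR-span overlap test
  mapped <- which(!is.na(rec$chrom) & !rec$is_duplicate &
                    rec$chrom == region$chrom &
                    rec$pos < region$end + pad &
                    rec$pos > region$start - 2L * pad)
  if (!length(mapped)) return(NULL)
  span <- cigar_ref_span(rec$cigar[mapped])
  inreg <- rec$pos[mapped] < region$end + pad &
    rec$pos[mapped] + span > region$start - pad
  mapped <- mapped[inreg]; span <- span[inreg]
  if (!length(mapped)) return(NULL)
  clips <- cigar_clips(rec$cigar[mapped])
  seqs <- rec$seq[mapped]
  cand <- list()
  r <- which(clips$right >= 6L)
  if (length(r)) {
    clip_seq <- substring(seqs[r], nchar(seqs[r]) - clips$right[r] + 1L)
    ok <- grepl("TTAGGG", clip_seq, fixed = TRUE)
    if (any(ok))
      cand$right <- data.frame(
        junction = rec$pos[mapped[r[ok]]] + span[r[ok]],
        orientation = "tel_right", clip = clip_seq[ok],
        stringsAsFactors = FALSE)
  }
  l <- which(clips$left >= 6L)
  if (length(l)) {
    clip_seq <- substring(seqs[l], 1L, clips$left[l])
    ok <- grepl("CCCTAA", clip_seq, fixed = TRUE)
    if (any(ok))
      cand$left <- data.frame(
        junction = rec$pos[mapped[l[ok]]],
        orientation = "tel_left", clip = clip_seq[ok],
        stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) return(NULL)
  # group identical junction positions per orientation (optionally with slack)
  best <- NULL
  for (ori in unique(cand$orientation)) {
    d <- cand[cand$orientation == ori, , drop = FALSE]
    d <- d[order(d$junction), , drop = FALSE]
    grp <- cumsum(c(1L, diff(d$junction) > cfg$junction_tol_bp))
    for (g in unique(grp)) {
      dd <- d[grp == g, , drop = FALSE]
      jx <- as.integer(names(which.max(table(dd$junction))))
      support <- if (cfg$junction_tol_bp > 0) nrow(dd)
                 else sum(dd$junction == jx)
      if (is.null(best) || support > best$support ||
          (support == best$support && jx < best$junction)) {
        best <- list(junction = jx, orientation = ori, support = support,
                     clips = dd$clip[dd$junction == jx])
      }
    }
  }
  if (best$support < cfg$min_split_reads) return(NULL)
  phase <- clip_repeat_phase(best$clips, best$orientation)
  data.frame(chrom = region$chrom, junction = best$junction,
             orientation = best$orientation, n_split = best$support,
             n_discordant = region$tumor_discordant,
             microhomology_bp = NA_integer_, repeat_phase = phase,
             cn_class = "unknown", sidedness = "one_sided",
             stringsAsFactors = FALSE)
}

# phase of the first clipped base within the repeat hexamer, majority-voted.
# tel_right clips read TTAGGG-type left to right; tel_left clips end in
# CCCTAA-type repeats adjacent to the junction.
clip_repeat_phase <- function(clips, orientation) {
  ph <- vapply(clips, function(cl) {
    if (orientation == "tel_right") {
      i0 <- regexpr("TTAGGG", cl, fixed = TRUE)[1] - 1L
      if (i0 < 0) return(NA_integer_)
      as.integer((6L - (i0 %% 6L)) %% 6L)
    } else {
      m <- gregexpr("CCCTAA", cl, fixed = TRUE)[[1]]
      if (m[1] == -1L) return(NA_integer_)
      last_end <- m[length(m)] + 5L           # 1-based end of last full match
      tail_len <- nchar(cl) - last_end
      as.integer((5L + tail_len) %% 6L)
    }
  }, integer(1), USE.NAMES = FALSE)
  ph <- ph[!is.na(ph)]
  if (!length(ph)) return(0L)
  as.integer(names(which.max(table(ph))))
}

#' Microhomology between the retained flank and the telomeric repeat
#'
#' Extends the telomeric repeat backwards across the junction in its observed
#' phase and orientation and counts the maximal run of reference bases on the
#' retained (non-telomeric) side, immediately adjacent to the junction, that
#' equal the extended repeat bases.  Junctions within 6 bp of a contig edge
#' are unknown (NA).
#'
#' @param locus one-row locus data.frame (needs chrom, junction, orientation,
#'   repeat_phase).
#' @param reference named character vector (or Biostrings DNAStringSet) of
#'   contig sequences covering the junction.
#' @param max_bp maximum flank inspected.
#' @return Integer microhomology length in bp, or NA.
#' @export
microhomology <- function(locus, reference, max_bp = 100L) {
  if (!is.character(reference)) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  refseq <- reference[[locus$chrom]]
  if (is.null(refseq)) stop("reference lacks contig ", locus$chrom)
  L <- nchar(refseq)
  j <- locus$junction; p <- locus$repeat_phase
  if (locus$orientation == "tel_right") {
    if (j < 6L) return(NA_integer_)
    hex <- c("T", "T", "A", "G", "G", "G")
    k <- 0L
    while (k < max_bp && j - k - 1L >= 0L) {
      expected <- hex[((p - k - 1L) %% 6L) + 1L]
      if (substr(refseq, j - k, j - k) != expected) break
      k <- k + 1L
    }
  } else {
    if (j > L - 6L) return(NA_integer_)
    hex <- c("C", "C", "C", "T", "A", "A")
    k <- 0L
    while (k < max_bp && j + k < L) {
      expected <- hex[((p + k + 1L) %% 6L) + 1L]
      if (substr(refseq, j + k + 1L, j + k + 1L) != expected) break
      k <- k + 1L
    }
  }
  k
}

#' Pair nearby opposite-orientation loci into two-sided events
#'
#' Greedy nearest pairing of opposite-orientation loci on the same chromosome
#' with gap at most \code{cfg$two_sided_window_bp} (10 kb); each locus joins
#' at most one event, and members are relabelled \code{two_sided_member}.
#'
#' @param loci locus data.frame.
#' @param cfg a \code{\link{neotel_config}}.
#' @return list(events = data.frame of events, loci = relabelled loci).
#' @export
pair_two_sided <- function(loci, cfg = neotel_config()) {
  events <- data.frame(chrom = character(), locus_a = integer(),
                       locus_b = integer(), junction_a = integer(),
                       junction_b = integer(), gap_bp = integer(),
                       true_insertion_evidence = logical(),
                       stringsAsFactors = FALSE)
  if (is.null(loci) || nrow(loci) < 2) {
    return(list(events = events, loci = loci))
  }
  loci$sidedness <- "one_sided"
  pairs <- list()
  for (cc in unique(loci$chrom)) {
    idx <- which(loci$chrom == cc)
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      if (loci$orientation[i] == loci$orientation[j]) next
      gap <- abs(loci$junction[j] - loci$junction[i])
      if (gap > cfg$two_sided_window_bp) next
      pairs[[length(pairs) + 1L]] <- c(i, j, gap)
    }
  }
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, 3]), , drop = FALSE]
    used <- logical(nrow(loci))
    for (k in seq_len(nrow(pm))) {
      i <- pm[k, 1]; j <- pm[k, 2]
      if (used[i] || used[j]) next
      used[i] <- used[j] <- TRUE
      a <- if (loci$junction[i] <= loci$junction[j]) i else j
      b <- if (a == i) j else i
      loci$sidedness[c(i, j)] <- "two_sided_member"
      events <- rbind(events, data.frame(
        chrom = loci$chrom[a], locus_a = a, locus_b = b,
        junction_a = loci$junction[a], junction_b = loci$junction[b],
        gap_bp = loci$junction[b] - loci$junction[a],
        true_insertion_evidence = NA, stringsAsFactors = FALSE))
    }
  }
  list(events = events, loci = loci)
}

#' Read-pair evidence for a true telomere insertion
#'
#' TRUE when at least one read pair has one end anchored (mapped, mapping
#' quality above the anchor threshold) entirely left of the event's left
#' junction and the other end anchored at or right of the right junction -
#' i.e. the fragment spans the inserted telomeric tract.
#'
#' @param event one row of the two-sided event table.
#' @param rec tumor alignment records.
#' @param cfg a \code{\link{neotel_config}}.
#' @return Logical.
#' @export
insertion_evidence <- function(event, rec, cfg = neotel_config()) {
  if (nrow(rec) == 0) return(FALSE)
  mi <- mate_index(rec$read_id)
  mapped <- !is.na(rec$chrom) & rec$chrom == event$chrom &
    rec$mapq > cfg$anchor_min_mapq & !rec$is_duplicate
  # only reads close to the left junction can belong to a spanning pair
  near <- mapped & rec$pos > event$junction_a - 5000L &
    rec$pos <= event$junction_a
  span <- integer(nrow(rec))
  span[near] <- cigar_ref_span(rec$cigar[near])
  left <- which(near & (rec$pos + span) <= event$junction_a & !is.na(mi))
  if (!length(left)) return(FALSE)
  m <- mi[left]
  any(mapped[m] & rec$pos[m] >= event$junction_b)
}

#' Copy-number context of a junction
#'
#' Finds the nearest copy-number segment boundary within
#' \code{cfg$cn_boundary_tol_bp} (50 kb) of the junction and compares the
#' total copy number of the segment on the telomeric side with the retained
#' side: lower is a \code{loss}, higher a \code{gain}, equal (or no boundary
#' in range) is copy-number neutral.  Neutral loci with a structural-variant
#' breakpoint within the two-sided window are \code{neutral_with_SV},
#' otherwise \code{neutral_no_SV}.  Junctions on chromosomes without segment
#' coverage are \code{unknown}.
#'
#' @param locus one-row locus data.frame.
#' @param segments copy-number segment table (see \code{\link{read_segments}}).
#' @param sv_breakpoints optional data.frame (chrom, pos) of SV breakpoints.
#' @param cfg a \code{\link{neotel_config}}.
#' @return One of loss, gain, neutral_with_SV, neutral_no_SV, unknown.
#' @export
associate_copy_number <- function(locus, segments, sv_breakpoints = NULL,
                                  cfg = neotel_config()) {
  seg <- segments[segments$chrom == locus$chrom, , drop = FALSE]
  if (nrow(seg) == 0) return("unknown")
  seg <- seg[order(seg$start), , drop = FALSE]
  neutral_class <- function() {
    if (!is.null(sv_breakpoints) && nrow(sv_breakpoints)) {
      near <- sv_breakpoints$chrom == locus$chrom &
        abs(sv_breakpoints$pos - locus$junction) <= cfg$two_sided_window_bp
      if (any(near)) return("neutral_with_SV")
    }
    "neutral_no_SV"
  }
  if (nrow(seg) < 2) return(neutral_class())
  boundaries <- seg$start[-1]                     # internal junction points
  d <- abs(boundaries - locus$junction)
  if (min(d) > cfg$cn_boundary_tol_bp) return(neutral_class())
  b <- which.min(d)
  cn_left <- seg$total_cn[b]; cn_right <- seg$total_cn[b + 1L]
  tel_cn <- if (locus$orientation == "tel_right") cn_right else cn_left
  ret_cn <- if (locus$orientation == "tel_right") cn_left else cn_right
  if (tel_cn < ret_cn) return("loss")
  if (tel_cn > ret_cn) return("gain")
  neutral_class()
}

#' Recurrent locus hotspots across a cohort
#'
#' Single-linkage merging of junction positions across samples with gap at
#' most \code{cfg$hotspot_merge_bp} (1 Mb); clusters recurrent in at least
#' \code{cfg$hotspot_min_samples} (3) distinct samples are reported with
#' their junction span.
#'
#' @param cohort_loci data.frame with columns sample_id, chrom, junction.
#' @param cfg a \code{\link{neotel_config}}.
#' @return data.frame: chrom, start, end, n_samples, n_loci, sample_ids.
#' @export
call_hotspots <- function(cohort_loci, cfg = neotel_config()) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    n_samples = integer(), n_loci = integer(),
                    sample_ids = character(), stringsAsFactors = FALSE)
  if (is.null(cohort_loci) || nrow(cohort_loci) == 0) return(out)
  for (cc in unique(cohort_loci$chrom)) {
    d <- cohort_loci[cohort_loci$chrom == cc, , drop = FALSE]
    d <- d[order(d$junction), , drop = FALSE]
    grp <- cumsum(c(1L, diff(d$junction) > cfg$hotspot_merge_bp))
    for (g in unique(grp)) {
      dd <- d[grp == g, , drop = FALSE]
      samples <- unique(dd$sample_id)
      if (length(samples) < cfg$hotspot_min_samples) next
      out <- rbind(out, data.frame(
        chrom = cc, start = min(dd$junction), end = max(dd$junction),
        n_samples = length(samples), n_loci = nrow(dd),
        sample_ids = paste(sort(samples), collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Call telomeric repeat loci for one tumor
#'
#' Runs the full caller: discordant anchor extraction in tumor and matched
#' control, candidate-region clustering, panel-of-normals exclusion,
#' split-read junction refinement, microhomology scoring (when a reference
#' is given), two-sided pairing with insertion-evidence testing, and
#' copy-number association (when segments are given).
#'
#' @param tumor tumor alignment records.
#' @param control matched-control alignment records (NULL: no control
#'   filtering).
#' @param pon list of panel-of-normals alignment record sets (or anchor
#'   data.frames).
#' @param reference named character vector of contig sequences (optional).
#' @param segments copy-number segment table (optional).
#' @param sv_breakpoints optional data.frame (chrom, pos).
#' @param sample_id sample label.
#' @param cfg a \code{\link{neotel_config}}.
#' @return An object of class \code{"repeat_locus_calls"}: list with
#'   \code{loci}, \code{events}, \code{regions} (audit trail of candidate
#'   regions), \code{unresolved} (regions without an exact junction),
#'   \code{sample_id} and \code{config}.
#' @export
call_repeat_loci <- function(tumor, control = NULL, pon = list(),
                             reference = NULL, segments = NULL,
                             sv_breakpoints = NULL, sample_id = "tumor",
                             cfg = neotel_config()) {
  anchors <- find_discordant_anchors(tumor, cfg)
  control_anchors <- if (!is.null(control)) {
    if (is.data.frame(control) && "seq" %in% names(control))
      find_discordant_anchors(control, cfg)
    else control
  }
  regions <- cluster_regions(anchors, control_anchors, cfg)
  if (length(pon)) {
    pon_anchors <- lapply(pon, function(p) {
      if (is.data.frame(p) && "seq" %in% names(p))
        find_discordant_anchors(p, cfg)
      else p
    })
    regions <- filter_panel_of_normals(regions, pon_anchors, cfg)
  }
  loci <- list(); unresolved <- list()
  for (i in seq_len(nrow(regions))) {
    lc <- refine_junction(regions[i, ], tumor, cfg)
    if (is.null(lc)) unresolved[[length(unresolved) + 1L]] <- regions[i, ]
    else loci[[length(loci) + 1L]] <- lc
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(chrom = character(), junction = integer(),
               orientation = character(), n_split = integer(),
               n_discordant = integer(), microhomology_bp = integer(),
               repeat_phase = integer(), cn_class = character(),
               sidedness = character(), stringsAsFactors = FALSE)
  if (!is.null(reference) && nrow(loci)) {
    loci$microhomology_bp <- vapply(seq_len(nrow(loci)), function(i)
      as.integer(microhomology(loci[i, ], reference)), integer(1))
  }
  ts <- pair_two_sided(loci, cfg)
  loci <- ts$loci; events <- ts$events
  if (nrow(events)) {
    events$true_insertion_evidence <- vapply(seq_len(nrow(events)),
      function(i) insertion_evidence(events[i, ], tumor, cfg), logical(1))
  }
  if (!is.null(segments) && nrow(loci)) {
    loci$cn_class <- vapply(seq_len(nrow(loci)), function(i)
      associate_copy_number(loci[i, ], segments, sv_breakpoints, cfg),
      character(1))
  }
  rownames(loci) <- NULL
  structure(list(loci = loci, events = events, regions = regions,
                 unresolved = if (length(unresolved))
                   do.call(rbind, unresolved) else NULL,
                 n_anchors = nrow(anchors), sample_id = sample_id,
                 config = cfg),
            class = "repeat_locus_calls")
}

#' @export
print.repeat_locus_calls <- function(x, ...) {
  cat("Telomeric repeat locus calls for sample '", x$sample_id, "'\n",
      sep = "")
  cat("  discordant anchors:", x$n_anchors,
      "| candidate regions:", nrow(x$regions),
      "| loci called:", nrow(x$loci), "\n")
  if (nrow(x$loci)) {
    cat("  loci:\n")
    print(x$loci[, c("chrom", "junction", "orientation", "n_split",
                     "n_discordant", "microhomology_bp", "cn_class",
                     "sidedness")], row.names = FALSE)
  }
  if (nrow(x$events)) {
    cat("  two-sided events:\n")
    print(x$events[, c("chrom", "junction_a", "junction_b", "gap_bp",
                       "true_insertion_evidence")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.repeat_locus_calls <- function(object, ...) {
  loci <- object$loci
  out <- list(
    sample_id = object$sample_id,
    n_loci = nrow(loci),
    n_one_sided = sum(loci$sidedness == "one_sided"),
    n_two_sided_events = nrow(object$events),
    microhomology_ge1 = if (nrow(loci))
      mean(loci$microhomology_bp >= 1, na.rm = TRUE) else NA_real_,
    cn_class = if (nrow(loci)) table(loci$cn_class) else NULL)
  class(out) <- "summary.repeat_locus_calls"
  out
}

#' @export
print.summary.repeat_locus_calls <- function(x, ...) {
  cat("Sample", x$sample_id, "-", x$n_loci, "telomeric repeat loci (",
      x$n_one_sided, "one-sided,", x$n_two_sided_events,
      "two-sided events )\n")
  if (!is.na(x$microhomology_ge1))
    cat(sprintf("  fraction with >=1 bp microhomology: %.3f\n",
                x$microhomology_ge1))
  if (!is.null(x$cn_class)) {
    cat("  copy-number classes:\n"); print(x$cn_class)
  }
  invisible(x)
}

#' @export
as.data.frame.repeat_locus_calls <- function(x, ...) x$loci
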
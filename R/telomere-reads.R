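#' Count telomeric hexamer occurrences on both strands
#'
#' Counts non-overlapping occurrences of any of the G-strand telomeric repeat
#' types (default TTAGGG, TCAGGG, TGAGGG, TTGGGG) scanning left to right, and
#' independently of their reverse complements (CCCTAA, CCCTGA, CCCTCA,
#' CCCAAC).  Occurrences need not be adjacent ("non-consecutive instances");
#' N bases never match.
#'
#' @param seq character vector of DNA sequences.
#' @param patterns G-strand hexamer set.
#' @return An integer matrix with one row per sequence and columns
#'   \code{fwd} (G-strand count) and \code{rev} (C-strand count).
#' @examples
#' count_hexamers(strrep("TTAGGG", 6))
#' @export
count_hexamers <- function(seq, patterns = neotel_config()$hexamers) {
  cbind(fwd = count_nonoverlapping(seq, patterns),
        rev = count_nonoverlapping(seq, revcomp(patterns)))
}

# non-overlapping left-to-right count of a pattern union; vectorized.
# grepl prefilter keeps the expensive gregexpr off pattern-free reads.
count_nonoverlapping <- function(seq, patterns) {
  n <- integer(length(seq))
  if (!length(seq)) return(n)
  rx <- paste(patterns, collapse = "|")
  hit <- grepl(rx, seq, perl = TRUE, useBytes = TRUE)
  if (any(hit)) {
    n[hit] <- vapply(gregexpr(rx, seq[hit], perl = TRUE, useBytes = TRUE),
                     length, integer(1))
  }
  n
}

#' Fixed-count telomeric read rule (WGS)
#'
#' A read is telomeric when it contains at least \code{min_hexamers}
#' (default 6) non-consecutive instances of the telomeric repeat types on one
#' strand.  Forward and reverse-strand counts are not summed; the maximum is
#' used, since a genuine telomeric read is strand-coherent.
#'
#' @inheritParams count_hexamers
#' @param min_hexamers minimum hexamer instances.
#' @return Logical vector.
#' @examples
#' is_telomeric_fixed(strrep("TTAGGG", 6))   # TRUE
#' is_telomeric_fixed(strrep("TTAGGG", 5))   # FALSE
#' @export
is_telomeric_fixed <- function(seq, min_hexamers = 6L,
                               patterns = neotel_config()$hexamers) {
  cnt <- count_hexamers(seq, patterns)
  pmax(cnt[, "fwd"], cnt[, "rev"]) >= min_hexamers
}

#' Per-100-bp telomeric read rule (RNA / ChIP)
#'
#' A read qualifies when its strand-coherent hexamer count reaches
#' \code{rt} repeats per 100 bp of read length; the required count is scaled
#' by the read length and rounded up (threshold semantics).  The published
#' operating points are \code{rt = 14} for TERRA extraction from RNA reads
#' and \code{rt = 8} for ChIP telomere extraction.
#'
#' @inheritParams count_hexamers
#' @param rt required repeats per 100 bp of read length (> 0).
#' @return Logical vector.
#' @examples
#' is_telomeric_per100bp(paste0(strrep("TTAGGG", 14), strrep("A", 16)), 14)
#' @export
is_telomeric_per100bp <- function(seq, rt,
                                  patterns = neotel_config()$hexamers) {
  stopifnot(rt > 0)
  cnt <- count_hexamers(seq, patterns)
  required <- ceiling(rt * nchar(seq) / 100)
  pmax(cnt[, "fwd"], cnt[, "rev"]) >= required
}

#' Satellite repeat read rule
#'
#' A read is a satellite read when the canonical satellite motif, or its
#' reverse complement, occurs as a substring.
#'
#' @param seq character vector of DNA sequences.
#' @param canonical canonical motif, e.g.
#'   \code{neotel_config()$satII_canonical}.
#' @return Logical vector.
#' @examples
#' cfg <- neotel_config()
#' is_satellite(paste0("AAAA", cfg$satII_canonical, "TTTT"),
#'              cfg$satII_canonical)
#' @export
is_satellite <- function(seq, canonical) {
  grepl(canonical, seq, fixed = TRUE) |
    grepl(revcomp(canonical), seq, fixed = TRUE)
}

#' Classify a read set under one of the three extraction rules
#'
#' Convenience wrapper returning one row per read with both strand counts and
#' the telomeric call under the selected rule.
#'
#' @param rec alignment records or a character vector of sequences.
#' @param mode "wgs" (fixed count), "rna" or "chip" (per-100-bp).
#' @param rt per-100-bp threshold override (defaults to the mode's standard
#'   operating point; ignored for \code{mode = "wgs"}).
#' @param cfg a \code{\link{neotel_config}}.
#' @return data.frame with columns read_id, fwd_count, rev_count, best_strand,
#'   is_telomeric, rule.
#' @export
classify_reads <- function(rec, mode = c("wgs", "rna", "chip"), rt = NULL,
                           cfg = neotel_config()) {
  mode <- match.arg(mode)
  if (is.character(rec)) {
    rec <- data.frame(read_id = as.character(seq_along(rec)), seq = rec,
                      stringsAsFactors = FALSE)
  }
  cnt <- count_hexamers(rec$seq, cfg$hexamers)
  if (mode == "wgs") {
    telo <- pmax(cnt[, "fwd"], cnt[, "rev"]) >= cfg$wgs_min_hexamers
    rule <- "fixed_count"
  } else {
    if (is.null(rt))
      rt <- if (mode == "rna") cfg$rna_rt_per_100bp else cfg$chip_rt_per_100bp
    telo <- pmax(cnt[, "fwd"], cnt[, "rev"]) >=
      ceiling(rt * nchar(rec$seq) / 100)
    rule <- "per_100bp"
  }
  data.frame(read_id = rec$read_id,
             fwd_count = cnt[, "fwd"], rev_count = cnt[, "rev"],
             best_strand = ifelse(cnt[, "rev"] > cnt[, "fwd"], "C", "G"),
             is_telomeric = telo, rule = rule,
             stringsAsFactors = FALSE)
}
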
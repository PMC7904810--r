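#' Pipeline configuration
#'
#' Bundles every numeric threshold of the pipeline with its default.  Each
#' default is the operating point of the published analysis workflow this
#' package implements; all are overridable.
#'
#' @param ... named overrides of the defaults listed below.  Unknown names are
#'   an error.
#'
#' @details Defaults:
#' \describe{
#'   \item{hexamers}{the four most common telomeric repeat types
#'     (G-strand): TTAGGG, TCAGGG, TGAGGG, TTGGGG.}
#'   \item{satII_canonical, satIII_canonical}{canonical human satellite II /
#'     III motifs used for satellite read extraction.}
#'   \item{wgs_min_hexamers}{6; minimum non-consecutive hexamer instances for
#'     the fixed-count telomeric read rule used on WGS reads.}
#'   \item{low_mapq}{8; reads with mapping quality below this (or unmapped)
#'     enter the telomere-content numerator.}
#'   \item{anchor_min_mapq}{30; discordant anchors must be uniquely mapped
#'     with mapping quality strictly above this.}
#'   \item{region_size_bp}{1000; width of candidate discordant-read regions.}
#'   \item{min_discordant}{4; minimum tumor discordant reads per region.}
#'   \item{max_control_discordant}{0; maximum matched-control discordant reads
#'     tolerated in a (padded) candidate region.}
#'   \item{pon_min_samples}{15; regions with discordant pairs in at least this
#'     many panel-of-normals samples are excluded.}
#'   \item{min_split_reads}{3; minimum split reads agreeing exactly on a
#'     junction position.}
#'   \item{two_sided_window_bp}{10000; maximum gap between opposite-orientation
#'     loci forming a two-sided event.}
#'   \item{gc_bin}{c(0.48, 0.52); inclusive GC-fraction window of the
#'     telomere-content denominator reads.}
#'   \item{rna_rt_per_100bp, chip_rt_per_100bp}{14 and 8; per-100-bp repeat
#'     thresholds for TERRA (RNA) and ChIP telomeric read extraction.}
#'   \item{ccircle_fold}{4; minimum fold increase of sample AUC over the
#'     no-polymerase control.}
#'   \item{ccircle_pos_frac}{0.20; minimum fraction of the positive-control
#'     AUC.}
#'   \item{alt_log2_telcontent}{1.0; log2 telomere-content ratio above which a
#'     tumor is ALT-classified.}
#'   \item{amp_min_copies}{8; gene copies (diploid-equivalent) defining
#'     amplification.}
#'   \item{tertp_min_alt_reads, tertp_min_vaf}{2 and 0.20; relaxed TERT
#'     promoter mutation calling thresholds.}
#'   \item{frip_min}{0.01; samples with fraction of reads in peaks below this
#'     are excluded from enrichment analyses.}
#'   \item{hotspot_merge_bp, hotspot_min_samples}{1e6 and 3; cohort hotspot
#'     clustering parameters.}
#'   \item{cn_boundary_tol_bp}{50000; maximum distance between a junction and
#'     a copy-number segment boundary for copy-number association, matching
#'     the detection limit of segment-based copy-number callers.}
#'   \item{min_anchor_bp}{20; minimum aligned bases for a soft-clipped read to
#'     count as anchored (simulator and junction refinement).}
#'   \item{junction_tol_bp}{0; split-read junction agreement tolerance
#'     (exact agreement by default).}
#' }
#'
#' @return A named list with class \code{"neotel_config"}.
#' @examples
#' cfg <- neotel_config(min_discordant = 6)
#' cfg$min_discordant
#' @export
neotel_config <- function(...) {
  cfg <- list(
    hexamers          = c("TTAGGG", "TCAGGG", "TGAGGG", "TTGGGG"),
    satII_canonical   = "ATTCCATTCGATTCCATTCG",
    satIII_canonical  = "ATTCCATTCCATTCCATTCCATTCCATTCC",
    wgs_min_hexamers  = 6L,
    low_mapq          = 8L,
    anchor_min_mapq   = 30L,
    region_size_bp    = 1000L,
    min_discordant    = 4L,
    max_control_discordant = 0L,
    pon_min_samples   = 15L,
    min_split_reads   = 3L,
    two_sided_window_bp = 10000L,
    gc_bin            = c(0.48, 0.52),
    rna_rt_per_100bp  = 14,
    chip_rt_per_100bp = 8,
    ccircle_fold      = 4,
    ccircle_pos_frac  = 0.20,
    alt_log2_telcontent = 1.0,
    amp_min_copies    = 8,
    tertp_min_alt_reads = 2L,
    tertp_min_vaf     = 0.20,
    frip_min          = 0.01,
    hotspot_merge_bp  = 1000000L,
    hotspot_min_samples = 3L,
    cn_boundary_tol_bp = 50000L,
    min_anchor_bp     = 20L,
    junction_tol_bp   = 0L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration option(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$gc_bin[1] <= cfg$gc_bin[2])
  structure(cfg, class = "neotel_config")
}

#' @export
print.neotel_config <- function(x, ...) {
  cat("neotel pipeline configuration\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, paste(format(val), collapse = ", ")))
  }
  invisible(x)
}
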
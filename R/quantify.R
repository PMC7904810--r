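#' TERRA expression from RNA-sequencing reads
#'
#' TERRA reads are reads passing the per-100-bp telomeric rule at
#' \code{rt = 14} repeats per 100 bp, counted independently of mapping
#' position (telomeric transcripts rarely align uniquely).  The count is
#' normalized by the total (non-duplicate) read count and scaled to reads per
#' million.
#'
#' @param rec alignment records of an RNA-seq sample (mapped and unmapped).
#' @param sample_id sample label.
#' @param cfg a \code{\link{neotel_config}}.
#' @return One-row data.frame: sample_id, terra_reads, total_reads,
#'   terra_per_million.
#' @export
terra_quantify <- function(rec, sample_id = "sample", cfg = neotel_config()) {
  rec <- rec[!rec$is_duplicate, , drop = FALSE]
  if (nrow(rec) == 0L) stop("empty read set")
  terra <- sum(is_telomeric_per100bp(rec$seq, cfg$rna_rt_per_100bp,
                                     cfg$hexamers))
  data.frame(sample_id = sample_id, terra_reads = terra,
             total_reads = nrow(rec),
             terra_per_million = terra / nrow(rec) * 1e6,
             stringsAsFactors = FALSE)
}

#' Repeat enrichment of a ChIP sample over its input
#'
#' Computes the log2 enrichment of repeat-class reads in the
#' immunoprecipitate relative to the input chromatin:
#' \deqn{log2\left(\frac{repeat\ reads\ in\ IP / total\ mapped\ reads}
#'                      {repeat\ reads\ in\ input / total\ mapped\ reads}\right)}
#' The repeat numerators scan all (including unmapped) non-duplicate records;
#' the denominators count mapped non-duplicate records only, exactly as the
#' normalization is defined.  The telomere class uses the per-100-bp rule at
#' \code{rt} (default 8); the satII/satIII classes use canonical motif
#' substring matching.
#'
#' @param ip,input alignment records for IP and input.
#' @param class "telomere", "satII" or "satIII".
#' @param rt per-100-bp threshold for the telomere class.
#' @param sample_id,mark labels carried through to the result.
#' @param cfg a \code{\link{neotel_config}}.
#' @return One-row data.frame with the counts, \code{log2_enrichment}
#'   (NA with a \code{reason} attribute when the input has zero repeat
#'   reads), \code{frip} (NA until \code{\link{frip_filter}} is applied) and
#'   \code{excluded}.
#' @export
repeat_enrichment <- function(ip, input,
                              class = c("telomere", "satII", "satIII"),
                              rt = NULL, sample_id = "sample", mark = "mark",
                              cfg = neotel_config()) {
  class <- match.arg(class)
  if (is.null(rt)) rt <- cfg$chip_rt_per_100bp
  nrep <- function(rec) {
    rec <- rec[!rec$is_duplicate, , drop = FALSE]
    switch(class,
      telomere = sum(is_telomeric_per100bp(rec$seq, rt, cfg$hexamers)),
      satII = sum(is_satellite(rec$seq, cfg$satII_canonical)),
      satIII = sum(is_satellite(rec$seq, cfg$satIII_canonical)))
  }
  nmapped <- function(rec) sum(!rec$is_duplicate & !is.na(rec$chrom))
  ip_rep <- nrep(ip); in_rep <- nrep(input)
  ip_tot <- nmapped(ip); in_tot <- nmapped(input)
  if (ip_tot == 0L || in_tot == 0L) stop("zero mapped reads")
  if (in_rep == 0L) {
    enr <- structure(NA_real_, reason = "zero repeat reads in input")
  } else if (ip_rep == 0L) {
    enr <- structure(NA_real_, reason = "zero repeat reads in IP")
  } else {
    enr <- log2((ip_rep / ip_tot) / (in_rep / in_tot))
  }
  out <- data.frame(sample_id = sample_id, mark = mark, class = class,
                    ip_repeat_reads = ip_rep, ip_mapped_total = ip_tot,
                    input_repeat_reads = in_rep, input_mapped_total = in_tot,
                    log2_enrichment = as.numeric(enr), frip = NA_real_,
                    excluded = FALSE, stringsAsFactors = FALSE)
  if (!is.null(attr(enr, "reason"))) attr(out, "reason") <- attr(enr, "reason")
  out
}

#' Apply the fraction-of-reads-in-peaks quality exclusion
#'
#' ChIP samples with a fraction of reads in peaks (FRiP) below
#' \code{cfg$frip_min} (default 1\%) are flagged as excluded from enrichment
#' analyses.  Peak calling itself is out of scope; the FRiP value is supplied
#' externally.  A sample at exactly the threshold is retained.
#'
#' @param result enrichment result row(s) from \code{\link{repeat_enrichment}}.
#' @param frip FRiP value(s) in [0, 1].
#' @param cfg a \code{\link{neotel_config}}.
#' @return \code{result} with \code{frip} and \code{excluded} filled in.
#' @export
frip_filter <- function(result, frip, cfg = neotel_config()) {
  stopifnot(all(frip >= 0 & frip <= 1))
  result$frip <- frip
  result$excluded <- frip < cfg$frip_min
  result
}
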
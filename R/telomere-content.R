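#' Count telomere-content numerator reads
#'
#' Counts non-duplicate reads that are unmapped or of very low alignment
#' confidence (mapping quality below \code{cfg$low_mapq}, default 8) and that
#' satisfy the fixed-count telomeric rule (6 hexamer instances).  Reads that
#' map confidently are excluded even when repeat-rich, since they represent
#' interstitial telomeric sequence rather than telomeres proper.
#'
#' @param rec alignment records.
#' @param cfg a \code{\link{neotel_config}}.
#' @return Integer count.
#' @export
select_telomere_reads <- function(rec, cfg = neotel_config()) {
  cand <- !rec$is_duplicate & (is.na(rec$chrom) | rec$mapq < cfg$low_mapq)
  sum(cand & is_telomeric_fixed(rec$seq, cfg$wgs_min_hexamers, cfg$hexamers))
}

#' Count GC-bin denominator reads
#'
#' Counts non-duplicate reads whose G+C fraction over non-N bases lies in the
#' inclusive window \code{cfg$gc_bin} (default 48-52\%).  Restricting the
#' denominator to this narrow GC window makes the telomere content robust to
#' library GC bias.  All-N reads are excluded (zero denominator).
#'
#' @inheritParams select_telomere_reads
#' @return Integer count.
#' @export
count_gc_bin <- function(rec, cfg = neotel_config()) {
  seqs <- rec$seq[!rec$is_duplicate]
  if (!length(seqs)) return(0L)
  freq <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                      c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  gc <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom, NA_real_)
  sum(!is.na(gc) & gc >= cfg$gc_bin[1] & gc <= cfg$gc_bin[2])
}

#' Per-sample GC-normalized telomere content
#'
#' Telomere content is the number of telomeric reads (unmapped or
#' mapq < 8, with at least 6 telomeric hexamer instances) per million reads
#' with a GC content of 48-52\%.  The "per million" scaling makes the values
#' human-readable; the ALT classification uses the tumor/control log2 ratio,
#' which is scale-free.
#'
#' @param rec alignment records of one sample.
#' @param sample_id sample label.
#' @param cfg a \code{\link{neotel_config}}.
#' @return A one-row data.frame: sample_id, tel_read_count,
#'   gc_bin_read_count, content.
#' @examples
#' # 10 telomeric reads per 1,000 GC-bin reads is a content of 10,000/million
#' @export
telomere_content <- function(rec, sample_id = "sample",
                             cfg = neotel_config()) {
  tel <- select_telomere_reads(rec, cfg)
  gcn <- count_gc_bin(rec, cfg)
  if (gcn == 0L) stop("no reads in the GC bin; content undefined")
  data.frame(sample_id = sample_id, tel_read_count = tel,
             gc_bin_read_count = gcn, content = tel / gcn * 1e6,
             stringsAsFactors = FALSE)
}

#' Tumor/control log2 telomere content ratio
#'
#' With a matched control, the ratio is \code{log2(tumor / control)} of the
#' content values.  Without one, the denominator is the arithmetic mean
#' content of all controls sharing the tumor's sequencing protocol key.
#'
#' @param tumor one-row content table from \code{\link{telomere_content}} (or
#'   a single numeric content value).
#' @param control matched-control content table / value, or a data.frame of
#'   control contents with columns \code{content} and \code{protocol} when no
#'   matched control exists.
#' @param protocol_key tumor protocol key used to select controls in cohort
#'   mode.
#' @return Numeric log2 ratio; the \code{normalization} attribute records
#'   which denominator was used.
#' @examples
#' log2_ratio(400, data.frame(content = c(100, 300),
#'                            protocol = "hiseq"), "hiseq")   # log2(400/200)
#' @export
log2_ratio <- function(tumor, control, protocol_key = NULL) {
  tc <- if (is.data.frame(tumor)) tumor$content else as.numeric(tumor)
  if (is.data.frame(control) && "protocol" %in% names(control)) {
    if (is.null(protocol_key)) stop("protocol_key required for cohort mode")
    pool <- control$content[control$protocol == protocol_key]
    if (!length(pool))
      stop("no controls with protocol key '", protocol_key, "'")
    cc <- mean(pool)
    norm <- "protocol_mean"
  } else {
    cc <- if (is.data.frame(control)) control$content else as.numeric(control)
    norm <- "matched_control"
  }
  if (cc <= 0) stop("control content must be positive")
  structure(log2(tc / cc), normalization = norm)
}
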
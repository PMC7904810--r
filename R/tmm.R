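#' C-Circle positivity call
#'
#' A sample is C-Circle positive when the amplified signal shows a minimum
#' 4-fold increase of the area under the curve relative to the control
#' without polymerase, and reaches at least 20\% of the positive-control
#' (CHLA-90) AUC.  A no-polymerase AUC of exactly zero satisfies the fold
#' condition (the signal cannot be attributed to background).
#'
#' @param auc_sample,auc_no_polymerase,auc_positive_control AUC values
#'   (vectorized; non-negative, positive control strictly positive).
#' @param cfg a \code{\link{neotel_config}}.
#' @return Logical vector.
#' @examples
#' call_ccircle(5, 1, 10)    # TRUE  (5-fold, 50% of positive control)
#' call_ccircle(10, 1, 60)   # FALSE (16.7% of positive control)
#' @export
call_ccircle <- function(auc_sample, auc_no_polymerase, auc_positive_control,
                         cfg = neotel_config()) {
  if (any(auc_sample < 0) || any(auc_no_polymerase < 0))
    stop("AUC values must be non-negative")
  if (any(auc_positive_control <= 0))
    stop("positive-control AUC must be positive")
  fold_ok <- auc_no_polymerase == 0 |
    auc_sample >= cfg$ccircle_fold * auc_no_polymerase
  frac_ok <- auc_sample >= cfg$ccircle_pos_frac * auc_positive_control
  fold_ok & frac_ok
}

#' Gene-level copy-number classification
#'
#' A gene is amplified when its copy number reaches
#' \code{cfg$amp_min_copies} scaled by ploidy/2 (default: at least 8 copies
#' in a diploid genome).  A copy number below 0.5 is a homozygous deletion;
#' any other copy number below ploidy is a deletion; loss of heterozygosity
#' that is not also a deletion (copy-neutral LOH, minor copy number 0) is
#' LOH; everything else is neutral.
#'
#' @param gene_cn total gene copy number (vectorized).
#' @param ploidy sample ploidy (> 0).
#' @param minor_cn minor allele copy number, or NA when unknown.
#' @param cfg a \code{\link{neotel_config}}.
#' @return Character vector over \{amplified, homozygous_deletion, deletion,
#'   LOH, neutral\}.
#' @examples
#' classify_gene_cnv(8, 2, 1)   # amplified
#' classify_gene_cnv(2, 2, 0)   # LOH (copy-neutral)
#' @export
classify_gene_cnv <- function(gene_cn, ploidy, minor_cn = NA_real_,
                              cfg = neotel_config()) {
  stopifnot(all(ploidy > 0))
  n <- max(length(gene_cn), length(ploidy), length(minor_cn))
  gene_cn <- rep_len(gene_cn, n); ploidy <- rep_len(ploidy, n)
  minor_cn <- rep_len(minor_cn, n)
  out <- rep("neutral", n)
  out[!is.na(minor_cn) & minor_cn == 0] <- "LOH"
  out[gene_cn < ploidy] <- "deletion"
  out[gene_cn < 0.5] <- "homozygous_deletion"
  out[gene_cn >= cfg$amp_min_copies * (ploidy / 2)] <- "amplified"
  out
}

#' Relaxed TERT promoter mutation call
#'
#' The hotspot promoter positions are recurrently mutated at low variant
#' allele fractions, so calling uses relaxed criteria: the mutated base must
#' be seen in at least 2 reads at a mutation frequency of at least 20\%.
#'
#' @param ref_reads,alt_reads read counts at the promoter position
#'   (vectorized; total depth must be positive).
#' @param cfg a \code{\link{neotel_config}}.
#' @return Logical vector.
#' @examples
#' call_tert_promoter(6, 2)   # TRUE (25% VAF)
#' call_tert_promoter(9, 1)   # FALSE
#' @export
call_tert_promoter <- function(ref_reads, alt_reads, cfg = neotel_config()) {
  depth <- ref_reads + alt_reads
  if (any(depth <= 0)) stop("zero depth at promoter position")
  alt_reads >= cfg$tertp_min_alt_reads &
    alt_reads / depth >= cfg$tertp_min_vaf
}

#' Telomere maintenance mechanism (TMM) subgroup classification
#'
#' Assigns each tumor to one of ALT, MNA, TERT, OTHER or HET_ALT_MNA from
#' four resolved predicates.  Decision order:
#' \enumerate{
#'   \item C-Circle negative, log2 telomere content > 1 \emph{and} amplified
#'     MYCN: HET_ALT_MNA (heterogeneous ALT/MNA despite C-Circle
#'     negativity);
#'   \item C-Circle positive \emph{or} log2 telomere content > 1: ALT;
#'   \item amplified MYCN: MNA (telomerase activation by MYCN);
#'   \item TERT structural variation or promoter mutation: TERT;
#'   \item otherwise OTHER.
#' }
#' ALT takes precedence over MNA and TERT where the evidence overlaps; the
#' evidence columns record all true predicates regardless of the label.
#'
#' @param ccircle logical; C-Circle positive.
#' @param log2_telcontent numeric; tumor/control log2 telomere content.
#' @param mycn_amplified logical.
#' @param tert_event logical; TERT SV or promoter mutation.
#' @param sample_id optional labels.
#' @param cfg a \code{\link{neotel_config}} (supplies the log2 telomere
#'   content cutoff, default 1).
#' @return data.frame with \code{label} and logical evidence columns
#'   ccircle_pos, telcontent_high, mycn_amp, tert_ev.
#' @examples
#' classify_tmm(TRUE, 0.2, FALSE, FALSE)$label    # "ALT"
#' classify_tmm(FALSE, 1.5, TRUE, FALSE)$label    # "HET_ALT_MNA"
#' @export
classify_tmm <- function(ccircle, log2_telcontent, mycn_amplified, tert_event,
                         sample_id = NULL, cfg = neotel_config()) {
  n <- max(length(ccircle), length(log2_telcontent), length(mycn_amplified),
           length(tert_event))
  ccircle <- rep_len(as.logical(ccircle), n)
  log2_telcontent <- rep_len(log2_telcontent, n)
  mycn_amplified <- rep_len(as.logical(mycn_amplified), n)
  tert_event <- rep_len(as.logical(tert_event), n)
  if (anyNA(ccircle) || anyNA(log2_telcontent) || anyNA(mycn_amplified) ||
      anyNA(tert_event))
    stop("all predicates must be resolved (no NA) at this layer")
  tel_high <- log2_telcontent > cfg$alt_log2_telcontent
  label <- rep("OTHER", n)
  label[tert_event] <- "TERT"
  label[mycn_amplified] <- "MNA"
  label[ccircle | tel_high] <- "ALT"
  label[!ccircle & tel_high & mycn_amplified] <- "HET_ALT_MNA"
  out <- data.frame(label = label, ccircle_pos = ccircle,
                    telcontent_high = tel_high, mycn_amp = mycn_amplified,
                    tert_ev = tert_event, stringsAsFactors = FALSE)
  if (!is.null(sample_id)) out <- cbind(sample_id = sample_id, out)
  out
}
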
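#' Read alignment records from a SAM or BAM file
#'
#' Converts the 1-based SAM coordinate convention to the package's internal
#' 0-based convention.  Duplicate-flagged reads are flagged, not dropped.
#' Only the CIGAR operations M, S, I, D are supported.
#'
#' @param path SAM text file (extension \code{.sam}) or BAM file
#'   (\code{.bam}; requires the Rsamtools package and, for region queries, an
#'   index).
#' @param region optional \code{c(chrom, start, end)} (start/end numeric,
#'   0-based half-open) restricting the records returned.  For SAM text this
#'   is a linear-scan filter; for BAM it is an indexed query and a missing
#'   index is an error.
#' @return A data.frame of alignment records (see
#'   \code{\link{alignment_records}}).
#' @export
read_alignments <- function(path, region = NULL) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(read_bam_records(path, region))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) {
    return(alignment_records(read_id = character(0), seq = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("malformed SAM line(s): fewer than 11 fields")
  get <- function(i) vapply(fields, `[[`, "", i)
  flag <- as.integer(get(2))
  unmapped <- bitwAnd(flag, 4L) > 0L
  mate_unmapped <- bitwAnd(flag, 8L) > 0L
  rname <- get(3); posn <- as.integer(get(4))
  rnext <- get(7); pnext <- as.integer(get(8))
  cigar <- get(6)
  read_id <- get(1)
  # surface malformed CIGARs with the offending read id
  bad <- !unmapped & !grepl("^([0-9]+[MSID])+$", cigar)
  if (any(bad))
    stop("malformed CIGAR for read ", read_id[which(bad)[1]], ": ",
         cigar[which(bad)[1]])
  mate_chrom <- ifelse(rnext == "=", rname, rnext)
  mate_chrom[mate_chrom == "*" | mate_unmapped] <- NA_character_
  alignment_records(
    read_id = read_id,
    chrom = ifelse(unmapped, NA_character_, rname),
    pos = ifelse(unmapped, NA_integer_, posn - 1L),
    mapq = ifelse(unmapped, 0L, as.integer(get(5))),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = ifelse(unmapped, "*", cigar),
    seq = get(10),
    mate_chrom = mate_chrom,
    mate_pos = ifelse(is.na(mate_chrom), NA_integer_, pnext - 1L),
    mate_strand = ifelse(is.na(mate_chrom),
                         NA_character_,
                         ifelse(bitwAnd(flag, 32L) > 0L, "-", "+")),
    is_proper_pair = bitwAnd(flag, 2L) > 0L,
    is_duplicate = bitwAnd(flag, 1024L) > 0L
  ) -> rec
  if (!is.null(region)) rec <- filter_region(rec, region)
  rec
}

read_bam_records <- function(path, region = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading BAM files requires the Rsamtools package")
  param_what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
                  "mpos", "seq")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(what = param_what)
  } else {
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path)))
      stop("region query on BAM requires an index (.bai)")
    which <- GenomicRanges::GRanges(region[[1]],
      IRanges::IRanges(as.numeric(region[[2]]) + 1, as.numeric(region[[3]])))
    param <- Rsamtools::ScanBamParam(what = param_what, which = which)
  }
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  flag <- b$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  alignment_records(
    read_id = b$qname,
    chrom = ifelse(unmapped, NA_character_, as.character(b$rname)),
    pos = ifelse(unmapped, NA_integer_, b$pos - 1L),
    mapq = ifelse(unmapped, 0L, b$mapq),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = ifelse(unmapped, "*", b$cigar),
    seq = as.character(b$seq),
    mate_chrom = ifelse(bitwAnd(flag, 8L) > 0L, NA_character_,
                        as.character(b$mrnm)),
    mate_pos = ifelse(bitwAnd(flag, 8L) > 0L, NA_integer_, b$mpos - 1L),
    mate_strand = ifelse(bitwAnd(flag, 8L) > 0L, NA_character_,
                         ifelse(bitwAnd(flag, 32L) > 0L, "-", "+")),
    is_proper_pair = bitwAnd(flag, 2L) > 0L,
    is_duplicate = bitwAnd(flag, 1024L) > 0L
  )
}

filter_region <- function(rec, region) {
  chrom <- region[[1]]
  start <- as.numeric(region[[2]]); end <- as.numeric(region[[3]])
  span <- ifelse(is.na(rec$chrom), 0L, cigar_ref_span(rec$cigar))
  keep <- !is.na(rec$chrom) & rec$chrom == chrom &
    rec$pos < end & (rec$pos + span) > start
  rec[keep, , drop = FALSE]
}

#' Write alignment records as SAM text
#'
#' The inverse of \code{\link{read_alignments}} for SAM text: internal 0-based
#' positions are converted back to the 1-based SAM convention.
#'
#' @param rec alignment record data.frame.
#' @param path output file.
#' @param ref_lengths named integer vector of contig lengths for the
#'   \code{@SQ} header lines; inferred crudely from the records when omitted.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(rec, path, ref_lengths = NULL) {
  if (is.null(ref_lengths)) {
    chroms <- unique(stats::na.omit(rec$chrom))
    if (length(chroms)) {
      ref_lengths <- vapply(chroms, function(cc) {
        i <- which(rec$chrom == cc)
        max(rec$pos[i] + cigar_ref_span(rec$cigar[i])) + 1L
      }, numeric(1))
    } else ref_lengths <- integer(0)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           if (length(ref_lengths))
             sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                     as.integer(ref_lengths)))
  flag <- 1L +                                        # paired
    ifelse(rec$is_proper_pair, 2L, 0L) +
    ifelse(is.na(rec$chrom), 4L, 0L) +
    ifelse(is.na(rec$mate_chrom), 8L, 0L) +
    ifelse(!is.na(rec$strand) & rec$strand == "-", 16L, 0L) +
    ifelse(!is.na(rec$mate_strand) & rec$mate_strand == "-", 32L, 0L) +
    ifelse(rec$is_duplicate, 1024L, 0L)
  rnext <- ifelse(is.na(rec$mate_chrom), "*",
                  ifelse(!is.na(rec$chrom) & rec$mate_chrom == rec$chrom,
                         "=", rec$mate_chrom))
  body <- paste(rec$read_id, flag,
                ifelse(is.na(rec$chrom), "*", rec$chrom),
                ifelse(is.na(rec$pos), 0L, rec$pos + 1L),
                rec$mapq,
                ifelse(is.na(rec$chrom), "*", rec$cigar),
                rnext,
                ifelse(is.na(rec$mate_pos), 0L, rec$mate_pos + 1L),
                0L, rec$seq, "*", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write called repeat loci as a BED6+ file
#'
#' One line per locus, 0-based half-open (a junction is a 1-bp feature).  The
#' name column encodes orientation and sidedness; extra columns carry the
#' split-read count, discordant count, microhomology and copy-number class.
#'
#' @param loci data.frame of called loci (see \code{\link{call_repeat_loci}}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  hdr <- paste0("#chrom\tchromStart\tchromEnd\tname\tscore\tstrand\t",
                "n_split\tn_discordant\tmicrohomology_bp\tcn_class")
  if (is.null(loci) || nrow(loci) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  name <- sprintf("%s|%s|%d", loci$orientation, loci$sidedness,
                  seq_len(nrow(loci)))
  body <- paste(loci$chrom, loci$junction, loci$junction + 1L, name,
                pmin(loci$n_split, 1000L),
                ifelse(loci$orientation == "tel_right", "+", "-"),
                loci$n_split, loci$n_discordant,
                ifelse(is.na(loci$microhomology_bp), ".",
                       loci$microhomology_bp),
                loci$cn_class, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write copy-number segment tables
#'
#' Tab-separated tables with columns \code{chrom}, \code{start}, \code{end}
#' (0-based half-open), \code{total_cn} and optionally \code{minor_cn}.
#' Segments must be sorted and non-overlapping per chromosome.
#'
#' @param path TSV file.
#' @return \code{read_segments}: a validated data.frame.
#' @export
read_segments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "total_cn")
  if (!all(req %in% names(seg)))
    stop("segment table must have columns: ", paste(req, collapse = ", "))
  if (!"minor_cn" %in% names(seg)) seg$minor_cn <- NA_real_
  validate_segments(seg)
  seg
}

#' @rdname read_segments
#' @param seg segment data.frame.
#' @export
write_segments <- function(seg, path) {
  validate_segments(seg)
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_segments <- function(seg) {
  if (any(seg$start >= seg$end)) stop("segments must satisfy start < end")
  for (cc in unique(seg$chrom)) {
    s <- seg[seg$chrom == cc, ]
    if (is.unsorted(s$start)) stop("segments not sorted on ", cc)
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segments on ", cc)
  }
  invisible(seg)
}
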
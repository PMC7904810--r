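#' Build a table of alignment records
#'
#' The atomic input of all read-level stages: one row per aligned or unmapped
#' read with mate information, clipping and mapping quality.  Positions are
#' 0-based leftmost reference coordinates; unmapped reads carry \code{NA}
#' chromosome and position and mapping quality 0.
#'
#' @param read_id character; shared by the two mates of a pair.
#' @param chrom character or NA (NA = unmapped).
#' @param pos integer, 0-based leftmost reference position (NA iff unmapped).
#' @param mapq integer 0-60.
#' @param strand "+" or "-".
#' @param cigar CIGAR string over operations M, S, I, D (e.g. "70M30S");
#'   "*" for unmapped reads.
#' @param seq DNA string over A, C, G, T, N (reference-forward orientation for
#'   mapped reads, as in SAM).
#' @param mate_chrom,mate_pos,mate_strand mate placement (NA when the mate is
#'   unmapped or absent).
#' @param is_proper_pair logical; both ends mapped in the expected
#'   orientation/insert range.
#' @param is_duplicate logical; duplicate-flagged reads are retained in the
#'   table but excluded from all counting operations.
#' @param validate check invariants (sum of M/S/I lengths equals sequence
#'   length; pos NA iff chrom NA; mapq 0 when unmapped).
#'
#' @return A data.frame with one row per record.
#' @examples
#' alignment_records(read_id = "r1", chrom = "chr1", pos = 100L, mapq = 60L,
#'                   strand = "+", cigar = "6M", seq = "ACGTAC")
#' @export
alignment_records <- function(read_id, chrom = NA_character_, pos = NA_integer_,
                              mapq = 0L, strand = "+", cigar = "*", seq,
                              mate_chrom = NA_character_, mate_pos = NA_integer_,
                              mate_strand = NA_character_,
                              is_proper_pair = FALSE, is_duplicate = FALSE,
                              validate = TRUE) {
  if (length(read_id) == 0) {
    return(data.frame(read_id = character(), chrom = character(),
                      pos = integer(), mapq = integer(), strand = character(),
                      cigar = character(), seq = character(),
                      mate_chrom = character(), mate_pos = integer(),
                      mate_strand = character(), is_proper_pair = logical(),
                      is_duplicate = logical(), stringsAsFactors = FALSE))
  }
  rec <- data.frame(
    read_id = as.character(read_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    mapq = as.integer(mapq),
    strand = as.character(strand),
    cigar = as.character(cigar),
    seq = toupper(as.character(seq)),
    mate_chrom = as.character(mate_chrom),
    mate_pos = as.integer(mate_pos),
    mate_strand = as.character(mate_strand),
    is_proper_pair = as.logical(is_proper_pair),
    is_duplicate = as.logical(is_duplicate),
    stringsAsFactors = FALSE
  )
  if (validate) validate_alignments(rec)
  rec
}

validate_alignments <- function(rec) {
  unmapped <- is.na(rec$chrom)
  if (any(xor(unmapped, is.na(rec$pos))))
    stop("pos must be NA exactly for unmapped records (chrom NA)")
  if (any(rec$mapq[unmapped] != 0L))
    stop("unmapped records must have mapq 0")
  mapped <- which(!unmapped & rec$cigar != "*")
  if (length(mapped)) {
    qlen <- cigar_query_length(rec$cigar[mapped])
    bad <- qlen != nchar(rec$seq[mapped])
    if (any(bad))
      stop("CIGAR/sequence length mismatch for read(s): ",
           paste(utils::head(rec$read_id[mapped][bad], 5), collapse = ", "))
  }
  invisible(rec)
}

#' Parse CIGAR strings
#'
#' @param cigar character vector of CIGAR strings (ops M, S, I, D).
#' @return A list of character vectors of tokens (e.g. "70M", "30S").
#' @keywords internal
parse_cigar <- function(cigar) {
  blank <- is.na(cigar) | cigar == "*"
  toks <- vector("list", length(cigar))
  toks[blank] <- list(character(0))
  if (any(!blank)) {
    m <- gregexpr("[0-9]+[MSID]", cigar[!blank])
    tk <- regmatches(cigar[!blank], m)
    covered <- vapply(m, function(mm)
      if (mm[1] == -1L) 0L else sum(attr(mm, "match.length")), integer(1))
    bad <- covered != nchar(cigar[!blank])
    if (any(bad))
      stop("malformed CIGAR: ", cigar[!blank][which(bad)[1]])
    toks[!blank] <- tk
  }
  toks
}

# sum of selected op lengths per CIGAR, vectorized
cigar_op_sum <- function(cigar, ops) {
  vapply(parse_cigar(cigar), function(tk) {
    if (!length(tk)) return(0L)
    op <- substring(tk, nchar(tk), nchar(tk))
    sum(as.integer(substring(tk, 1L, nchar(tk) - 1L))[op %in% ops])
  }, integer(1))
}

# query (read) length implied by a CIGAR: sum of M/S/I op lengths
cigar_query_length <- function(cigar) cigar_op_sum(cigar, c("M", "S", "I"))

# reference span of a CIGAR: sum of M/D op lengths
cigar_ref_span <- function(cigar) cigar_op_sum(cigar, c("M", "D"))

# leading / trailing soft-clip lengths (0 when none)
cigar_clips <- function(cigar) {
  parsed <- parse_cigar(cigar)
  left <- vapply(parsed, function(tk)
    if (length(tk) && endsWith(tk[1], "S"))
      as.integer(substring(tk[1], 1L, nchar(tk[1]) - 1L)) else 0L, integer(1))
  right <- vapply(parsed, function(tk) {
    n <- length(tk)
    if (n && endsWith(tk[n], "S"))
      as.integer(substring(tk[n], 1L, nchar(tk[n]) - 1L)) else 0L
  }, integer(1))
  data.frame(left = left, right = right)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("TTAGGG")
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
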
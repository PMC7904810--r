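# Independent oracles used to cross-check the package implementations.

# character-by-character greedy left-to-right non-overlapping scan
naive_hexamer_count <- function(seq, patterns) {
  n <- nchar(seq); count <- 0L; pos <- 1L
  while (pos <= n - 5L) {
    if (substr(seq, pos, pos + 5L) %in% patterns) {
      count <- count + 1L
      pos <- pos + 6L
    } else {
      pos <- pos + 1L
    }
  }
  count
}

naive_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

# full hypergeometric enumeration of the two-sided Fisher p-value
fisher_enum_p <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= pobs * (1 + rel_tol)])
}

# full enumeration of the two-sided exact Wilcoxon rank-sum p-value
wilcox_enum_p <- function(x, y) {
  z <- c(x, y); n <- length(z); nx <- length(x)
  r <- rank(z)
  wobs <- sum(r[seq_len(nx)])
  sets <- utils::combn(n, nx)
  ws <- apply(sets, 2, function(i) sum(r[i]))
  p <- 2 * min(mean(ws <= wobs), mean(ws >= wobs))
  min(p, 1)
}

# rank-then-Pearson Spearman oracle
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

random_seq <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), "")
}

# minimal paired records: one mapped anchor + one mate
make_pair <- function(id, anchor_chrom, anchor_pos, anchor_mapq, anchor_seq,
                      mate_seq, mate_unmapped = TRUE, proper = FALSE,
                      anchor_dup = FALSE, mate_dup = FALSE) {
  rbind(
    alignment_records(read_id = id, chrom = anchor_chrom, pos = anchor_pos,
                      mapq = anchor_mapq, strand = "+",
                      cigar = paste0(nchar(anchor_seq), "M"),
                      seq = anchor_seq,
                      mate_chrom = if (mate_unmapped) NA else anchor_chrom,
                      mate_pos = if (mate_unmapped) NA else anchor_pos + 200L,
                      mate_strand = if (mate_unmapped) NA else "-",
                      is_proper_pair = proper, is_duplicate = anchor_dup),
    alignment_records(read_id = id,
                      chrom = if (mate_unmapped) NA else anchor_chrom,
                      pos = if (mate_unmapped) NA else anchor_pos + 200L,
                      mapq = if (mate_unmapped) 0L else 60L,
                      strand = "-",
                      cigar = if (mate_unmapped) "*"
                              else paste0(nchar(mate_seq), "M"),
                      seq = mate_seq,
                      mate_chrom = anchor_chrom, mate_pos = anchor_pos,
                      mate_strand = "+", is_proper_pair = proper,
                      is_duplicate = mate_dup))
}

TEL100 <- substr(strrep("TTAGGG", 17), 1, 100)     # pure telomeric 100-mer
BG100 <- strrep("ACTG", 25)                        # non-telomeric 100-mer

# identify split (soft-clipped) records near a junction; used to thin
# split-read support in threshold-sharpness checks
split_read_ids <- function(rec, chrom, junction, window = 500) {
  i <- which(!is.na(rec$chrom) & rec$chrom == chrom &
               grepl("S", rec$cigar, fixed = TRUE) &
               abs(rec$pos - junction) <= window)
  unique(rec$read_id[i])
}
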
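STOP_CODONS <- c("TAA", "TAG", "TGA")

## Longest ATG..stop span (in codons, excluding the stop) within one reading
## frame given as a codon vector.
orf_in_codons <- function(codons) {
  starts <- which(codons == "ATG")
  if (!length(starts)) return(0L)
  stops <- which(codons %in% STOP_CODONS)
  if (!length(stops)) return(0L)
  ## first stop strictly after each start
  nxt <- stops[findInterval(starts, stops) + 1L]
  spans <- nxt - starts
  spans <- spans[!is.na(spans)]
  if (!length(spans)) 0L else max(spans)
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

#' Longest open reading frame
#'
#' Scans all six reading frames (three on each strand) for spans that start
#' with ATG and end at the first in-frame stop codon (TAA/TAG/TGA), and
#' returns the longest such ORF in amino acids (start codon included, stop
#' excluded). Spans without an in-frame stop are not counted. `N` bases
#' never match a start or stop codon.
#'
#' @param sequence nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @return integer ORF length in amino acids; 0 if no ORF.
#' @examples
#' longest_orf("ATGAAATAG")  # 2
#' @export
longest_orf <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  seq <- toupper(sequence)
  if (grepl("[^ACGTN]", seq)) stop("sequence has characters outside ACGTN", call. = FALSE)
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    n <- nchar(s)
    for (off in 0:2) {
      if (n - off < 3L) next
      m <- n - off
      m <- m - m %% 3L
      codons <- substring(s, off + seq(1L, m, 3L), off + seq(3L, m + 2L, 3L))
      best <- max(best, orf_in_codons(codons))
    }
  }
  best
}

#' Classify transcripts as lncRNA or mRNA
#'
#' Applies the standard length/coding-potential heuristic: a transcript is a
#' lncRNA when it is at least `min_lnc_len` nucleotides long, its longest
#' ORF is shorter than `max_orf_aa` amino acids, and (when `use_hits`) it
#' has no protein-database hit. It is an mRNA when the ORF reaches
#' `max_orf_aa` or a hit is recorded. Everything else (e.g. short
#' transcripts without a long ORF) is `ambiguous`.
#'
#' @param records data frame with columns `id`, `length` and either
#'   `longest_orf_aa` or `sequence` (ORFs are computed with
#'   [longest_orf()] when absent); optional logical `hit_flag`.
#' @param min_lnc_len minimum lncRNA length in nt (default 200, the
#'   conventional long/short non-coding boundary).
#' @param max_orf_aa ORF length (aa) at or above which a transcript is
#'   considered coding (default 100).
#' @param use_hits also require lncRNAs to lack a protein hit, and treat a
#'   hit as evidence of coding (default `TRUE` when `hit_flag` is present).
#' @return `records` with columns `longest_orf_aa` and `biotype`
#'   (`"lncRNA"`, `"mRNA"` or `"ambiguous"`) filled in.
#' @export
classify_transcripts <- function(records, min_lnc_len = 200, max_orf_aa = 100,
                                 use_hits = "hit_flag" %in% names(records)) {
  records <- as.data.frame(records)
  if (!all(c("id", "length") %in% names(records))) {
    stop("records must have 'id' and 'length' columns", call. = FALSE)
  }
  if (anyNA(records$length)) stop("missing transcript length", call. = FALSE)
  if (is.null(records$longest_orf_aa)) {
    if (is.null(records$sequence)) {
      stop("provide 'longest_orf_aa' or 'sequence'", call. = FALSE)
    }
    records$longest_orf_aa <- vapply(records$sequence, longest_orf, integer(1))
  }
  hit <- if (use_hits) {
    if (is.null(records$hit_flag)) stop("use_hits = TRUE but no 'hit_flag' column",
                                        call. = FALSE)
    records$hit_flag %in% TRUE
  } else rep(FALSE, nrow(records))
  is_coding <- records$longest_orf_aa >= max_orf_aa | hit
  is_lnc <- records$length >= min_lnc_len &
    records$longest_orf_aa < max_orf_aa & !hit
  records$biotype <- ifelse(is_coding, "mRNA",
                            ifelse(is_lnc, "lncRNA", "ambiguous"))
  records
}
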
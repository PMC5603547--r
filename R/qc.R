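#' Aggregate per-sample read-accounting statistics
#'
#' Summarizes a per-sample table of raw, cleaned and mapped read counts into
#' the totals and percentages conventionally reported for an RNA-seq
#' experiment: total raw/clean/mapped reads, the percentage of raw reads
#' surviving cleaning, per-sample mapping ratios (mapped/clean), their
#' unweighted mean, and the range of raw read counts in millions.
#'
#' The mean mapping ratio is the unweighted average of the per-sample ratios
#' after they have been rounded to one decimal, matching how such tables are
#' printed (averaging the printed column); it is not the pooled ratio
#' \eqn{\sum mapped / \sum clean}. All percentages are rounded half-up to one
#' decimal.
#'
#' @param records data frame with columns `sample_id`, `raw_reads`,
#'   `clean_reads`, `mapped_reads` (additional columns such as `group` and
#'   `time_h` are carried along but unused).
#' @return A list of class `mapping_summary`: `total_raw`, `total_clean`,
#'   `total_mapped`, `pct_clean`, `per_sample_ratio` (named, 1 decimal),
#'   `mean_ratio`, `min_raw_millions`, `max_raw_millions`, `n_samples`.
#' @examples
#' tab <- data.frame(sample_id = c("a", "b"),
#'                   raw_reads = c(100, 200),
#'                   clean_reads = c(90, 180),
#'                   mapped_reads = c(80, 150))
#' summarize_mapping(tab)
#' @seealso [assembly_stats()], [trout_read_stats()]
#' @export
summarize_mapping <- function(records) {
  records <- as.data.frame(records)
  need <- c("raw_reads", "clean_reads", "mapped_reads")
  if (nrow(records) == 0L) stop("empty read-accounting table", call. = FALSE)
  if (!all(need %in% names(records))) {
    stop("records must have columns raw_reads, clean_reads, mapped_reads", call. = FALSE)
  }
  raw <- records$raw_reads; cln <- records$clean_reads; mp <- records$mapped_reads
  if (anyNA(c(raw, cln, mp))) stop("read counts contain NA", call. = FALSE)
  bad <- !(mp <= cln & cln <= raw & mp >= 0)
  if (any(bad)) {
    stop("invalid record(s) ", paste(which(bad), collapse = ", "),
         ": need 0 <= mapped <= clean <= raw", call. = FALSE)
  }
  ratio <- round_half_up(100 * mp / cln, 1)
  names(ratio) <- as.character(records$sample_id %||% seq_along(raw))
  out <- list(
    total_raw = sum(raw),
    total_clean = sum(cln),
    total_mapped = sum(mp),
    pct_clean = round_half_up(100 * sum(cln) / sum(raw), 1),
    per_sample_ratio = ratio,
    mean_ratio = round_half_up(mean(ratio), 1),
    min_raw_millions = round_half_up(min(raw) / 1e6, 1),
    max_raw_millions = round_half_up(max(raw) / 1e6, 1),
    n_samples = length(raw)
  )
  class(out) <- "mapping_summary"
  out
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat("Read accounting over", x$n_samples, "samples\n")
  cat(sprintf("  raw    %s\n", format(x$total_raw, big.mark = ",")))
  cat(sprintf("  clean  %s (%.1f%%)\n", format(x$total_clean, big.mark = ","), x$pct_clean))
  cat(sprintf("  mapped %s (mean mapping ratio %.1f%%)\n",
              format(x$total_mapped, big.mark = ","), x$mean_ratio))
  cat(sprintf("  raw reads per sample: %.1f-%.1f million\n",
              x$min_raw_millions, x$max_raw_millions))
  invisible(x)
}

#' Assembly-level contig statistics
#'
#' Computes the standard descriptive statistics of a transcriptome assembly
#' from its contig lengths: contig count, min/max/mean/median length and N50.
#' N50 is the largest length `L` such that contigs of length at least `L`
#' jointly cover at least half of the total assembled bases (descending
#' cumulative sum crossing total/2).
#'
#' @param lengths integer vector of contig lengths in bp (all >= 1).
#' @param digits decimals used when rounding the mean length (default 0,
#'   half-up, as assembly tables print whole bp).
#' @return A list of class `assembly_stats`: `n_contigs`, `max_len`,
#'   `min_len`, `mean_len`, `median_len`, `n50`, `total_len`.
#' @examples
#' assembly_stats(c(2, 3, 4, 5, 6))$n50  # 5
#' @export
assembly_stats <- function(lengths, digits = 0) {
  if (length(lengths) == 0L) stop("empty length list", call. = FALSE)
  if (!is.numeric(lengths)) stop("lengths must be numeric", call. = FALSE)
  if (anyNA(lengths) || any(lengths < 1)) {
    stop("contig lengths must be positive", call. = FALSE)
  }
  dec <- sort(lengths, decreasing = TRUE)
  total <- sum(dec)
  n50 <- dec[which(cumsum(dec) >= total / 2)[1L]]
  out <- list(
    n_contigs = length(lengths),
    max_len = max(lengths),
    min_len = min(lengths),
    mean_len = round_half_up(mean(lengths), digits),
    median_len = stats::median(lengths),
    n50 = n50,
    total_len = total
  )
  class(out) <- "assembly_stats"
  out
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly of", format(x$n_contigs, big.mark = ","), "contigs,",
      format(x$total_len, big.mark = ","), "bp total\n")
  cat(sprintf("  length range %s-%s bp, mean %s, median %s, N50 %s\n",
              format(x$min_len, big.mark = ","), format(x$max_len, big.mark = ","),
              format(x$mean_len, big.mark = ","), format(x$median_len, big.mark = ","),
              format(x$n50, big.mark = ",")))
  invisible(x)
}

#' Bundled per-sample read-accounting table
#'
#' Per-sample raw, cleaned and mapped read counts for the 16 muscle RNA-seq
#' libraries (two treatments, estradiol vs vehicle control, at 24 h and 72 h
#' post-injection, four replicates each) of a published rainbow trout
#' estradiol exposure experiment. Used as a worked input for
#' [summarize_mapping()].
#'
#' @return data frame with columns `sample_id`, `group`, `time_h`,
#'   `replicate`, `raw_reads`, `clean_reads`, `mapped_reads`.
#' @export
trout_read_stats <- function() {
  path <- system.file("extdata", "trout_e2_read_stats.tsv", package = "lncnet",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
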
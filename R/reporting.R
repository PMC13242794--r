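# Summary statistics and the per-read trim log.

#' Run statistics
#'
#' Counters of read/pair fates accumulated by [run_paired()] /
#' [run_single()]. For paired mode the four fates (`both_surviving`,
#' `fwd_only`, `rev_only`, `dropped`) partition the input pairs exactly;
#' for single-end mode `surviving` and `dropped` partition the reads.
#'
#' @param mode `"PE"` or `"SE"`.
#' @param input Number of input pairs (PE) or reads (SE).
#' @param both_surviving,fwd_only,rev_only Pair-fate counts (PE).
#' @param surviving Surviving read count (SE).
#' @param dropped Dropped pair/read count.
#' @return A `run_stats` object.
#' @export
run_stats <- function(mode = c("PE", "SE"), input = 0L,
                      both_surviving = 0L, fwd_only = 0L, rev_only = 0L,
                      surviving = 0L, dropped = 0L) {
  mode <- match.arg(mode)
  s <- if (mode == "PE")
    list(mode = mode, input = input, both_surviving = both_surviving,
         fwd_only = fwd_only, rev_only = rev_only, dropped = dropped)
  else
    list(mode = mode, input = input, surviving = surviving,
         dropped = dropped)
  structure(s, class = "run_stats")
}

check_partition <- function(stats) {
  total <- if (stats$mode == "PE")
    stats$both_surviving + stats$fwd_only + stats$rev_only + stats$dropped
  else stats$surviving + stats$dropped
  if (total != stats$input)
    stop("internal error: fate counts (", total,
         ") do not partition the input (", stats$input, ")")
  invisible(stats)
}

fmt_pct <- function(x, n) {
  if (n == 0) "0.00" else sprintf("%.2f", 100 * x / n)
}

#' Render run statistics as the summary file text
#'
#' One datum per line. Paired mode:
#' `Input Read Pairs`, `Both Surviving`, `Forward Only Surviving`,
#' `Reverse Only Surviving`, `Dropped`; single-end mode: `Input Reads`,
#' `Surviving`, `Dropped`. Percentages are `100*x/N` rounded to two
#' decimals (`0.00` when `N = 0`). The fate counts must partition the
#' input.
#'
#' @param stats A [run_stats()].
#' @return Character vector of summary lines.
#' @examples
#' render_summary(run_stats("PE", 100, 90, 5, 3, dropped = 2))
#' @export
render_summary <- function(stats) {
  check_partition(stats)
  n <- stats$input
  if (stats$mode == "PE") {
    c(paste0("Input Read Pairs: ", n),
      paste0("Both Surviving: ", stats$both_surviving,
             " (", fmt_pct(stats$both_surviving, n), "%)"),
      paste0("Forward Only Surviving: ", stats$fwd_only,
             " (", fmt_pct(stats$fwd_only, n), "%)"),
      paste0("Reverse Only Surviving: ", stats$rev_only,
             " (", fmt_pct(stats$rev_only, n), "%)"),
      paste0("Dropped: ", stats$dropped,
             " (", fmt_pct(stats$dropped, n), "%)"))
  } else {
    c(paste0("Input Reads: ", n),
      paste0("Surviving: ", stats$surviving,
             " (", fmt_pct(stats$surviving, n), "%)"),
      paste0("Dropped: ", stats$dropped,
             " (", fmt_pct(stats$dropped, n), "%)"))
  }
}

#' @export
print.run_stats <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}

#' Render one trim-log line
#'
#' Space-separated fields: read name, surviving length, first kept
#' offset (0-based), last kept position (exclusive), bases trimmed from
#' the 3' end. A dropped read logs `name 0 0 0 L` with `L` the original
#' length.
#'
#' @param read_name Read identifier.
#' @param start,end Kept range (0-based, half-open) within the original
#'   read, or `NULL`/`NA` start for a dropped read.
#' @param original_length Length before trimming.
#' @return One log line.
#' @examples
#' render_trimlog_line("r1", 10, 80, 100) # kept [10, 80) of 100
#' @export
render_trimlog_line <- function(read_name, start, end, original_length) {
  if (is.null(start) || is.na(start))
    return(paste(read_name, 0L, 0L, 0L, original_length))
  paste(read_name, end - start, start, end, original_length - end)
}
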
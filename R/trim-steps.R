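# Per-read trimming and filtering operators.
#
# Each operator is defined on the keep-interval level: an internal iv_*
# function maps (bases, quals) to the kept 0-based half-open range
# c(start, end) of the current read, or NULL when the read is dropped.
# The exported step_* wrappers package that range into a step_outcome;
# the engine composes the intervals directly. Every surviving output is
# therefore a contiguous substring of the input with qualities trimmed
# in lockstep, and length never increases.
#
# Threshold comparisons are uniformly strict: a read fails when the
# tested quantity is < the threshold. Window means are compared exactly
# as sum(quals) < q * w, so no floating-point drift can flip a boundary.

iv_headcrop <- function(bases, quals, n) {
  len <- length(quals)
  if (len <= n) return(NULL)
  c(n, len)
}

iv_tailcrop <- function(bases, quals, n) {
  len <- length(quals)
  if (len <= n) return(NULL)
  c(0L, len - n)
}

iv_crop <- function(bases, quals, n) {
  len <- length(quals)
  c(0L, min(n, len))
}

iv_leading <- function(bases, quals, q) {
  keep <- which(quals >= q)
  if (!length(keep)) return(NULL)
  c(keep[1L] - 1L, length(quals))
}

iv_trailing <- function(bases, quals, q) {
  keep <- which(quals >= q)
  if (!length(keep)) return(NULL)
  c(0L, keep[length(keep)])
}

iv_sliding_window <- function(bases, quals, w, q) {
  k <- .sliding_window_keep(quals, w, q)
  if (k == 0L) return(NULL)
  c(0L, k)
}

iv_maxinfo <- function(bases, quals, target, strictness) {
  k <- .maxinfo_keep(quals, target, strictness)
  if (k == 0L) return(NULL)
  c(0L, k)
}

iv_avgqual <- function(bases, quals, q) {
  len <- length(quals)
  if (len == 0L || sum(quals) < q * len) return(NULL)
  c(0L, len)
}

iv_minlen <- function(bases, quals, n) {
  len <- length(quals)
  if (len < n) return(NULL)
  c(0L, len)
}

# Wrap an interval into the user-facing outcome structure.
outcome_from_iv <- function(read, iv) {
  if (!is.null(iv)) iv <- as.integer(iv)
  len <- length(read$quals)
  if (is.null(iv))
    return(structure(list(read = NULL, dropped = TRUE,
                          cut_from_start = 0L, cut_from_end = len,
                          original_length = len),
                     class = "step_outcome"))
  structure(list(read = keep_slice(read, iv[1L], iv[2L]), dropped = FALSE,
                 cut_from_start = iv[1L], cut_from_end = len - iv[2L],
                 original_length = len),
            class = "step_outcome")
}

#' @export
print.step_outcome <- function(x, ...) {
  if (x$dropped) {
    cat("<step_outcome> dropped (was ", x$original_length, " bp)\n", sep = "")
  } else {
    cat("<step_outcome> kept ", length(x$read), "/", x$original_length,
        " bp (cut ", x$cut_from_start, " from 5', ",
        x$cut_from_end, " from 3')\n", sep = "")
  }
  invisible(x)
}

#' Trimming and filtering steps
#'
#' The per-read operators behind the step tokens. Each takes a read and
#' returns a `step_outcome` holding either the trimmed read (always a
#' contiguous substring of the input, bases and qualities in lockstep)
#' or a dropped marker, plus the number of bases cut from each end.
#'
#' * `step_headcrop()` / `step_tailcrop()` — remove a fixed number of
#'   bases from the 5' / 3' end (UMI and barcode removal); a read no
#'   longer than `n` is dropped.
#' * `step_crop()` — keep at most the first `n` bases; never drops.
#' * `step_leading()` / `step_trailing()` — strip bases below quality `q`
#'   from the 5' / 3' end.
#' * `step_sliding_window()` — scan windows of width `w` 5' to 3'; at
#'   the first window whose mean quality is below `q` the read is cut
#'   before that window, then any remaining trailing bases below `q`
#'   are removed. A read shorter than `w` is one window.
#' * `step_maxinfo()` — keep the prefix maximizing an information score
#'   balancing length against accumulated error risk (see
#'   [maxinfo_score()]); ties go to the longer prefix.
#' * `step_avgqual()` — drop the whole read when its mean quality is
#'   below `q`; never trims.
#' * `step_minlen()` — drop reads shorter than `n` (the MINLEN and
#'   BASECOUNT tokens; BASECOUNT enforces a post-trimming length floor).
#'
#' All comparisons are strict: a read fails when the quantity is `< `
#' the threshold, so a mean exactly at `q` or a length exactly `n`
#' survives.
#'
#' @param read An [fq_read()].
#' @param n Base count (>= 0).
#' @param q Integer PHRED quality threshold.
#' @param w Window width (>= 1).
#' @param target_length MAXINFO target read length (>= 1).
#' @param strictness MAXINFO strictness in (0, 1); larger values weight
#'   error avoidance over read length.
#' @return A `step_outcome`.
#' @examples
#' r <- fq_read("r", "ACGTACGT", c(30, 30, 30, 30, 10, 10, 10, 10))
#' step_sliding_window(r, 4, 20)
#' step_minlen(r, 36)
#' @name trim_steps
NULL

#' @rdname trim_steps
#' @export
step_headcrop <- function(read, n)
  outcome_from_iv(read, iv_headcrop(read$bases, read$quals, n))

#' @rdname trim_steps
#' @export
step_tailcrop <- function(read, n)
  outcome_from_iv(read, iv_tailcrop(read$bases, read$quals, n))

#' @rdname trim_steps
#' @export
step_crop <- function(read, n)
  outcome_from_iv(read, iv_crop(read$bases, read$quals, n))

#' @rdname trim_steps
#' @export
step_leading <- function(read, q)
  outcome_from_iv(read, iv_leading(read$bases, read$quals, q))

#' @rdname trim_steps
#' @export
step_trailing <- function(read, q)
  outcome_from_iv(read, iv_trailing(read$bases, read$quals, q))

#' @rdname trim_steps
#' @export
step_sliding_window <- function(read, w, q)
  outcome_from_iv(read, iv_sliding_window(read$bases, read$quals, w, q))

#' @rdname trim_steps
#' @export
step_maxinfo <- function(read, target_length, strictness)
  outcome_from_iv(read, iv_maxinfo(read$bases, read$quals,
                                   target_length, strictness))

#' @rdname trim_steps
#' @export
step_avgqual <- function(read, q)
  outcome_from_iv(read, iv_avgqual(read$bases, read$quals, q))

#' @rdname trim_steps
#' @export
step_minlen <- function(read, n)
  outcome_from_iv(read, iv_minlen(read$bases, read$quals, n))

#' MAXINFO prefix score
#'
#' The objective maximized by [step_maxinfo()]. For a prefix of length
#' `L` of a read with PHRED scores `q_i` the score is the sum of three
#' terms: a logistic length factor `ln(1 / (1 + exp(T - 1 - L)))`
#' saturating near the target length `T`; a coverage factor
#' `(1 - s) * ln(L)` (`-Inf` at `L = 0`) rewarding additional bases with
#' diminishing returns; and a correctness factor
#' `s * sum_{i<L} ln(1 - 10^(-q_i/10))` penalizing accumulated error
#' risk (a score of 0 is treated as 1 to keep the logarithm finite).
#' The strictness `s` in (0, 1) shifts weight between the last two.
#'
#' @param quals Integer vector of PHRED scores.
#' @param prefix_length Prefix length `L` in `0..length(quals)`.
#' @inheritParams trim_steps
#' @return The score, `-Inf` at `L = 0`.
#' @export
maxinfo_score <- function(quals, prefix_length, target_length, strictness) {
  L <- prefix_length
  stopifnot(L >= 0, L <= length(quals))
  if (L == 0L) return(-Inf)
  x <- target_length - 1 - L
  flen <- if (x > 35) -x else -log1p(exp(x))
  q <- pmax(quals[seq_len(L)], 1L)
  flen + (1 - strictness) * log(L) +
    strictness * sum(log(1 - 10^(-q / 10)))
}
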
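# ILLUMINACLIP: adapter detection and removal, in simple mode (adapter
# aligned against a single read) and palindrome mode (read-through
# detected by aligning the forward read against the reverse complement
# of the reverse read, both 5'-extended with their ligated adapter
# prefixes).

#' Clipping parameters for ILLUMINACLIP
#'
#' @param seed_mismatches Maximum mismatches tolerated in the 16-base
#'   alignment seed.
#' @param palindrome_threshold Minimum alignment score for a palindrome
#'   (read-through) hit; 30 corresponds to roughly 50 perfectly matching
#'   bases at a log10(4) match bonus.
#' @param simple_threshold Minimum alignment score for a simple-mode
#'   hit; 10 corresponds to roughly 17 perfect matches.
#' @param min_adapter_length Shortest 3'-overlap considered in simple
#'   mode (shorter overlaps are only examined while a perfect match
#'   could still reach the threshold).
#' @param keep_both_reads In palindrome mode the reverse mate of a
#'   clipped pair carries no extra information; keep it anyway?
#' @return A `clip_params` list.
#' @export
clip_params <- function(seed_mismatches = 2L, palindrome_threshold = 30,
                        simple_threshold = 10, min_adapter_length = 8L,
                        keep_both_reads = FALSE) {
  stopifnot(seed_mismatches >= 0, palindrome_threshold >= 0,
            simple_threshold >= 0, min_adapter_length >= 1)
  structure(list(seed_mismatches = as.integer(seed_mismatches),
                 palindrome_threshold = as.numeric(palindrome_threshold),
                 simple_threshold = as.numeric(simple_threshold),
                 min_adapter_length = as.integer(min_adapter_length),
                 keep_both_reads = isTRUE(keep_both_reads)),
            class = "clip_params")
}

#' Load an adapter FASTA into palindrome pairs and simple adapters
#'
#' Records whose names end in `/1` and `/2` with a common stem form a
#' palindrome pair (the 5' adapter prefixes ligated to the forward and
#' reverse read, respectively); every other record is used as a simple
#' adapter. A `/1` or `/2` record without its mate falls back to simple
#' mode with a warning.
#'
#' @param path Adapter FASTA file.
#' @return An `adapter_set`: list with `palindrome` (data frame of
#'   `stem`, `fwd`, `rev`) and `simple` (data frame of `name`,
#'   `sequence`).
#' @export
load_adapters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs))
    stop("adapter FASTA '", path, "' contains no sequences")
  nm <- names(seqs)
  sq <- toupper(as.character(seqs))
  is1 <- endsWith(nm, "/1")
  is2 <- endsWith(nm, "/2")
  stem <- sub("/[12]$", "", nm)
  pal_stems <- intersect(stem[is1], stem[is2])
  orphan <- (is1 | is2) & !(stem %in% pal_stems)
  if (any(orphan))
    warning("adapter record(s) ", paste(nm[orphan], collapse = ", "),
            " lack a palindrome mate; used in simple mode")
  palindrome <- data.frame(
    stem = pal_stems,
    fwd = sq[is1][match(pal_stems, stem[is1])],
    rev = sq[is2][match(pal_stems, stem[is2])],
    stringsAsFactors = FALSE)
  simple_idx <- which(!(is1 | is2) | orphan)
  simple <- data.frame(name = nm[simple_idx], sequence = sq[simple_idx],
                       stringsAsFactors = FALSE)
  structure(list(palindrome = palindrome, simple = simple),
            class = "adapter_set")
}

#' @export
print.adapter_set <- function(x, ...) {
  cat("<adapter_set> ", nrow(x$palindrome), " palindrome pair(s), ",
      nrow(x$simple), " simple adapter(s)\n", sep = "")
  invisible(x)
}

#' Score a gap-free alignment window
#'
#' Each matching column (case-insensitive; `N` matches nothing) adds
#' `log10(4)` (~0.602), each mismatching column subtracts `q/10` where
#' `q` is the read base's PHRED score. Under this scale the customary
#' simple threshold 10 needs ~17 perfect matches and the palindrome
#' threshold 30 needs ~50.
#'
#' @param read_bases,adapter_bases Equal-length base strings.
#' @param read_quals Integer PHRED scores for `read_bases`.
#' @return The alignment score.
#' @examples
#' alignment_score(strrep("A", 17), rep(30L, 17), strrep("A", 17)) # >= 10
#' @export
alignment_score <- function(read_bases, read_quals, adapter_bases) {
  .alignment_score(read_bases, as.integer(read_quals), adapter_bases)
}

# Earliest qualifying clip offset over a set of simple adapters; -1 when
# no adapter aligns above threshold.
simple_clip_offset_set <- function(bases, quals, adapters, params) {
  best <- -1L
  for (a in adapters) {
    o <- .simple_clip_offset(bases, quals, a, params$seed_mismatches,
                             params$simple_threshold,
                             params$min_adapter_length)
    if (o >= 0L && (best < 0L || o < best)) best <- o
  }
  best
}

iv_simple_clip <- function(bases, quals, adapters, params) {
  o <- simple_clip_offset_set(bases, quals, adapters, params)
  if (o < 0L) return(c(0L, length(quals)))
  if (o == 0L) return(NULL)
  c(0L, o)
}

#' Clip a single adapter from one read (simple mode)
#'
#' Scans every alignment offset of the adapter start within the read,
#' 5' to 3', including partial 3' overlaps. A candidate must pass the
#' seed test (at most `seed_mismatches` mismatches in the first
#' `min(16, overlap)` adapter bases) and reach `simple_threshold` with
#' its full-overlap [alignment_score()]. The read is truncated before
#' the earliest qualifying offset; an adapter found at offset 0 drops
#' the read.
#'
#' @param read An [fq_read()].
#' @param adapter Adapter sequence (character) or an `adapter_set`, in
#'   which case all simple adapters are scanned and the earliest clip
#'   wins.
#' @param params A [clip_params()].
#' @return A `step_outcome`.
#' @export
simple_clip <- function(read, adapter, params = clip_params()) {
  adapters <- if (inherits(adapter, "adapter_set")) adapter$simple$sequence
              else as.character(adapter)
  outcome_from_iv(read, iv_simple_clip(read$bases, read$quals,
                                       adapters, params))
}

#' Detect and clip adapter read-through across a pair (palindrome mode)
#'
#' Each mate is conceptually extended 5' with its ligated adapter prefix
#' and the extended forward read is aligned against the reverse
#' complement of the extended reverse read at every implied fragment
#' length below the read length. Candidates pass a 16-base seed test and
#' a full-overlap score against `palindrome_threshold`; the best score
#' wins (ties to the shortest fragment). On a hit both mates are
#' truncated to the fragment length; unless `keep_both_reads`, the
#' reverse mate (whose sequence is then wholly redundant with the
#' forward mate) is dropped.
#'
#' @param fwd,rev The two mates as [fq_read()].
#' @param adapters An `adapter_set` with at least one palindrome pair,
#'   or a list/vector of two prefix sequences `(fwd, rev)`.
#' @param params A [clip_params()].
#' @return List with `fwd` and `rev` `step_outcome`s and the detected
#'   `fragment_length` (`NA` when no read-through was found).
#' @export
palindrome_clip <- function(fwd, rev, adapters, params = clip_params()) {
  if (inherits(adapters, "adapter_set")) pal <- adapters$palindrome
  else pal <- data.frame(fwd = adapters[[1L]], rev = adapters[[2L]])
  L <- palindrome_fragment_set(fwd$bases, fwd$quals, rev$bases, rev$quals,
                               pal, params)
  n1 <- length(fwd$quals)
  n2 <- length(rev$quals)
  if (L < 0L)
    return(list(fwd = outcome_from_iv(fwd, c(0L, n1)),
                rev = outcome_from_iv(rev, c(0L, n2)),
                fragment_length = NA_integer_))
  list(fwd = outcome_from_iv(fwd, c(0L, min(L, n1))),
       rev = if (params$keep_both_reads)
               outcome_from_iv(rev, c(0L, min(L, n2)))
             else outcome_from_iv(rev, NULL),
       fragment_length = L)
}

# Best (shortest on ties) qualifying fragment length over all palindrome
# pairs; -1 when none qualifies.
palindrome_fragment_set <- function(b1, q1, b2, q2, pal, params) {
  best <- -1L
  for (i in seq_len(nrow(pal))) {
    L <- .palindrome_fragment(b1, as.integer(q1), b2, as.integer(q2),
                              pal$fwd[i], pal$rev[i],
                              params$seed_mismatches,
                              params$palindrome_threshold)
    if (L >= 0L && (best < 0L || L < best)) best <- L
  }
  best
}

#' Count reads still carrying an adapter prefix
#'
#' Searches each read (or each record of a FASTQ file) for the first
#' `k` bases of an adapter as an exact substring -- the usual
#' residual-contamination metric after clipping.
#'
#' @param x List of [fq_read()], an internal batch, or a FASTQ path.
#' @param adapter Adapter sequence.
#' @param k Prefix length searched (default 12).
#' @return Number of reads containing the adapter `k`-mer prefix.
#' @export
residual_adapter_count <- function(x, adapter, k = 12L) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- read_fastq(x)
  bases <- if (inherits(x, "fq_batch")) x$bases
           else vapply(x, `[[`, "", "bases")
  kmer <- toupper(substr(adapter, 1L, k))
  sum(grepl(kmer, toupper(bases), fixed = TRUE))
}

# Reverse complement (delegates to Biostrings; N stays N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
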
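#' Construct a sequencing read
#'
#' A read couples a FASTQ identifier (header without the leading `"@"`),
#' a base string and the per-base integer PHRED scores. Bases and scores
#' always have equal length; trimming only ever returns contiguous
#' sub-ranges of both, in lockstep.
#'
#' @param name Character scalar identifier.
#' @param bases Character scalar over `A`, `C`, `G`, `T`, `N`
#'   (case preserved; quality logic never inspects bases).
#' @param quals Integer vector of PHRED scores in `[0, 93]`, one per base.
#' @return An object of class `fq_read`.
#' @examples
#' fq_read("r1", "ACGT", c(40L, 40L, 30L, 2L))
#' @export
fq_read <- function(name, bases, quals) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(bases), length(bases) == 1L)
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals))
    stop("read '", name, "': bases and quality scores differ in length")
  if (length(quals) && (min(quals) < 0L || max(quals) > 93L))
    stop("read '", name, "': PHRED scores must lie in [0, 93]")
  structure(list(name = name, bases = bases, quals = quals),
            class = "fq_read")
}

#' @export
print.fq_read <- function(x, ...) {
  cat("<fq_read> ", x$name, " (", nchar(x$bases), " bp)\n", sep = "")
  cat("  ", x$bases, "\n", sep = "")
  cat("  Q: ", paste(x$quals, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
length.fq_read <- function(x) nchar(x$bases)

# Keep the 0-based half-open range [start, end) of a read.
keep_slice <- function(read, start, end) {
  fq_read(read$name,
          substr(read$bases, start + 1L, end),
          read$quals[seq_len(end - start) + start])
}

#' Decode a FASTQ quality string into PHRED scores
#'
#' @param qual_text ASCII quality string.
#' @param offset Encoding offset, 33 (Phred33) or 64 (Phred64).
#' @param record Optional record name used in error messages.
#' @return Integer vector of scores, `code(char) - offset`.
#' @examples
#' decode_quality("IIII", 33) # 40 40 40 40
#' decode_quality("h", 64)    # 40
#' @export
decode_quality <- function(qual_text, offset = 33L, record = "<unnamed>") {
  codes <- utf8ToInt(qual_text)
  if (length(codes) && min(codes) < offset)
    stop("record '", record, "': quality character below PHRED offset ",
         offset, " (malformed input or wrong encoding)")
  as.integer(codes - offset)
}

# Inverse of decode_quality.
encode_quality <- function(quals, offset = 33L) {
  if (!length(quals)) return("")
  intToUtf8(quals + offset)
}

#' Detect the PHRED quality encoding of a set of quality lines
#'
#' Scans up to `sample_limit` quality strings and inspects the range of
#' ASCII codes: a code below 64 forces Phred33; a minimum of at least 64
#' together with a maximum above 74 forces Phred64. Codes confined to
#' 64..74 are compatible with both encodings, and guessing silently is
#' exactly the kind of hard-to-diagnose error automatic detection exists
#' to prevent, so that case is an error: pass `-phred33`/`-phred64`
#' explicitly.
#'
#' @param quality_lines Character vector of raw FASTQ quality strings.
#' @param sample_limit Maximum number of lines inspected (default 10000).
#' @return The detected offset, `33L` or `64L`.
#' @export
detect_encoding <- function(quality_lines, sample_limit = 10000L) {
  quality_lines <- head(quality_lines, sample_limit)
  quality_lines <- quality_lines[nzchar(quality_lines)]
  if (!length(quality_lines))
    stop("cannot detect PHRED encoding: no quality data found")
  codes <- utf8ToInt(paste(quality_lines, collapse = ""))
  m <- min(codes)
  M <- max(codes)
  if (m < 64L) return(33L)
  if (M > 74L) return(64L)
  stop("ambiguous PHRED encoding (all quality codes in 64..74); ",
       "specify -phred33 or -phred64 explicitly")
}

# Detect encoding from the head of a FASTQ file.
detect_encoding_file <- function(path, sample_limit = 10000L) {
  con <- open_fastq_connection(path)
  on.exit(close(con))
  lines <- readLines(con, n = 4L * sample_limit)
  if (length(lines) < 4L)
    stop("cannot detect PHRED encoding: '", path, "' holds no complete record")
  detect_encoding(lines[seq(4L, length(lines) - length(lines) %% 4L, by = 4L)],
                  sample_limit)
}
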
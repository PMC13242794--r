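# FASTQ reading/writing with transparent compression, block-parallel
# multi-member GZIP output, template-based output naming, and pre-run
# pairing validation.

# Connection chosen by suffix: .gz -> GZIP, .bz2 -> BZIP2, else plain.
open_fastq_connection <- function(path, mode = "rt") {
  if (!grepl("^r", mode) || file.exists(path)) {
    # ok
  } else stop("input file not found: '", path, "'")
  if (endsWith(path, ".gz")) gzfile(path, mode)
  else if (endsWith(path, ".bz2")) bzfile(path, mode)
  else file(path, mode)
}

# A batch of records stored column-wise: parallel character vectors of
# names (without "@"), bases, and raw quality strings.
fq_batch <- function(name = character(), bases = character(),
                     qual = character()) {
  structure(list(name = name, bases = bases, qual = qual),
            class = "fq_batch")
}

#' @export
length.fq_batch <- function(x) length(x$name)

# Parse 4*k raw lines into a batch. `first_ordinal` is the 0-based index
# of the first record, used in error messages.
parse_fastq_lines <- function(lines, first_ordinal = 0L, path = "<stream>") {
  n <- length(lines)
  if (n == 0L) return(fq_batch())
  if (n %% 4L != 0L)
    stop("'", path, "': truncated FASTQ record at record ",
         first_ordinal + n %/% 4L, " (end of file inside a record)")
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("'", path, "': record ", first_ordinal + bad[1L] - 1L,
         " does not start with '@'")
  plus <- lines[idx + 2L]
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("'", path, "': record ", first_ordinal + bad[1L] - 1L,
         " lacks the '+' separator line")
  bases <- lines[idx + 1L]
  qual <- lines[idx + 3L]
  bad <- which(nchar(bases) != nchar(qual))
  if (length(bad))
    stop("'", path, "': record ", first_ordinal + bad[1L] - 1L, " ('",
         sub("^@", "", hdr[bad[1L]]),
         "') has mismatched sequence and quality lengths")
  fq_batch(sub("^@", "", hdr), bases, qual)
}

# Streaming reader: an environment with $next_batch(n) -> fq_batch
# (0-length at EOF) and $close().
fq_reader <- function(path) {
  con <- open_fastq_connection(path)
  ordinal <- 0L
  list(
    next_batch = function(n) {
      lines <- readLines(con, n = 4L * n)
      b <- parse_fastq_lines(lines, ordinal, path)
      ordinal <<- ordinal + length(b)
      b
    },
    close = function() close(con),
    path = path
  )
}

#' Read a FASTQ file
#'
#' Reads a complete (optionally GZIP- or BZIP2-compressed, by suffix)
#' FASTQ file into a list of [fq_read()] objects. The quality encoding
#' is auto-detected from the first records unless given. Malformed
#' records (truncated file, missing `@`/`+` lines, sequence/quality
#' length mismatch) raise an error naming the record ordinal. Text after
#' `+` on the separator line is accepted and discarded.
#'
#' @param path FASTQ file path (`.gz`, `.bz2`, or plain).
#' @param encoding `"auto"`, `33`, or `64`.
#' @param sample_limit Records inspected for auto-detection.
#' @return List of `fq_read`, with the offset used in
#'   `attr(, "offset")`.
#' @export
read_fastq <- function(path, encoding = "auto", sample_limit = 10000L) {
  offset <- resolve_encoding(path, encoding, sample_limit)
  r <- fq_reader(path)
  on.exit(r$close())
  out <- list()
  repeat {
    b <- r$next_batch(100000L)
    if (!length(b)) break
    out <- c(out, lapply(seq_along(b$name), function(i)
      fq_read(b$name[i], b$bases[i],
              decode_quality(b$qual[i], offset, b$name[i]))))
  }
  attr(out, "offset") <- offset
  out
}

resolve_encoding <- function(path, encoding, sample_limit = 10000L) {
  if (identical(encoding, "auto")) detect_encoding_file(path, sample_limit)
  else if (as.integer(encoding) %in% c(33L, 64L)) as.integer(encoding)
  else stop("encoding must be \"auto\", 33 or 64")
}

# Serialize a batch (or list of fq_read) into FASTQ lines.
serialize_fastq <- function(x, offset = 33L) {
  if (inherits(x, "fq_batch")) {
    if (!length(x)) return(character())
    as.vector(rbind(paste0("@", x$name), x$bases, "+", x$qual))
  } else {
    if (!length(x)) return(character())
    as.vector(rbind(paste0("@", vapply(x, `[[`, "", "name")),
                    vapply(x, `[[`, "", "bases"),
                    "+",
                    vapply(x, function(r) encode_quality(r$quals, offset), "")))
  }
}

# ---- block-parallel GZIP writer ---------------------------------------------

# Writer object with $write(lines, n_records) and $close(). For .gz
# paths the output is a multi-member GZIP stream: every block_records
# records are serialized and compressed as one complete member (fresh
# dictionary), members written strictly in input order. Standard
# decompressors concatenate members, so `gunzip` yields bytes identical
# to the plain serial serialization. Pending members are compressed
# `workers` at a time via forked workers when workers > 1; the bytes do
# not depend on the worker count.
fq_writer <- function(path, workers = 1L, block_records = 10000L,
                      gzip_blocks = endsWith(path, ".gz")) {
  if (gzip_blocks && !endsWith(path, ".gz"))
    stop("block-parallel output requires a .gz path")
  if (gzip_blocks) {
    con <- file(path, "wb")
    buf <- character()
    nrec <- 0L
    pending <- list()
    wrote_member <- FALSE
    flush_pending <- function(all = FALSE) {
      if (!length(pending)) return(invisible())
      if (length(pending) >= workers || all) {
        members <- if (workers > 1L && length(pending) > 1L)
          parallel::mclapply(pending, .gzip_compress_member,
                             mc.cores = workers)
        else lapply(pending, .gzip_compress_member)
        for (m in members) writeBin(m, con)
        wrote_member <<- TRUE
        pending <<- list()
      }
      invisible()
    }
    cut_blocks <- function() {
      while (nrec >= block_records) {
        take <- 4L * block_records
        block <- buf[seq_len(take)]
        buf <<- buf[-seq_len(take)]
        nrec <<- nrec - block_records
        pending[[length(pending) + 1L]] <<-
          charToRaw(paste0(paste(block, collapse = "\n"), "\n"))
        flush_pending()
      }
    }
    list(
      write = function(lines, n_records = length(lines) %/% 4L) {
        if (!length(lines)) return(invisible())
        buf <<- c(buf, lines)
        nrec <<- nrec + n_records
        cut_blocks()
        invisible()
      },
      close = function() {
        if (nrec > 0L) {
          pending[[length(pending) + 1L]] <<-
            charToRaw(paste0(paste(buf, collapse = "\n"), "\n"))
        } else if (!wrote_member && !length(pending)) {
          pending[[1L]] <<- raw(0)  # empty stream: one empty member
        }
        flush_pending(all = TRUE)
        close(con)
        invisible()
      },
      path = path
    )
  } else {
    con <- if (endsWith(path, ".bz2")) bzfile(path, "wt") else file(path, "wt")
    list(
      write = function(lines, n_records = NULL) {
        if (length(lines)) writeLines(lines, con)
        invisible()
      },
      close = function() { close(con); invisible() },
      path = path
    )
  }
}

#' Write reads to a FASTQ file
#'
#' Serializes reads in order (bare `+` separator line) and writes them
#' plain, BZIP2 (`.bz2` suffix) or GZIP (`.gz` suffix) compressed. For
#' GZIP, `mode = "serial"` writes one single-member stream and
#' `mode = "parallel_blocks"` writes a multi-member stream with one
#' independently compressed member (dictionary reset) per
#' `block_records` records; both decompress to identical bytes, and the
#' multi-member bytes are identical for every worker count.
#'
#' @param reads List of [fq_read()] or an internal batch.
#' @param path Output path.
#' @param mode `"serial"` or `"parallel_blocks"` (the latter requires a
#'   `.gz` path).
#' @param workers Compression workers for `parallel_blocks`.
#' @param block_records Records per compressed member.
#' @param offset PHRED offset used to encode qualities.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, mode = c("serial", "parallel_blocks"),
                        workers = 1L, block_records = 10000L, offset = 33L) {
  mode <- match.arg(mode)
  lines <- serialize_fastq(reads, offset)
  nrec <- length(lines) %/% 4L
  if (mode == "parallel_blocks") {
    if (!endsWith(path, ".gz"))
      stop("parallel_blocks mode requires a .gz output path")
    w <- fq_writer(path, workers = workers, block_records = block_records)
    w$write(lines, nrec)
    w$close()
  } else {
    con <- if (endsWith(path, ".gz")) gzfile(path, "wt")
           else if (endsWith(path, ".bz2")) bzfile(path, "wt")
           else file(path, "wt")
    if (length(lines)) writeLines(lines, con)
    close(con)
  }
  invisible(path)
}

# ---- template-based file naming ---------------------------------------------

#' Derive the four paired/unpaired output names from a template
#'
#' Inserts `_1P` (forward paired), `_1U` (forward unpaired), `_2P`
#' (reverse paired) and `_2U` (reverse unpaired) before the recognized
#' extension chain (`.fastq`/`.fq`/`.txt`, optionally followed by
#' `.gz`/`.bz2`) of the template.
#'
#' @param baseout Template path, e.g. `"out.fq.gz"`.
#' @return Named list with `fwd_paired`, `fwd_unpaired`, `rev_paired`,
#'   `rev_unpaired`.
#' @examples
#' derive_output_names("out.fq.gz")
#' @export
derive_output_names <- function(baseout) {
  m <- regexpr("(\\.(fastq|fq|txt))?(\\.(gz|bz2))?$", baseout)
  ext <- regmatches(baseout, m)
  base <- substr(baseout, 1L, m - 1L)
  list(fwd_paired   = paste0(base, "_1P", ext),
       fwd_unpaired = paste0(base, "_1U", ext),
       rev_paired   = paste0(base, "_2P", ext),
       rev_unpaired = paste0(base, "_2U", ext))
}

#' Find the mate of a forward input file
#'
#' Given `-basein` naming like `x_1.fq.gz`, tries in turn replacing the
#' last `_1` with `_2`, `_R1` with `_R2`, and `.1.` with `.2.`; the
#' first pattern producing an existing file wins.
#'
#' @param basein Forward (mate 1) input path.
#' @return The mate 2 path.
#' @export
find_mate_path <- function(basein) {
  cands <- c(sub("(.*)_R1", "\\1_R2", basein),
             sub("(.*)_1", "\\1_2", basein),
             sub("(.*)\\.1\\.", "\\1.2.", basein))
  for (cand in cands)
    if (cand != basein && file.exists(cand)) return(cand)
  stop("cannot derive mate file for '", basein,
       "' (tried _R1->_R2, _1->_2, .1.->.2.)")
}

# ---- pairing validation -----------------------------------------------------

canonical_read_names <- function(x) {
  x <- sub("[ \t].*$", "", x)      # first whitespace-delimited token
  sub("/[12]$", "", x)             # strip mate suffix
}

#' Validate that two name streams are synchronized mates
#'
#' Names match when equal after taking the first whitespace-delimited
#' token and stripping a trailing `/1` or `/2`. Reports the first
#' mismatching 0-based ordinal with both names, or an unequal stream
#' length, or OK.
#'
#' @param names_fwd,names_rev Character vectors of read names (FASTQ
#'   headers without `@`).
#' @return A `pairing_report`: list with `ok`, and on failure either
#'   `ordinal`/`fwd_name`/`rev_name` or `length_mismatch = TRUE` with
#'   `n_fwd`/`n_rev`.
#' @examples
#' validate_pairing(c("r1/1", "r2/1"), c("r1/2", "r2/2"))
#' @export
validate_pairing <- function(names_fwd, names_rev) {
  cf <- canonical_read_names(names_fwd)
  cr <- canonical_read_names(names_rev)
  m <- min(length(cf), length(cr))
  if (m > 0L) {
    diff <- which(cf[seq_len(m)] != cr[seq_len(m)])
    if (length(diff)) {
      i <- diff[1L]
      return(structure(list(ok = FALSE, ordinal = i - 1L,
                            fwd_name = names_fwd[i], rev_name = names_rev[i],
                            length_mismatch = FALSE),
                       class = "pairing_report"))
    }
  }
  if (length(cf) != length(cr))
    return(structure(list(ok = FALSE, ordinal = m, length_mismatch = TRUE,
                          n_fwd = length(cf), n_rev = length(cr)),
                     class = "pairing_report"))
  structure(list(ok = TRUE), class = "pairing_report")
}

#' @export
print.pairing_report <- function(x, ...) {
  if (x$ok) cat("pairing OK\n")
  else if (isTRUE(x$length_mismatch))
    cat("pairing FAILED: unequal record counts (forward ", x$n_fwd,
        ", reverse ", x$n_rev, ")\n", sep = "")
  else
    cat("pairing FAILED at record ", x$ordinal, ": '", x$fwd_name,
        "' vs '", x$rev_name, "'\n", sep = "")
  invisible(x)
}

#' Validate pairing of two FASTQ files before processing
#'
#' Streams the read names of both files in parallel and applies
#' [validate_pairing()]; intended as a pre-run integrity check of
#' paired-end inputs.
#'
#' @param path_fwd,path_rev FASTQ file paths.
#' @param batch_size Records read per chunk.
#' @return A `pairing_report`.
#' @export
validate_pairing_files <- function(path_fwd, path_rev, batch_size = 10000L) {
  r1 <- fq_reader(path_fwd)
  r2 <- fq_reader(path_rev)
  on.exit({ r1$close(); r2$close() })
  done <- 0L
  n1 <- 0L; n2 <- 0L
  repeat {
    b1 <- r1$next_batch(batch_size)
    b2 <- r2$next_batch(batch_size)
    n1 <- n1 + length(b1); n2 <- n2 + length(b2)
    if (!length(b1) && !length(b2)) break
    m <- min(length(b1), length(b2))
    rep <- validate_pairing(b1$name[seq_len(m)], b2$name[seq_len(m)])
    if (!rep$ok) {
      rep$ordinal <- rep$ordinal + done
      return(rep)
    }
    if (length(b1) != length(b2)) {
      # one file ended (or chunked short) - drain both to count records
      while (length(b <- r1$next_batch(batch_size))) n1 <- n1 + length(b)
      while (length(b <- r2$next_batch(batch_size))) n2 <- n2 + length(b)
      break
    }
    done <- done + m
  }
  if (n1 != n2)
    return(structure(list(ok = FALSE, ordinal = min(n1, n2),
                          length_mismatch = TRUE, n_fwd = n1, n_rev = n2),
                     class = "pairing_report"))
  structure(list(ok = TRUE), class = "pairing_report")
}
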
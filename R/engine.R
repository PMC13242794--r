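# Pipeline engine: applies an ordered step list to read/pair streams
# with paired fate bookkeeping, batched (optionally forked) execution,
# and strict output-order preservation.
#
# Concurrency contract: every step is a pure function of its read
# (pair), so for fixed inputs and steps all outputs are byte-identical
# (after decompression) for every worker count. Workers only ever
# process whole batches whose results are written back in ordinal
# order.

# Compile parsed step specs into executable form. ILLUMINACLIP loads its
# adapter FASTA here, i.e. before any read data is processed.
compile_steps <- function(steps) {
  lapply(parse_steps(steps), function(sp) {
    a <- sp$args
    switch(sp$step_name,
      ILLUMINACLIP = list(
        kind = "clip",
        aset = load_adapters(a$fasta),
        params = clip_params(a$seed_mismatches, a$palindrome_threshold,
                             a$simple_threshold, a$min_adapter_length,
                             a$keep_both_reads)),
      SLIDINGWINDOW = list(kind = "iv", fn = function(b, q)
        iv_sliding_window(b, q, a$window, a$quality)),
      MAXINFO = list(kind = "iv", fn = function(b, q)
        iv_maxinfo(b, q, a$target_length, a$strictness)),
      LEADING = list(kind = "iv", fn = function(b, q)
        iv_leading(b, q, a$quality)),
      TRAILING = list(kind = "iv", fn = function(b, q)
        iv_trailing(b, q, a$quality)),
      CROP = list(kind = "iv", fn = function(b, q)
        iv_crop(b, q, a$length)),
      HEADCROP = list(kind = "iv", fn = function(b, q)
        iv_headcrop(b, q, a$length)),
      TAILCROP = list(kind = "iv", fn = function(b, q)
        iv_tailcrop(b, q, a$length)),
      MINLEN = list(kind = "iv", fn = function(b, q)
        iv_minlen(b, q, a$length)),
      BASECOUNT = list(kind = "iv", fn = function(b, q)
        iv_minlen(b, q, a$length)),
      AVGQUAL = list(kind = "iv", fn = function(b, q)
        iv_avgqual(b, q, a$quality)),
      stop("unhandled step ", sp$step_name))
  })
}

# Apply the compiled steps to one pair (or a single read when bs2 is
# NULL). Returns alive flags, trimmed bases/quals, and the absolute kept
# range within each original read. A drop short-circuits the remaining
# steps for that mate.
apply_compiled <- function(bs1, ql1, bs2 = NULL, ql2 = NULL, compiled) {
  a1 <- TRUE
  a2 <- !is.null(bs2)
  paired <- a2
  st1 <- 0L
  st2 <- 0L
  for (st in compiled) {
    if (st$kind == "clip") {
      if (a1 && a2 && nrow(st$aset$palindrome)) {
        L <- palindrome_fragment_set(bs1, ql1, bs2, ql2,
                                     st$aset$palindrome, st$params)
        if (L >= 0L) {
          if (L < length(ql1)) {
            bs1 <- substr(bs1, 1L, L)
            ql1 <- ql1[seq_len(L)]
          }
          if (!st$params$keep_both_reads) {
            a2 <- FALSE
          } else if (L < length(ql2)) {
            bs2 <- substr(bs2, 1L, L)
            ql2 <- ql2[seq_len(L)]
          }
        }
      }
      simple <- st$aset$simple$sequence
      if (length(simple)) {
        if (a1) {
          iv <- iv_simple_clip(bs1, ql1, simple, st$params)
          if (is.null(iv)) a1 <- FALSE
          else if (iv[2L] < length(ql1)) {
            bs1 <- substr(bs1, 1L, iv[2L])
            ql1 <- ql1[seq_len(iv[2L])]
          }
        }
        if (a2) {
          iv <- iv_simple_clip(bs2, ql2, simple, st$params)
          if (is.null(iv)) a2 <- FALSE
          else if (iv[2L] < length(ql2)) {
            bs2 <- substr(bs2, 1L, iv[2L])
            ql2 <- ql2[seq_len(iv[2L])]
          }
        }
      }
    } else {
      if (a1) {
        iv <- st$fn(bs1, ql1)
        if (is.null(iv)) a1 <- FALSE
        else if (iv[1L] > 0L || iv[2L] < length(ql1)) {
          st1 <- st1 + iv[1L]
          bs1 <- substr(bs1, iv[1L] + 1L, iv[2L])
          ql1 <- ql1[seq.int(iv[1L] + 1L, length.out = iv[2L] - iv[1L])]
        }
      }
      if (a2) {
        iv <- st$fn(bs2, ql2)
        if (is.null(iv)) a2 <- FALSE
        else if (iv[1L] > 0L || iv[2L] < length(ql2)) {
          st2 <- st2 + iv[1L]
          bs2 <- substr(bs2, iv[1L] + 1L, iv[2L])
          ql2 <- ql2[seq.int(iv[1L] + 1L, length.out = iv[2L] - iv[1L])]
        }
      }
    }
    if (!a1 && !a2) break
  }
  list(alive1 = a1, bases1 = bs1, quals1 = ql1, start1 = st1,
       alive2 = if (paired) a2 else NA,
       bases2 = bs2, quals2 = ql2, start2 = st2)
}

#' Apply a step list to one read
#'
#' Steps are applied left to right; a drop short-circuits the remaining
#' steps. The returned outcome carries the cumulative bases cut from
#' each end, for the trim log.
#'
#' @param read An [fq_read()].
#' @param steps Character vector of step tokens or list of parsed
#'   `step_spec`s.
#' @return A `step_outcome`.
#' @examples
#' r <- fq_read("r", strrep("A", 50), rep(35L, 50))
#' apply_steps_single(r, c("HEADCROP:5", "MINLEN:36"))
#' @export
apply_steps_single <- function(read, steps) {
  compiled <- compile_steps(steps)
  res <- apply_compiled(read$bases, read$quals, compiled = compiled)
  n <- length(read$quals)
  if (!res$alive1) return(outcome_from_iv(read, NULL))
  outcome_from_iv(read, c(res$start1, res$start1 + length(res$quals1)))
}

#' Apply a step list to a read pair
#'
#' Pair-aware steps (palindrome ILLUMINACLIP) see both mates; all other
#' steps apply to each mate independently. The pair fate records which
#' mates survived.
#'
#' @param fwd,rev The two mates as [fq_read()].
#' @param steps Step tokens or parsed specs.
#' @return List with `fwd` and `rev` `step_outcome`s and `fate`, one of
#'   `"both_surviving"`, `"fwd_only"`, `"rev_only"`, `"dropped"`.
#' @export
apply_steps_pair <- function(fwd, rev, steps) {
  compiled <- compile_steps(steps)
  res <- apply_compiled(fwd$bases, fwd$quals, rev$bases, rev$quals, compiled)
  out_f <- if (res$alive1)
    outcome_from_iv(fwd, c(res$start1, res$start1 + length(res$quals1)))
  else outcome_from_iv(fwd, NULL)
  out_r <- if (isTRUE(res$alive2))
    outcome_from_iv(rev, c(res$start2, res$start2 + length(res$quals2)))
  else outcome_from_iv(rev, NULL)
  fate <- if (res$alive1 && isTRUE(res$alive2)) "both_surviving"
          else if (res$alive1) "fwd_only"
          else if (isTRUE(res$alive2)) "rev_only"
          else "dropped"
  list(fwd = out_f, rev = out_r, fate = fate)
}

# Process one batch of pairs; returns output lines per file, trim-log
# lines, and fate counts. Pure function of its inputs.
process_batch_pe <- function(b1, b2, compiled, offset, trimlog = FALSE) {
  n <- length(b1$name)
  keep1 <- logical(n)
  keep2 <- logical(n)
  l1 <- character(4L * n)
  l2 <- character(4L * n)
  fate <- integer(4L)  # both, fwd_only, rev_only, dropped
  tl <- if (trimlog) character(2L * n) else character()
  for (i in seq_len(n)) {
    q1 <- decode_quality(b1$qual[i], offset, b1$name[i])
    q2 <- decode_quality(b2$qual[i], offset, b2$name[i])
    o1 <- length(q1)
    o2 <- length(q2)
    r <- apply_compiled(b1$bases[i], q1, b2$bases[i], q2, compiled)
    a1 <- r$alive1
    a2 <- isTRUE(r$alive2)
    fi <- if (a1 && a2) 1L else if (a1) 2L else if (a2) 3L else 4L
    fate[fi] <- fate[fi] + 1L
    if (a1) {
      keep1[i] <- TRUE
      j <- 4L * (i - 1L)
      l1[j + 1L] <- paste0("@", b1$name[i])
      l1[j + 2L] <- r$bases1
      l1[j + 3L] <- "+"
      l1[j + 4L] <- encode_quality(r$quals1, offset)
    }
    if (a2) {
      keep2[i] <- TRUE
      j <- 4L * (i - 1L)
      l2[j + 1L] <- paste0("@", b2$name[i])
      l2[j + 2L] <- r$bases2
      l2[j + 3L] <- "+"
      l2[j + 4L] <- encode_quality(r$quals2, offset)
    }
    if (trimlog) {
      tl[2L * i - 1L] <- if (a1)
        render_trimlog_line(b1$name[i], r$start1,
                            r$start1 + length(r$quals1), o1)
      else render_trimlog_line(b1$name[i], NULL, NULL, o1)
      tl[2L * i] <- if (a2)
        render_trimlog_line(b2$name[i], r$start2,
                            r$start2 + length(r$quals2), o2)
      else render_trimlog_line(b2$name[i], NULL, NULL, o2)
    }
  }
  both <- keep1 & keep2
  sel <- function(lines, keep) lines[rep(keep, each = 4L)]
  list(fate = fate,
       p1 = sel(l1, both), u1 = sel(l1, keep1 & !keep2),
       p2 = sel(l2, both), u2 = sel(l2, keep2 & !keep1),
       trimlog = tl)
}

process_batch_se <- function(b1, compiled, offset, trimlog = FALSE) {
  n <- length(b1$name)
  keep1 <- logical(n)
  l1 <- character(4L * n)
  fate <- integer(2L)  # surviving, dropped
  tl <- if (trimlog) character(n) else character()
  for (i in seq_len(n)) {
    q1 <- decode_quality(b1$qual[i], offset, b1$name[i])
    o1 <- length(q1)
    r <- apply_compiled(b1$bases[i], q1, compiled = compiled)
    if (r$alive1) {
      fate[1L] <- fate[1L] + 1L
      keep1[i] <- TRUE
      j <- 4L * (i - 1L)
      l1[j + 1L] <- paste0("@", b1$name[i])
      l1[j + 2L] <- r$bases1
      l1[j + 3L] <- "+"
      l1[j + 4L] <- encode_quality(r$quals1, offset)
    } else fate[2L] <- fate[2L] + 1L
    if (trimlog) {
      tl[i] <- if (r$alive1)
        render_trimlog_line(b1$name[i], r$start1,
                            r$start1 + length(r$quals1), o1)
      else render_trimlog_line(b1$name[i], NULL, NULL, o1)
    }
  }
  list(fate = fate, p1 = l1[rep(keep1, each = 4L)], tl = tl)
}

# Plain line writer with suffix-based compression (for the trim log).
line_writer <- function(path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "wt")
         else if (endsWith(path, ".bz2")) bzfile(path, "wt")
         else file(path, "wt")
  list(write = function(lines) {
    if (length(lines)) writeLines(lines, con)
    invisible()
  },
  close = function() close(con))
}

run_group <- function(group, fun, threads) {
  res <- if (threads > 1L && length(group) > 1L)
    parallel::mclapply(group, fun, mc.cores = threads)
  else lapply(group, fun)
  for (x in res)
    if (inherits(x, "try-error") || inherits(x, "condition"))
      stop(x)
  res
}

#' Run the trimming pipeline on a read-pair stream
#'
#' Reads two record-synchronized FASTQ files, applies the step list to
#' every pair, and writes four outputs: forward/reverse paired (both
#' mates survived) and forward/reverse unpaired (only that mate
#' survived). `.gz` outputs are written as block-compressed multi-member
#' GZIP streams whose bytes are identical for every `threads` value;
#' batches may be processed by forked workers but are always written in
#' input order.
#'
#' @param input_fwd,input_rev Input FASTQ paths (plain/.gz/.bz2). When
#'   `input_rev` is `NULL` it is derived from `input_fwd` via
#'   [find_mate_path()].
#' @param steps Character vector of step tokens (applied left to right)
#'   or parsed specs.
#' @param output A `-baseout`-style template passed to
#'   [derive_output_names()], or four explicit paths in the order
#'   forward-paired, forward-unpaired, reverse-paired, reverse-unpaired.
#' @param threads Worker count; results do not depend on it.
#' @param encoding `"auto"` (detect from the forward file), `33` or
#'   `64`.
#' @param trimlog Optional per-read trim-log path.
#' @param summary_file Optional summary statistics path.
#' @param validate_pairs Validate name synchronization of the two inputs
#'   before any processing; a failure aborts the run.
#' @param batch_size Pairs per processing batch.
#' @param block_records Records per compressed GZIP member.
#' @return A [run_stats()], invisibly printed summary.
#' @export
run_paired <- function(input_fwd, input_rev = NULL, steps, output,
                       threads = 1L, encoding = "auto", trimlog = NULL,
                       summary_file = NULL, validate_pairs = FALSE,
                       batch_size = 5000L, block_records = 10000L) {
  if (is.null(input_rev)) input_rev <- find_mate_path(input_fwd)
  compiled <- compile_steps(steps)      # validates steps + adapter FASTA
  outs <- if (length(output) == 1L) derive_output_names(output)
          else if (length(output) == 4L)
            stats::setNames(as.list(output),
                            c("fwd_paired", "fwd_unpaired",
                              "rev_paired", "rev_unpaired"))
          else stop("output must be one template or four explicit paths")
  if (anyDuplicated(unlist(outs)))
    stop("the four output paths must be distinct")
  if (validate_pairs) {
    rep <- validate_pairing_files(input_fwd, input_rev)
    if (!rep$ok) {
      msg <- utils::capture.output(print(rep))
      stop("paired-end inputs are not synchronized: ", msg)
    }
  }
  offset <- resolve_encoding(input_fwd, encoding)
  r1 <- fq_reader(input_fwd)
  r2 <- fq_reader(input_rev)
  ws <- lapply(outs, fq_writer, workers = threads,
               block_records = block_records)
  tw <- if (!is.null(trimlog)) line_writer(trimlog)
  on.exit({
    r1$close(); r2$close()
  }, add = TRUE)
  fate <- integer(4L)
  repeat {
    group <- list()
    repeat {
      b1 <- r1$next_batch(batch_size)
      b2 <- r2$next_batch(batch_size)
      if (length(b1) != length(b2))
        stop("paired inputs have unequal record counts ",
             "(use validate_pairs to locate the divergence)")
      if (!length(b1)) break
      group[[length(group) + 1L]] <- list(b1 = b1, b2 = b2)
      if (length(group) >= threads || length(b1) < batch_size) break
    }
    if (!length(group)) break
    res <- run_group(group, function(g)
      process_batch_pe(g$b1, g$b2, compiled, offset, !is.null(trimlog)),
      threads)
    for (x in res) {
      fate <- fate + x$fate
      ws$fwd_paired$write(x$p1)
      ws$fwd_unpaired$write(x$u1)
      ws$rev_paired$write(x$p2)
      ws$rev_unpaired$write(x$u2)
      if (!is.null(tw)) tw$write(x$trimlog)
    }
    if (length(group[[length(group)]]$b1) < batch_size) break
  }
  for (w in ws) w$close()
  if (!is.null(tw)) tw$close()
  stats <- run_stats("PE", input = sum(fate), both_surviving = fate[1L],
                     fwd_only = fate[2L], rev_only = fate[3L],
                     dropped = fate[4L])
  if (!is.null(summary_file))
    writeLines(render_summary(stats), summary_file)
  stats
}

#' Run the trimming pipeline on a single-end stream
#'
#' Single-end counterpart of [run_paired()]: one input, one output,
#' fates are surviving/dropped, and ILLUMINACLIP uses simple mode only.
#'
#' @inheritParams run_paired
#' @param input Input FASTQ path.
#' @param output Output FASTQ path.
#' @return A [run_stats()].
#' @export
run_single <- function(input, steps, output, threads = 1L,
                       encoding = "auto", trimlog = NULL,
                       summary_file = NULL, batch_size = 5000L,
                       block_records = 10000L) {
  compiled <- compile_steps(steps)
  offset <- resolve_encoding(input, encoding)
  r1 <- fq_reader(input)
  w <- fq_writer(output, workers = threads, block_records = block_records)
  tw <- if (!is.null(trimlog)) line_writer(trimlog)
  on.exit(r1$close(), add = TRUE)
  fate <- integer(2L)
  repeat {
    group <- list()
    repeat {
      b1 <- r1$next_batch(batch_size)
      if (!length(b1)) break
      group[[length(group) + 1L]] <- b1
      if (length(group) >= threads || length(b1) < batch_size) break
    }
    if (!length(group)) break
    res <- run_group(group, function(b)
      process_batch_se(b, compiled, offset, !is.null(trimlog)), threads)
    for (x in res) {
      fate <- fate + x$fate
      w$write(x$p1)
      if (!is.null(tw)) tw$write(x$tl)
    }
    if (length(group[[length(group)]]) < batch_size) break
  }
  w$close()
  if (!is.null(tw)) tw$close()
  stats <- run_stats("SE", input = sum(fate), surviving = fate[1L],
                     dropped = fate[2L])
  if (!is.null(summary_file))
    writeLines(render_summary(stats), summary_file)
  stats
}
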
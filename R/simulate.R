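# Seeded synthetic paired-read generator: known insert sizes, adapter
# read-through, configurable quality decay, encoding variants, and
# deliberately corrupted pairings. Produces every fixture the test
# suite needs, with a truth table that makes adapter-clip recovery
# exactly scorable.

# Fixed synthetic adapter read-through sequences (invented, 34 bp; they
# are not any vendor's real adapters).
SYNTHETIC_ADAPTER_R1 <- "AGTTCGGACTGATCGTACCAGTTGCAAGCTAGGT"
SYNTHETIC_ADAPTER_R2 <- "TCAGGCATTCGAAGCTGTACGATCCTAGGTTCAA"

#' Configuration for the synthetic paired-read generator
#'
#' The default scenario emulates a NovaSeq-like 2x100 bp library with a
#' short insert distribution (mean 60, sd 10, floor 20) so that most
#' pairs read through into adapter, a 0.1% per-base substitution error
#' rate, and per-cycle mean quality decaying linearly from Q38 to Q20.
#'
#' `adapter_read1`/`adapter_read2` are the sequences that appear at the
#' 3' end of each mate once the polymerase runs off the insert; the
#' palindrome-mode adapter prefixes are their reverse complements, with
#' read 1 contaminated by the reverse complement of the `/2` prefix and
#' vice versa (see [write_adapter_fasta()]).
#'
#' @param n_pairs Number of read pairs.
#' @param read_length Read length (both mates).
#' @param insert_mean,insert_sd,insert_min Normal insert-length
#'   distribution, rounded and floored at `insert_min`.
#' @param adapter_read1,adapter_read2 Read-through sequences.
#' @param error_rate Mean per-base substitution rate; individual bases
#'   err with probability proportional to their `10^(-q/10)` so errors
#'   concentrate where quality is low.
#' @param qual_start,qual_end Per-cycle mean quality at the first and
#'   last cycle (linear decay).
#' @param qual_sd Per-base quality jitter (scores clamped to `[2, 41]`).
#' @param seed Integer seed; the same seed and configuration produce
#'   byte-identical files.
#' @param name_prefix Read-name prefix.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_pairs = 1000L, read_length = 100L,
                       insert_mean = 60, insert_sd = 10, insert_min = 20L,
                       adapter_read1 = SYNTHETIC_ADAPTER_R1,
                       adapter_read2 = SYNTHETIC_ADAPTER_R2,
                       error_rate = 0.001,
                       qual_start = 38, qual_end = 20, qual_sd = 3,
                       seed = 1L, name_prefix = "sim") {
  stopifnot(n_pairs >= 0, read_length >= 1, insert_min >= 1,
            error_rate >= 0, error_rate < 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 insert_min = as.integer(insert_min),
                 adapter_read1 = toupper(adapter_read1),
                 adapter_read2 = toupper(adapter_read2),
                 error_rate = error_rate, qual_start = qual_start,
                 qual_end = qual_end, qual_sd = qual_sd,
                 seed = as.integer(seed), name_prefix = name_prefix),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate paired reads with known inserts and adapter read-through
#'
#' Fragments are drawn from the configured insert distribution; when an
#' insert is shorter than the read length each mate continues into its
#' read-through adapter sequence and then into random bases. The truth
#' table records, per pair, the true insert length and the 0-based
#' adapter start offset in each mate (`NA` when there is no
#' read-through). Substitution errors are placed with probability
#' proportional to each base's error probability `10^(-q/10)`, scaled so
#' the mean rate equals `error_rate`.
#'
#' @param cfg A [sim_config()].
#' @return List with `fwd` and `rev` (lists of [fq_read()]) and `truth`
#'   (data frame: `pair`, `insert`, `adapter_start`).
#' @export
simulate_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_pairs
  R <- cfg$read_length
  inserts <- pmax(cfg$insert_min,
                  as.integer(round(rnorm(n, cfg$insert_mean, cfg$insert_sd))))
  mu <- seq(cfg$qual_start, cfg$qual_end, length.out = R)
  # scale quality-driven error probabilities to the requested mean rate
  scale <- if (cfg$error_rate > 0) cfg$error_rate / mean(10^(-mu / 10)) else 0
  ad1 <- strsplit(cfg$adapter_read1, "")[[1L]]
  ad2 <- strsplit(cfg$adapter_read2, "")[[1L]]
  mk_mate <- function(frag_chars, adapter_chars, L) {
    if (L >= R) return(frag_chars[seq_len(R)])
    k <- R - L
    tail <- if (k <= length(adapter_chars)) adapter_chars[seq_len(k)]
            else c(adapter_chars, sample(BASES, k - length(adapter_chars),
                                         replace = TRUE))
    c(frag_chars[seq_len(L)], tail)
  }
  mk_quals <- function() {
    q <- as.integer(round(rnorm(R, mu, cfg$qual_sd)))
    pmin(pmax(q, 2L), 41L)
  }
  inject <- function(chars, quals) {
    # a fixed number of draws per read, so configurations differing only
    # in error_rate share fragments and qualities under the same seed
    p <- pmin(0.75, scale * 10^(-quals / 10))
    u <- runif(R)
    alt <- sample.int(3L, R, replace = TRUE)
    for (j in which(u < p)) chars[j] <- BASES[BASES != chars[j]][alt[j]]
    chars
  }
  fwd_reads <- vector("list", n)
  rev_reads <- vector("list", n)
  for (i in seq_len(n)) {
    L <- inserts[i]
    frag <- sample(BASES, L, replace = TRUE)
    q1 <- mk_quals()
    q2 <- mk_quals()
    b1 <- inject(mk_mate(frag, ad1, L), q1)
    b2 <- inject(mk_mate(rev(chartr_chars(frag)), ad2, L), q2)
    nm <- sprintf("%s_%06d", cfg$name_prefix, i)
    fwd_reads[[i]] <- fq_read(paste0(nm, "/1"), paste(b1, collapse = ""), q1)
    rev_reads[[i]] <- fq_read(paste0(nm, "/2"), paste(b2, collapse = ""), q2)
  }
  truth <- data.frame(pair = sprintf("%s_%06d", cfg$name_prefix, seq_len(n)),
                      insert = inserts,
                      adapter_start = ifelse(inserts < R, inserts,
                                             NA_integer_))
  list(fwd = fwd_reads, rev = rev_reads, truth = truth)
}

# complement a character vector of bases
chartr_chars <- function(chars) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars])
}

#' Write simulated pairs, truth table, and adapter FASTA to disk
#'
#' @param cfg A [sim_config()].
#' @param prefix Output path prefix; writes `<prefix>_1<ext>`,
#'   `<prefix>_2<ext>`, `<prefix>_truth.tsv` and
#'   `<prefix>_adapters.fa`.
#' @param compress Write GZIP-compressed FASTQ (`.fastq.gz`) instead of
#'   plain `.fastq`.
#' @return Named list of the paths plus the truth data frame, invisibly.
#' @export
generate_pairs <- function(cfg, prefix, compress = FALSE) {
  sim <- simulate_pairs(cfg)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  p1 <- paste0(prefix, "_1", ext)
  p2 <- paste0(prefix, "_2", ext)
  pt <- paste0(prefix, "_truth.tsv")
  pa <- paste0(prefix, "_adapters.fa")
  write_fastq(sim$fwd, p1)
  write_fastq(sim$rev, p2)
  write.table(sim$truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  write_adapter_fasta(cfg, pa)
  invisible(list(fwd = p1, rev = p2, truth_path = pt, adapters = pa,
                 truth = sim$truth))
}

#' Write the palindrome + simple adapter FASTA matching a configuration
#'
#' The palindrome records `SynPE/1` and `SynPE/2` hold the adapter
#' prefixes ligated 5' of each mate, i.e. the reverse complements of the
#' opposite mate's read-through sequence; the read-through sequences
#' themselves are included as simple adapters.
#'
#' @param cfg A [sim_config()] (or any list with `adapter_read1`,
#'   `adapter_read2`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_adapter_fasta <- function(cfg, path) {
  lines <- c(">SynPE/1", revcomp(cfg$adapter_read2),
             ">SynPE/2", revcomp(cfg$adapter_read1),
             ">SynSimple1", cfg$adapter_read1,
             ">SynSimple2", cfg$adapter_read2)
  writeLines(lines, path)
  invisible(path)
}

#' Corrupt the synchronization of a simulated pair set
#'
#' Produces inputs that [validate_pairing()] must reject, with the known
#' first divergence: `"shuffle"` permutes the reverse records,
#' `"drop_one"` deletes one reverse record (length mismatch), and
#' `"rename"` alters the name of reverse record `k`.
#'
#' @param fwd,rev Lists of [fq_read()] (mates in sync).
#' @param mode Corruption mode.
#' @param k 0-based record index for `"rename"` and `"drop_one"`.
#' @param seed Seed for `"shuffle"`.
#' @return List with `fwd`, `rev`, and `expected` (`ordinal` of the
#'   first mismatch, or `length_mismatch = TRUE`).
#' @export
corrupt_pairing <- function(fwd, rev, mode = c("shuffle", "drop_one", "rename"),
                            k = 0L, seed = 1L) {
  mode <- match.arg(mode)
  n <- length(rev)
  stopifnot(n >= 2L, k >= 0L, k < n)
  names_of <- function(x) vapply(x, `[[`, "", "name")
  if (mode == "shuffle") {
    set.seed(seed)
    repeat {
      perm <- sample.int(n)
      if (any(perm != seq_len(n))) break
    }
    rev2 <- rev[perm]
    cf <- canonical_read_names(names_of(fwd))
    cr <- canonical_read_names(names_of(rev2))
    ord <- which(cf != cr)[1L] - 1L
    list(fwd = fwd, rev = rev2, expected = list(ordinal = ord))
  } else if (mode == "drop_one") {
    expected <- if (k == n - 1L)
      list(length_mismatch = TRUE, n_fwd = length(fwd), n_rev = n - 1L)
    else list(ordinal = as.integer(k))  # names diverge before the end
    list(fwd = fwd, rev = rev[-(k + 1L)], expected = expected)
  } else {
    r <- rev[[k + 1L]]
    rev[[k + 1L]] <- fq_read(paste0(r$name, "_corrupt"), r$bases, r$quals)
    list(fwd = fwd, rev = rev, expected = list(ordinal = as.integer(k)))
  }
}

#' Re-encode a Phred33 FASTQ file as Phred64
#'
#' Shifts every quality character by +31 (e.g. `I` (Q40, code 73)
#' becomes `h` (code 104)), leaving everything else untouched.
#'
#' @param path_in,path_out Input and output FASTQ paths.
#' @return `path_out`, invisibly.
#' @export
reencode_phred64 <- function(path_in, path_out) {
  r <- fq_reader(path_in)
  on.exit(r$close())
  w <- fq_writer(path_out, gzip_blocks = endsWith(path_out, ".gz"))
  repeat {
    b <- r$next_batch(10000L)
    if (!length(b)) break
    b$qual <- vapply(b$qual,
                     function(s) if (nzchar(s)) intToUtf8(utf8ToInt(s) + 31L)
                                 else s, "")
    w$write(serialize_fastq(b), length(b))
  }
  w$close()
  invisible(path_out)
}
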
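# Fixture builders shared across the suite. Everything is generated in
# code; no stored data files.

# A read with given qualities and arbitrary (deterministic) bases.
mk_read <- function(quals, name = "r") {
  quals <- as.integer(quals)
  bases <- paste(rep_len(c("A", "C", "G", "T"), length(quals)),
                 collapse = "")
  fq_read(name, bases, quals)
}

random_read <- function(len, name = "r", qmin = 2L, qmax = 41L) {
  fq_read(name,
          paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = ""),
          sample(qmin:qmax, len, replace = TRUE))
}

# Check the fundamental trimming invariant: the surviving read is the
# contiguous substring of the original implied by the reported cuts,
# with qualities in lockstep.
expect_contiguous <- function(outcome, original) {
  n <- length(original$quals)
  if (outcome$dropped) {
    expect_null(outcome$read)
    return(invisible())
  }
  s <- outcome$cut_from_start
  e <- n - outcome$cut_from_end
  expect_identical(outcome$read$bases, substr(original$bases, s + 1L, e))
  expect_identical(outcome$read$quals, original$quals[seq_len(e - s) + s])
  expect_lte(length(outcome$read), n)
}

# Default shared scenario used across the acceptance suite
# (novaseq-like: 2x100 bp, insert 60 +/- 10 floored at 20, error 0.1%,
# quality decay Q38 -> Q20).
default_scenario <- function(n_pairs, seed) sim_config(n_pairs = n_pairs,
                                                       seed = seed)

gz_lines <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con)
}
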
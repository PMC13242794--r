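# Step composition, pair fate bookkeeping, and the order/byte-identity
# contracts of the streaming engine.

test_that("steps compose left to right and a drop short-circuits", {
  r <- fq_read("r", strrep("A", 100), rep(35L, 100))
  out <- apply_steps_single(r, "MINLEN:36")
  expect_identical(out$read, r)

  # SLIDINGWINDOW cuts to 18 bases (the last window spanning the cliff
  # fails), then MINLEN:36 drops
  r <- mk_read(c(rep(35, 20), rep(2, 80)))
  solo <- apply_steps_single(r, "SLIDINGWINDOW:4:20")
  expect_identical(length(solo$read), 18L)
  out <- apply_steps_single(r, c("SLIDINGWINDOW:4:20", "MINLEN:36"))
  expect_true(out$dropped)

  # empty step list is the identity
  out <- apply_steps_single(r, character())
  expect_identical(out$read, r)
  expect_identical(out$cut_from_start, 0L)
  expect_identical(out$cut_from_end, 0L)
})

test_that("cumulative end cuts are tracked across steps for the trim log", {
  r <- mk_read(rep(30, 50))
  out <- apply_steps_single(r, c("HEADCROP:5", "TAILCROP:7", "HEADCROP:3"))
  expect_identical(out$cut_from_start, 8L)
  expect_identical(out$cut_from_end, 7L)
  expect_identical(length(out$read), 35L)
  expect_contiguous(out, r)
})

test_that("pair fates derive from which mates survive", {
  fwd <- mk_read(rep(35, 80), "p/1")
  rev <- mk_read(rep(35, 80), "p/2")
  res <- apply_steps_pair(fwd, rev, "MINLEN:36")
  expect_identical(res$fate, "both_surviving")

  weak <- mk_read(rep(10, 80), "p/2")
  res <- apply_steps_pair(fwd, weak, "AVGQUAL:20")
  expect_identical(res$fate, "fwd_only")
  expect_true(res$rev$dropped)
  res <- apply_steps_pair(weak, fwd, "AVGQUAL:20")
  expect_identical(res$fate, "rev_only")
  res <- apply_steps_pair(weak, weak, "AVGQUAL:20")
  expect_identical(res$fate, "dropped")
})

run_scenario <- function(sim, steps, threads, dir, tag, ...) {
  p1 <- file.path(dir, paste0(tag, "_1.fastq"))
  p2 <- file.path(dir, paste0(tag, "_2.fastq"))
  write_fastq(sim$fwd, p1)
  write_fastq(sim$rev, p2)
  run_paired(p1, p2, steps = steps,
             output = file.path(dir, paste0(tag, "_out.fq.gz")),
             threads = threads,
             summary_file = file.path(dir, paste0(tag, "_summary.txt")),
             ...)
}

test_that("an identity pipeline reproduces its input and conserves pairs", {
  d <- tempfile(); dir.create(d)
  sim <- simulate_pairs(sim_config(n_pairs = 120, seed = 31))
  st <- run_scenario(sim, character(), threads = 1L, d, "id")
  expect_identical(st$input, 120L)
  expect_identical(st$both_surviving, 120L)
  expect_identical(st$fwd_only + st$rev_only + st$dropped, 0L)
  back <- read_fastq(file.path(d, "id_out_1P.fq.gz"), encoding = 33)
  attr(back, "offset") <- NULL
  expect_identical(back, sim$fwd)
  expect_identical(length(gz_lines(file.path(d, "id_out_1U.fq.gz"))), 0L)
})

test_that("outputs are byte-identical across worker counts and in input order", {
  d <- tempfile(); dir.create(d)
  sim <- simulate_pairs(sim_config(n_pairs = 400, seed = 32))
  fa <- file.path(d, "ad.fa")
  write_adapter_fasta(sim_config(), fa)
  steps <- c(paste0("ILLUMINACLIP:", fa, ":2:30:10"),
             "SLIDINGWINDOW:4:20", "MINLEN:36")
  st1 <- run_scenario(sim, steps, threads = 1L, d, "w1", batch_size = 64L)
  st2 <- run_scenario(sim, steps, threads = 2L, d, "w2", batch_size = 64L)
  expect_identical(unclass(st1), unclass(st2))
  for (s in c("_1P", "_1U", "_2P", "_2U")) {
    a <- gz_lines(file.path(d, paste0("w1_out", s, ".fq.gz")))
    b <- gz_lines(file.path(d, paste0("w2_out", s, ".fq.gz")))
    expect_identical(a, b)
  }
  expect_identical(readLines(file.path(d, "w1_summary.txt")),
                   readLines(file.path(d, "w2_summary.txt")))
  # survivors appear in input order in every file
  nm <- sub("/1$", "", vapply(sim$fwd, `[[`, "", "name"))
  lines <- gz_lines(file.path(d, "w1_out_1U.fq.gz"))
  out_nm <- sub("/1$", "",
                sub("^@", "", lines[seq(1, length(lines), by = 4L)]))
  expect_identical(out_nm, nm[nm %in% out_nm])
})

test_that("fate counts partition the input and rerunning is deterministic", {
  d <- tempfile(); dir.create(d)
  sim <- simulate_pairs(sim_config(n_pairs = 150, seed = 33))
  st <- run_scenario(sim, c("MAXINFO:40:0.5", "AVGQUAL:24", "MINLEN:30"),
                     threads = 1L, d, "f")
  expect_identical(st$both_surviving + st$fwd_only + st$rev_only + st$dropped,
                   st$input)
  st2 <- run_scenario(sim, c("MAXINFO:40:0.5", "AVGQUAL:24", "MINLEN:30"),
                      threads = 1L, d, "f2")
  expect_identical(unclass(st)[-1], unclass(st2)[-1])
})

test_that("the trim log holds one line per input read, both mates", {
  d <- tempfile(); dir.create(d)
  sim <- simulate_pairs(sim_config(n_pairs = 50, seed = 34))
  p1 <- file.path(d, "t_1.fastq"); write_fastq(sim$fwd, p1)
  p2 <- file.path(d, "t_2.fastq"); write_fastq(sim$rev, p2)
  log <- file.path(d, "trim.log")
  st <- run_paired(p1, p2, steps = c("SLIDINGWINDOW:4:20", "MINLEN:90"),
                   output = file.path(d, "t_out.fq.gz"), trimlog = log)
  lines <- readLines(log)
  expect_length(lines, 100L)
  flds <- strsplit(lines, " ")
  # surviving length + offset arithmetic is consistent on every line
  for (f in flds) {
    v <- as.integer(f[-1])
    expect_identical(v[1], v[3] - v[2])
  }
  # dropped reads log as "name 0 0 0 L"
  dropped <- vapply(flds, function(f) f[2] == "0", TRUE)
  if (any(dropped))
    expect_true(all(vapply(flds[dropped],
                           function(f) identical(f[2:4], c("0", "0", "0")),
                           TRUE)))
})

test_that("single-end mode uses surviving/dropped fates only", {
  d <- tempfile(); dir.create(d)
  sim <- simulate_pairs(sim_config(n_pairs = 60, seed = 35))
  p <- file.path(d, "se.fastq")
  write_fastq(sim$fwd, p)
  st <- run_single(p, steps = c("SLIDINGWINDOW:4:20", "MINLEN:36"),
                   output = file.path(d, "se_out.fastq"),
                   summary_file = file.path(d, "se_summary.txt"))
  expect_identical(st$mode, "SE")
  expect_identical(st$surviving + st$dropped, 60L)
  expect_match(readLines(file.path(d, "se_summary.txt"))[1],
               "^Input Reads: 60$")
  out <- read_fastq(file.path(d, "se_out.fastq"), encoding = 33)
  expect_length(out, st$surviving)
})

test_that("pairing validation aborts the run before writing output", {
  d <- tempfile(); dir.create(d)
  sim <- simulate_pairs(sim_config(n_pairs = 20, seed = 36))
  cor <- corrupt_pairing(sim$fwd, sim$rev, "rename", k = 3)
  p1 <- file.path(d, "v_1.fastq"); write_fastq(cor$fwd, p1)
  p2 <- file.path(d, "v_2.fastq"); write_fastq(cor$rev, p2)
  expect_error(run_paired(p1, p2, steps = "MINLEN:36",
                          output = file.path(d, "v_out.fq.gz"),
                          validate_pairs = TRUE),
               "not synchronized")
  expect_false(file.exists(file.path(d, "v_out_1P.fq.gz")))
})

test_that("step and adapter problems are raised before any data is read", {
  d <- tempfile(); dir.create(d)
  expect_error(run_paired("nope_1.fq", "nope_2.fq", steps = "BOGUS:1",
                          output = file.path(d, "x.fq.gz")),
               "unknown step")
  expect_error(run_paired("nope_1.fq", "nope_2.fq",
                          steps = "ILLUMINACLIP:absent.fa:2:30:10",
                          output = file.path(d, "x.fq.gz")))
})

test_that("explicit four-path outputs are honoured and must be distinct", {
  d <- tempfile(); dir.create(d)
  sim <- simulate_pairs(sim_config(n_pairs = 10, seed = 37))
  p1 <- file.path(d, "e_1.fastq"); write_fastq(sim$fwd, p1)
  p2 <- file.path(d, "e_2.fastq"); write_fastq(sim$rev, p2)
  outs <- file.path(d, c("a.fq", "b.fq", "c.fq", "dd.fq"))
  st <- run_paired(p1, p2, steps = "MINLEN:1", output = outs)
  expect_true(all(file.exists(outs)))
  expect_error(run_paired(p1, p2, steps = "MINLEN:1",
                          output = rep(outs[1], 4)), "distinct")
})
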
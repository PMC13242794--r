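# Adapter loading, alignment scoring, simple-mode clipping, and
# palindrome read-through detection.

LOG10_4 <- log10(4)

write_fasta <- function(named, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", names(named)), unname(named))), path)
  path
}

test_that("adapter FASTA records partition into palindrome pairs and simple", {
  p <- write_fasta(c("P/1" = "ACGTACGTAC", "P/2" = "TTGGCCAATT",
                     "A" = "GGGGCCCCAA"))
  aset <- load_adapters(p)
  expect_identical(nrow(aset$palindrome), 1L)
  expect_identical(aset$palindrome$stem, "P")
  expect_identical(aset$palindrome$fwd, "ACGTACGTAC")
  expect_identical(aset$palindrome$rev, "TTGGCCAATT")
  expect_identical(aset$simple$sequence, "GGGGCCCCAA")

  aset <- load_adapters(write_fasta(c(A = "ACGTACGT", B = "TTTTAAAA")))
  expect_identical(nrow(aset$palindrome), 0L)
  expect_identical(nrow(aset$simple), 2L)

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(load_adapters(empty), "no sequences")

  expect_warning(aset <- load_adapters(write_fasta(c("P/1" = "ACGTACGT"))),
                 "palindrome mate")
  expect_identical(nrow(aset$palindrome), 0L)
  expect_identical(aset$simple$sequence, "ACGTACGT")
})

test_that("alignment scoring gives log10(4) per match, -q/10 per mismatch", {
  a <- strrep("A", 17)
  s <- alignment_score(a, rep(30L, 17), a)
  expect_equal(s, 17 * LOG10_4, tolerance = 1e-12)
  expect_gte(s, 10)  # 17 perfect matches reach the simple threshold
  s50 <- alignment_score(strrep("C", 50), rep(30L, 50), strrep("C", 50))
  expect_equal(s50, 50 * LOG10_4, tolerance = 1e-12)
  expect_gte(s50, 30)  # 50 perfect matches reach the palindrome threshold
  # all-mismatch windows can only score <= 0
  expect_lte(alignment_score(strrep("A", 20), rep(0L, 20), strrep("C", 20)), 0)
  expect_equal(alignment_score("ACGT", c(10L, 20L, 30L, 40L), "TGCA"), -10)
  # case-insensitive matching; N matches nothing and costs q/10
  expect_equal(alignment_score("acgt", rep(30L, 4), "ACGT"), 4 * LOG10_4)
  expect_equal(alignment_score("ACGN", rep(30L, 4), "ACGN"),
               3 * LOG10_4 - 3)
})

test_that("simple clipping truncates before the earliest qualifying offset", {
  set.seed(21)
  adapter <- paste(sample(c("A", "C", "G", "T"), 33, replace = TRUE),
                   collapse = "")
  insert <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                  collapse = "")
  r <- fq_read("r", paste0(insert, adapter), rep(35L, 53))
  out <- simple_clip(r, adapter)
  expect_false(out$dropped)
  expect_identical(out$read$bases, insert)
  # adapter at offset 0 drops the read
  r0 <- fq_read("r0", adapter, rep(35L, 33))
  expect_true(simple_clip(r0, adapter)$dropped)
  # partial 3' overlap long enough to reach threshold is clipped
  r17 <- fq_read("r17", paste0(insert, substr(adapter, 1, 17)), rep(35L, 37))
  expect_identical(simple_clip(r17, adapter)$read$bases, insert)
  # an overlap that cannot reach the threshold is ignored
  r10 <- fq_read("r10", paste0(insert, substr(adapter, 1, 10)), rep(35L, 30))
  expect_identical(simple_clip(r10, adapter)$read$bases, r10$bases)
})

test_that("random reads are practically never falsely clipped", {
  set.seed(22)
  adapter <- paste(sample(c("A", "C", "G", "T"), 33, replace = TRUE),
                   collapse = "")
  clipped <- 0L
  for (i in 1:1000) {
    r <- random_read(100)
    out <- simple_clip(r, adapter)
    if (out$dropped || length(out$read) < 100L) clipped <- clipped + 1L
  }
  expect_lte(clipped, 1L)
})

test_that("an adapter sharing no seed leaves reads unchanged", {
  r <- fq_read("r", strrep("A", 60), rep(35L, 60))
  out <- simple_clip(r, strrep("C", 30))
  expect_identical(out$read$bases, r$bases)
})

# Build a read-through pair the way the sequencer produces it: mate 1
# reads the fragment then the reverse complement of the /2 prefix,
# mate 2 reads the reverse complement of the fragment then the reverse
# complement of the /1 prefix.
make_readthrough_pair <- function(insert_len, read_len, prefix1, prefix2,
                                  q = 35L) {
  rc <- function(x) readtrim:::revcomp(x)
  frag <- paste(sample(c("A", "C", "G", "T"), insert_len, replace = TRUE),
                collapse = "")
  fill <- function(core) {
    k <- read_len - nchar(core)
    if (k > 0)
      core <- paste0(core, paste(sample(c("A", "C", "G", "T"), k,
                                        replace = TRUE), collapse = ""))
    substr(core, 1, read_len)
  }
  b1 <- fill(paste0(frag, rc(prefix2)))
  b2 <- fill(paste0(rc(frag), rc(prefix1)))
  list(fwd = fq_read("p/1", b1, rep(q, read_len)),
       rev = fq_read("p/2", b2, rep(q, read_len)))
}

test_that("palindrome mode recovers the fragment length and drops the mate", {
  set.seed(23)
  prefix1 <- paste(sample(c("A", "C", "G", "T"), 34, replace = TRUE),
                   collapse = "")
  prefix2 <- paste(sample(c("A", "C", "G", "T"), 34, replace = TRUE),
                   collapse = "")
  pr <- make_readthrough_pair(60, 100, prefix1, prefix2)
  res <- palindrome_clip(pr$fwd, pr$rev, list(prefix1, prefix2))
  expect_identical(res$fragment_length, 60L)
  expect_identical(length(res$fwd$read), 60L)
  expect_true(res$rev$dropped)
  # surviving bases are untouched, only truncated
  expect_identical(res$fwd$read$bases, substr(pr$fwd$bases, 1, 60))

  # keep_both_reads retains the trimmed reverse mate
  res <- palindrome_clip(pr$fwd, pr$rev, list(prefix1, prefix2),
                         clip_params(keep_both_reads = TRUE))
  expect_identical(length(res$fwd$read), 60L)
  expect_identical(length(res$rev$read), 60L)
  expect_identical(res$rev$read$bases, substr(pr$rev$bases, 1, 60))

  # no read-through: insert longer than the read leaves both unchanged
  pr <- make_readthrough_pair(150, 100, prefix1, prefix2)
  res <- palindrome_clip(pr$fwd, pr$rev, list(prefix1, prefix2))
  expect_true(is.na(res$fragment_length))
  expect_identical(res$fwd$read, pr$fwd)
  expect_identical(res$rev$read, pr$rev)
})

test_that("palindrome detection tolerates scattered sequencing errors", {
  set.seed(24)
  prefix1 <- paste(sample(c("A", "C", "G", "T"), 34, replace = TRUE),
                   collapse = "")
  prefix2 <- paste(sample(c("A", "C", "G", "T"), 34, replace = TRUE),
                   collapse = "")
  hits <- 0L
  for (i in 1:50) {
    L <- sample(25:95, 1)
    pr <- make_readthrough_pair(L, 100, prefix1, prefix2)
    # two random substitutions on the forward mate
    b <- strsplit(pr$fwd$bases, "")[[1]]
    for (j in sample(100, 2)) b[j] <- sample(setdiff(c("A","C","G","T"), b[j]), 1)
    fwd <- fq_read(pr$fwd$name, paste(b, collapse = ""), pr$fwd$quals)
    res <- palindrome_clip(fwd, pr$rev, list(prefix1, prefix2))
    if (identical(res$fragment_length, L)) hits <- hits + 1L
  }
  expect_gte(hits, 49L)
})

test_that("residual adapter counting finds k-mer prefixes", {
  adapter <- "ACGTACGTACGTTTTT"
  reads <- list(fq_read("a", paste0("GGGG", substr(adapter, 1, 12)), rep(30L, 16)),
                fq_read("b", "GGGGGGGGGGGGGGGG", rep(30L, 16)))
  expect_identical(residual_adapter_count(reads, adapter), 1L)
})
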
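# Independent brute-force oracles for the quality trimmers. These
# enumerate every window / every prefix directly from the rule
# definitions and share no code with the package implementation.

# Exhaustive window scan: compute every window sum, find the first
# failing window, cut there, then strip trailing bases below q.
oracle_sliding_window <- function(quals, w, q) {
  n <- length(quals)
  if (n == 0L) return(0L)
  if (n < w) return(if (sum(quals) < q * n) 0L else n)
  cs <- c(0L, cumsum(quals))
  starts <- 0:(n - w)
  sums <- cs[starts + w + 1L] - cs[starts + 1L]
  fail <- which(sums < q * w)
  if (!length(fail)) return(n)
  keep <- starts[fail[1L]]
  while (keep > 0L && quals[keep] < q) keep <- keep - 1L
  keep
}

# Exhaustive prefix-score maximization, ties toward larger L.
oracle_maxinfo <- function(quals, target, strictness) {
  n <- length(quals)
  if (n == 0L) return(0L)
  L <- seq_len(n)
  x <- target - 1 - L
  flen <- ifelse(x > 35, -x, -log1p(exp(x)))
  fcov <- (1 - strictness) * log(L)
  ferr <- strictness * cumsum(log(1 - 10^(-pmax(quals, 1) / 10)))
  sc <- flen + fcov + ferr
  max(which(sc == max(sc)))
}
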
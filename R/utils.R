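# Round a positive vector to integers by largest remainder, preserving an
# exact total and a per-element minimum.
round_preserve_total <- function(x, total, min_each = 1L) {
  stopifnot(all(is.finite(x)), total >= length(x) * min_each)
  f <- pmax(floor(x), min_each)
  diff <- total - sum(f)
  if (diff > 0) {
    # award the shortfall to the largest fractional remainders, cycling
    ord <- order(x - floor(x), decreasing = TRUE)
    idx <- rep_len(ord, diff)
    add <- tabulate(idx, nbins = length(x))
    f <- f + add
  } else if (diff < 0) {
    # remove the excess from the smallest remainders, never below min_each
    ord <- order(x - floor(x))
    need <- -diff
    i <- 1L
    while (need > 0L) {
      j <- ord[(i - 1L) %% length(ord) + 1L]
      if (f[j] > min_each) {
        f[j] <- f[j] - 1L
        need <- need - 1L
      }
      i <- i + 1L
      if (i > 10L * length(x) * max(1L, abs(diff))) stop("rounding failed")
    }
  }
  storage.mode(f) <- "integer"
  f
}

# deterministic 31-bit seed from a string id and a master seed
derive_seed <- function(id, master) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(master) * 7919) %% 2147483647)
}
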
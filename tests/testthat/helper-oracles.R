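# Independent oracles used across the suite.

# Direct-summation 2-D DFT (O(N^4)); returns the half spectrum.
naive_dft2_half <- function(m) {
  H <- nrow(m); W <- ncol(m)
  wf <- W %/% 2L + 1L
  out <- matrix(complex(real = 0), H, wf)
  for (u in 0:(H - 1)) for (v in 0:(wf - 1)) {
    s <- 0 + 0i
    for (h in 0:(H - 1)) for (w in 0:(W - 1)) {
      s <- s + m[h + 1, w + 1] * exp(-2i * pi * (u * h / H + v * w / W))
    }
    out[u + 1, v + 1] <- s
  }
  out
}

# Normalised radial frequency of half-spectrum bin (row u, col v), 1-based,
# written independently of the implementation.
bin_radius <- function(u, v, H, W) {
  u0 <- u - 1
  fy <- if (u0 < ceiling(H / 2)) u0 / H else (u0 - H) / H
  fx <- (v - 1) / W
  sqrt((abs(fy) / 0.5)^2 + (fx / 0.5)^2) / sqrt(2)
}

# Exhaustive concordant-pair AUC (ties count 1/2).
pairwise_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

random_mask_pair <- function(n = 8L) {
  list(a = matrix(rbinom(n * n, 1, 0.4), n, n),
       b = matrix(rbinom(n * n, 1, 0.4), n, n))
}
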
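# Independent oracles, deliberately naive: direct summations and scalar
# loops, sharing no code with the implementation they check.

# Direct evaluation of the windowed-transform double sum: for each time
# shift m (1-based segment start) and each one-sided frequency bin k,
#   S(k, m) = | sum_n x[n] * W[n - m] * exp(-i * 2*pi*k/Nfft * n) |^2
# using absolute sample indices n (the phase differs from an fft of the
# extracted segment by a unimodular factor, so squared magnitudes agree).
stft_bruteforce <- function(x, fft_length, segment_length, hop) {
  taper <- signal::hanning(segment_length)
  starts <- seq.int(1L, length(x) - segment_length + 1L, by = hop)
  nbin <- fft_length / 2 + 1
  out <- matrix(0, nbin, length(starts))
  for (mi in seq_along(starts)) {
    m <- starts[mi]
    n_idx <- m:(m + segment_length - 1L)
    w_x <- x[n_idx] * taper
    for (k in seq_len(nbin)) {
      omega <- 2 * pi * (k - 1) / fft_length
      s <- sum(w_x * exp(-1i * omega * (n_idx - 1)))
      out[k, mi] <- Mod(s)^2
    }
  }
  out
}

# Scalar element-wise walk through the five gate equations (peephole form),
# or the standard form when peephole = FALSE.
lstm_cell_bruteforce <- function(x, h_prev, c_prev, w, peephole = TRUE) {
  H <- length(h_prev)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(H); cc <- numeric(H)
  i_g <- numeric(H); f_g <- numeric(H)
  for (u in 1:H) {
    pi_term <- if (peephole) sum(w$Whi[u, ] * c_prev) else sum(w$Whi[u, ] * h_prev)
    i_g[u] <- sig(sum(w$Wxi[u, ] * x) + pi_term + w$bi[u])
    f_term <- sum(w$Wxf[u, ] * x) + sum(w$Whf[u, ] * h_prev) + w$bf[u]
    if (peephole) f_term <- f_term + sum(w$Wcf[u, ] * c_prev)
    f_g[u] <- sig(f_term)
    g <- tanh(sum(w$Wxc[u, ] * x) + sum(w$Whc[u, ] * h_prev) + w$bc[u])
    cc[u] <- f_g[u] * c_prev[u] + i_g[u] * g
  }
  for (u in 1:H) {
    o_term <- sum(w$Wxo[u, ] * x) + sum(w$Who[u, ] * h_prev) + w$bo[u]
    if (peephole) o_term <- o_term + sum(w$Wco[u, ] * cc)
    o <- sig(o_term)
    h[u] <- o * tanh(cc[u])
  }
  list(h = h, c = cc)
}

# Random labelled feature set with independent Gaussian rows per class.
random_feature_set <- function(n_per_class = 20, p = 8, seed = 1,
                               classes = c("ST", "SI", "WA"), shift = 0) {
  set.seed(seed)
  mats <- lapply(seq_along(classes), function(k) {
    matrix(rnorm(n_per_class * p, mean = shift * k), n_per_class, p)
  })
  feature_set(do.call(rbind, mats),
              rep(classes, each = n_per_class), provenance = "OR")
}

# Tiny, clearly separable two-class set for classifier sanity checks.
separable_feature_set <- function(n = 12, p = 8, seed = 3) {
  set.seed(seed)
  a <- matrix(rnorm(n * p, mean = -2, sd = 0.2), n, p)
  b <- matrix(rnorm(n * p, mean = 2, sd = 0.2), n, p)
  feature_set(rbind(a, b), rep(c("ST", "SI"), each = n), provenance = "OR")
}
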
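# Independent oracles, written with explicit scalar loops and no shared code
# with the package internals.

# Brute-force polar distribution score: loops only.
pds_bruteforce <- function(x, y, cx, cy, n_bins = 8) {
  n <- length(x)
  angles <- numeric(n)
  for (i in seq_len(n)) angles[i] <- atan2(y[i] - cy, x[i] - cx)
  ssum <- 0; csum <- 0
  for (i in seq_len(n)) {
    ssum <- ssum + sin(angles[i]); csum <- csum + cos(angles[i])
  }
  mu <- if (sqrt((ssum / n)^2 + (csum / n)^2) < 1e-8) 0 else
    atan2(ssum / n, csum / n)
  counts <- rep(0, n_bins)
  width <- 2 * pi / n_bins
  for (i in seq_len(n)) {
    a <- angles[i] - mu
    while (a <= -pi) a <- a + 2 * pi
    while (a > pi) a <- a - 2 * pi
    b <- 1
    while (b < n_bins && a >= -pi + b * width) b <- b + 1
    # top edge pi belongs with -pi (first sector)
    if (b == n_bins && a >= pi) b <- 1
    counts[b] <- counts[b] + 1
  }
  score <- 0
  for (b in seq_len(n_bins)) score <- score + abs(counts[b] / n - 1 / n_bins)
  score
}

# Second-moment length of a rendered rod, in pixels: for a uniform rod of
# length L blurred by a Gaussian of sd sigma, the intensity variance along
# the rod axis is L^2/12 + sigma^2, so L = sqrt(12 * (var - sigma^2)).
rod_length_moment <- function(img, background, sigma_px) {
  fr <- img - background
  px <- which(fr > 0.05 * max(fr), arr.ind = TRUE)
  w <- fr[px]; w <- w / sum(w)
  mu <- colSums(px * w)
  cc <- sweep(px, 2, mu)
  S <- t(cc) %*% (cc * w)
  v_along <- eigen(S, symmetric = TRUE)$values[1]
  sqrt(12 * max(v_along - sigma_px^2, 0))
}

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments (tiny n only).
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * length(y) / 2
  us <- apply(idx, 2, function(ii) {
    sum(rank(pooled)[ii]) - n * (n + 1) / 2
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
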
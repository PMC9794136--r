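# Independent oracles kept deliberately separate from the package's own
# implementations: generic weighted least squares through lm(), a brute-force
# cumulative-weight walk for the weighted median, a fine-grid kernel argmax
# for the mode, and exhaustive configuration enumeration for colocalization.

wls_origin <- function(bx, by, w) unname(coef(lm(by ~ bx - 1, weights = w)))
wls_free <- function(bx, by, w) unname(coef(lm(by ~ bx, weights = w)))

median_walk <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]; w <- weights[ord] / sum(weights)
  csum <- 0
  for (i in seq_along(r)) {
    centre <- csum + w[i] / 2
    if (centre >= 0.5) {
      if (i == 1) return(r[1])
      prev <- csum - w[i - 1] / 2
      return(r[i - 1] + (r[i] - r[i - 1]) * (0.5 - prev) / (centre - prev))
    }
    csum <- csum + w[i]
  }
  r[length(r)]
}

grid_mode <- function(ratios, weights, bandwidth, n_grid = 20000) {
  grid <- seq(min(ratios) - 3 * bandwidth, max(ratios) + 3 * bandwidth,
              length.out = n_grid)
  dens <- sapply(grid, function(x)
    sum(weights / sum(weights) * dnorm((x - ratios) / bandwidth)))
  grid[which.max(dens)]
}

silverman_bw <- function(ratios) {
  s <- sd(ratios); m <- mad(ratios)
  if (m == 0) m <- s
  0.9 * min(s, m) * length(ratios)^(-1 / 5)
}

enum_coloc <- function(z1, se1, z2, se2, p1, p2, p12, sd1, sd2) {
  abf1 <- exp(wakefield_labf(z1, se1, sd1))
  abf2 <- exp(wakefield_labf(z2, se2, sd2))
  n <- length(z1)
  h <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (i in seq_len(n)) {
    h["H1"] <- h["H1"] + p1 * abf1[i]
    h["H2"] <- h["H2"] + p2 * abf2[i]
    h["H4"] <- h["H4"] + p12 * abf1[i] * abf2[i]
    for (j in seq_len(n)) {
      if (i != j) h["H3"] <- h["H3"] + p1 * p2 * abf1[i] * abf2[j]
    }
  }
  h / sum(h)
}
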
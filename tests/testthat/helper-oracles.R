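# Independent oracles shared across test files. Each is a deliberately
# brute-force or closed-form counterpart to an implementation path.

# exhaustive between-class variance scan over all 256 thresholds
otsu_oracle <- function(gray) {
  g <- as.integer(round(gray))
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(g); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# O(n^2) pairwise concordance with half credit for ties
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# ridge as plain OLS on the sqrt(lambda)-augmented design
ridge_oracle <- function(X, y, lambda) {
  Xa <- rbind(X, sqrt(lambda) * diag(ncol(X)))
  unname(qr.solve(Xa, c(y, rep(0, ncol(X)))))
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

std_pop <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
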
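# independent brute-force implementations used as oracles
oracle_corr <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  num / (sqrt(sum((a - ma)^2)) * sqrt(sum((b - mb)^2)))
}
oracle_mape <- function(y, yhat, guard = 1e-3) {
  acc <- 0; n <- 0
  for (i in seq_along(y)) {
    if (abs(y[i]) >= guard) { acc <- acc + abs(y[i] - yhat[i]) / abs(y[i]); n <- n + 1 }
  }
  acc / n
}
oracle_rmse <- function(y, yhat) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + (y[i] - yhat[i])^2
  sqrt(acc / length(y))
}
oracle_skew <- function(x) {
  m <- sum(x) / length(x)
  m2 <- sum((x - m)^2) / length(x)
  m3 <- sum((x - m)^3) / length(x)
  m3 / m2^1.5
}
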
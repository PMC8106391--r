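# Independent brute-force oracles, kept deliberately naive (explicit loops,
# normal equations) so they share no code path with the implementation.

oracle_mk <- function(x) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) for (k in (i + 1):n) {
    d <- x[k] - x[i]
    S <- S + if (d > 0) 1 else if (d < 0) -1 else 0
  }
  tie_term <- 0
  for (v in unique(x)) {
    t <- sum(x == v)
    if (t > 1) tie_term <- tie_term + t * (t - 1) * (2 * t + 5)
  }
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  list(S = S, var_s = var_s)
}

oracle_mk_z <- function(x) {
  st <- oracle_mk(x)
  if (st$S > 0) (st$S - 1) / sqrt(st$var_s)
  else if (st$S < 0) (st$S + 1) / sqrt(st$var_s)
  else 0
}

oracle_theil_sen <- function(x, t = seq_along(x)) {
  slopes <- c()
  n <- length(x)
  for (j in seq_len(n - 1)) for (i in (j + 1):n)
    slopes <- c(slopes, (x[i] - x[j]) / (t[i] - t[j]))
  median(slopes)
}

oracle_lm_noint <- function(X, y) {
  drop(solve(t(X) %*% X) %*% (t(X) %*% y))
}

# central Savitzky-Golay weights from the polynomial normal equations
oracle_sg_weights <- function(window, order) {
  h <- (window - 1) / 2
  A <- outer(-h:h, 0:order, `^`)
  H <- A %*% solve(t(A) %*% A) %*% t(A)
  H[h + 1, ]
}
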
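# shared oracles, independent of the implementation paths they check

# bracketed bisection root of the delay equation z^n e^{-z/2} = C on the
# ascending branch (z in (0, 2n)); C supplied on the log scale
bisectDelayRoot <- function(logC, n, tol = 1e-12) {
  g <- function(z) n * log(z) - z / 2 - logC
  lo <- 1e-12
  hi <- 2 * n
  if (g(hi) < 0) return(NA_real_)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, hi)) break
  }
  (lo + hi) / 2
}

# log C of the general delay equation, assembled independently in the test
logCOf <- function(x1, y, n) {
  if (y == 0) return(lgamma(n + 1) - log(x1))
  C1 <- x1 - y / (n - 1)
  C2 <- (3.25 + 7.5 / x1) * (1 - y / (11.8 + 8.2 * x1)) -
    1 / (11.8 + 8.2 * x1)
  num <- 1 + C2 * y
  if (C1 == 0 || num / C1 <= 0) return(NA_real_)
  log(abs(num)) + lgamma(n + 1) - log(abs(C1))
}

# root-mean-square distance between two mean-total curves, as a fraction
# of the initial total
rmsFrac <- function(a, b, total0) sqrt(mean((a - b)^2)) / total0
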
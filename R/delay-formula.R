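# The state-dependent time delay: closed-form solution of the lumped-chain
# passage-time equation via the Lambert W function, and the calibrated
# approximation of its C2 coefficient.

#' Delay-equation coefficients
#'
#' `coeffC1` computes C1 = x1 + y - n*y/(n-1) (equivalently x1 - y/(n-1)).
#' `alphaOf` and `betaOf` are the calibrated coefficient functions
#' alpha(x1) = 3.25 + 7.5/x1 and beta(x1) = 11.8 + 8.2*x1.  `coeffC2` is
#' the state-only approximation of C2 = 1 - k*tau2/(n-1):
#' \deqn{C_2(x_1, y) = \alpha(x_1)\,(1 - y/\beta(x_1)) - 1/\beta(x_1),}
#' which is monotonically decreasing in y, approaches alpha(x1) as y -> 0,
#' and equals -1/y exactly at the boundary y = beta(x1) - the calibrated
#' stand-in for the locus C1 = 0 (y = x1 (n-1)) where the delay equation
#' itself forces 1 + C2 y = 0.
#'
#' @param x1 copy number of the consumed species (>= 1 for `alphaOf`,
#'   `betaOf`, `coeffC2`).
#' @param y copy number of the imaginary (in-transit) species (>= 0).
#' @param n lumped chain length (>= 2).
#' @return Numeric vector.
#' @examples
#' coeffC1(20, 0, 9)          # 20
#' alphaOf(10)                # 4.0
#' betaOf(10)                 # 93.8
#' coeffC2(8, betaOf(8), 9)   # -1/betaOf(8)
#' @name delay-coefficients
NULL

#' @rdname delay-coefficients
#' @export
coeffC1 <- function(x1, y, n) {
  stopifnot(all(n >= 2))
  x1 + y - n * y / (n - 1)
}

#' @rdname delay-coefficients
#' @export
alphaOf <- function(x1) {
  stopifnot(all(x1 >= 1))
  3.25 + 7.5 / x1
}

#' @rdname delay-coefficients
#' @export
betaOf <- function(x1) {
  stopifnot(all(x1 >= 1))
  11.8 + 8.2 * x1
}

#' @rdname delay-coefficients
#' @export
coeffC2 <- function(x1, y, n) {
  stopifnot(all(x1 >= 1), all(y >= 0))
  a <- alphaOf(x1)
  b <- betaOf(x1)
  a * (1 - y / b) - 1 / b
}

# Principal-branch Lambert W for arguments in [-1/e, 0], by Halley
# iteration with a bounded step count; seeded with the branch-point series
# near -1/e, where naive fixed-point schemes oscillate without converging.
lambertW0 <- function(x) {
  minx <- -exp(-1)
  if (x < minx) {
    if (x > minx - 1e-12) x <- minx else return(NA_real_)
  }
  w <- if (x < -0.25) {
    p <- sqrt(2 * (exp(1) * x + 1))
    -1 + p - p^2 / 3
  } else x * exp(-x)
  for (i in 1:50) {
    ew <- exp(w)
    f <- w * ew - x
    if (f == 0) break
    dw <- f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
    if (!is.finite(dw)) break
    w <- w - dw
    if (abs(dw) < 1e-13 * (1 + abs(w))) break
  }
  w
}

# log of C = (1 + C2*y) * n! / C1 computed in log space so that n! never
# overflows; returns NA when C <= 0 (no root on the ascending branch).
logCoeffC <- function(x1, y, n, C2 = coeffC2(x1, y, n)) {
  C1 <- coeffC1(x1, y, n)
  num <- 1 + C2 * y
  if (num / C1 <= 0) return(NA_real_)
  log(abs(num)) + lgamma(n + 1) - log(abs(C1))
}

#' Closed-form state-dependent time delay
#'
#' Solves the lumped-chain delay equation
#' \deqn{z^n e^{-z/2} = C, \qquad z = k\,\tau_2,}
#' where \eqn{C = (1 + C_2 y)\, n! / C_1} (and \eqn{C = n!/x_1} when
#' `y = 0`), picking the root on the ascending branch via the principal
#' Lambert W branch: \eqn{\tau_2 = -\frac{2n}{k} W_0(-C^{1/n}/(2n))}.
#' That branch makes the delay increase as the copy number decreases and
#' increase with the in-transit count, matching the behaviour of exact
#' chain simulations.  Dispatch: `y = 0` uses \eqn{C = n!/x_1}; `C1 = 0`
#' uses the branch value \eqn{k\tau_2 = (n-1)(1 + 1/y)} obtained by setting
#' both sides of the equation to zero; otherwise the general C.
#'
#' Degenerate states: in the thin band where the approximated C turns
#' negative (between the zeros of C1 and 1 + C2 y) there is no root, and
#' for very small x1 the Lambert argument can drop below -1/e.  With
#' `strict = TRUE` (the default) these raise an error carrying the state
#' and the offending argument; with `strict = FALSE` (the simulation
#' engine's behaviour) they fall back to the C1 = 0 branch value or to the
#' branch-point cap z = 2n, respectively.
#'
#' @param x1 copy number of the consumed species, >= 1 (a consuming firing
#'   needs a molecule).
#' @param y copy number of the imaginary species (>= 0).
#' @param k effective per-step rate (1/time).
#' @param n lumped chain length (>= 2).
#' @param strict error (TRUE) or fall back (FALSE) on degenerate states.
#' @return The delay time tau2 (> 0), vectorized over the state arguments.
#' @examples
#' tau2ClosedForm(20, 0, 0.126, 9)
#' @export
tau2ClosedForm <- function(x1, y, k, n, strict = TRUE) {
  m <- max(length(x1), length(y), length(k), length(n))
  x1 <- rep_len(x1, m); y <- rep_len(y, m)
  k <- rep_len(k, m); n <- rep_len(as.integer(n), m)
  stopifnot(all(k > 0), all(n >= 2))
  if (any(x1 < 1))
    stop("x1 must be >= 1: the delay is evaluated at a consuming firing")
  out <- numeric(m)
  for (i in seq_len(m)) {
    if (y[i] == 0) {
      logC <- lgamma(n[i] + 1) - log(x1[i])
    } else {
      C1 <- coeffC1(x1[i], y[i], n[i])
      if (abs(C1) < 1e-12) {
        out[i] <- (n[i] - 1) * (1 + 1 / y[i]) / k[i]
        next
      }
      logC <- logCoeffC(x1[i], y[i], n[i])
      if (is.na(logC)) {
        if (strict)
          stop(sprintf(paste0("no positive root: C <= 0 at state x1 = %g, ",
                              "y = %g, n = %d (band between the zeros of C1 ",
                              "and 1 + C2*y)"), x1[i], y[i], n[i]))
        out[i] <- (n[i] - 1) * (1 + 1 / y[i]) / k[i]
        next
      }
    }
    arg <- -exp(logC / n[i]) / (2 * n[i])
    if (arg < -exp(-1)) {
      if (strict)
        stop(sprintf(paste0("Lambert W argument %.6g < -1/e at state ",
                            "x1 = %g, y = %g, k = %g, n = %d"),
                     arg, x1[i], y[i], k[i], n[i]))
      out[i] <- 2 * n[i] / k[i]
      next
    }
    out[i] <- -2 * n[i] * lambertW0(arg) / k[i]
  }
  out
}

#' Time delay of a consuming firing
#'
#' The delay attached to a delayed reaction is tau = tau2 - tau1, where
#' tau1 is the waiting time of the consuming firing drawn by the SSA and
#' tau2 the state-dependent passage time from [tau2ClosedForm()].  The
#' difference is floored at a tiny positive epsilon (1e-9 time units) so a
#' completion is always scheduled strictly after its firing.
#'
#' @param x1,y,k,n state and lumped-chain parameters, as in
#'   [tau2ClosedForm()].
#' @param tau1 waiting time of the consuming firing (>= 0).
#' @param strict see [tau2ClosedForm()].
#' @return The delay tau (>= 1e-9).
#' @export
stateDelay <- function(x1, y, k, n, tau1, strict = TRUE) {
  stopifnot(all(tau1 >= 0))
  pmax(tau2ClosedForm(x1, y, k, n, strict = strict) - tau1, 1e-9)
}

#' Harmonic-mean lumping of Michaelis-Menten parameters
#'
#' Lumps the per-step maximal rates and equilibrium constants of steps
#' 2..n into single effective values by the harmonic mean:
#' \eqn{\bar V = (n-1)/\sum 1/V_i}, \eqn{\bar K = (n-1)/\sum 1/K_i}.
#'
#' @param V,K numeric vectors over the lumped steps (all > 0, equal length).
#' @return Named numeric `c(Vbar, Kbar)`.
#' @examples
#' harmonicMeans(c(38.27, 73.44, 35.84, 9.31, 2.08),
#'               c(12185600, 11852800, 9164800, 6476800, 2073600))
#' @export
harmonicMeans <- function(V, K) {
  stopifnot(length(V) == length(K), all(V > 0), all(K > 0))
  c(Vbar = length(V) / sum(1 / V), Kbar = length(K) / sum(1 / K))
}

#' Effective per-step rate of a lumped Michaelis-Menten chain
#'
#' The in-transit molecules U are assumed evenly spread over the n - 1
#' lumped steps, so each step sees about U/(n-1) molecules and the
#' per-molecule rate is the Michaelis-Menten rate per substrate molecule
#' evaluated there:
#' \deqn{k_{\mathrm{eff}} = \bar V / (\bar K + U/(n-1)).}
#' In the pseudo-first-order regime (U << Kbar) this reduces to Vbar/Kbar.
#'
#' @param U current in-transit copy number (>= 0).
#' @param Vbar,Kbar harmonic-mean parameters from [harmonicMeans()].
#' @param n lumped chain length.
#' @return The effective rate (1/time).
#' @export
mmEffectiveRate <- function(U, Vbar, Kbar, n) {
  stopifnot(all(U >= 0), Vbar > 0, Kbar > 0, n >= 2)
  Vbar / (Kbar + U / (n - 1))
}
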
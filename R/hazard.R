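#' Partial-fraction decomposition of a linear-rational integrand
#'
#' On any interval where the migration fraction and both population
#' functions are simultaneously linear, every event hazard in the model is
#' of the form \deqn{(a_1 + b_1 t)(a_2 + b_2 t) / (a_3 + b_3 t),} which can
#' be rewritten as \eqn{c_0 + c_1 t + c_2/(a_3 + b_3 t)} and integrated in
#' closed form (polynomial plus logarithm).  When the denominator is
#' constant (\eqn{b_3 = 0}) the integrand is a pure quadratic polynomial;
#' the quadratic coefficient is then returned in `quad` and `c2` is zero.
#'
#' @param a1,b1,a2,b2,a3,b3 coefficients of the two numerator factors and
#'   the denominator.
#' @return A list with components `c0`, `c1`, `c2`, `quad`.
#' @examples
#' rational_decompose(1, 0, 1, 0, 1, 0)  # constant 1
#' rational_decompose(0, 1, 0, 1, 0, 1)  # t * t / t = t
#' @export
rational_decompose <- function(a1, b1, a2, b2, a3, b3) {
  if (a3 == 0 && b3 == 0) stop("degenerate denominator: a3 = b3 = 0")
  # numerator A + B t + C t^2
  A <- a1 * a2
  B <- a1 * b2 + a2 * b1
  C <- b1 * b2
  if (b3 == 0) {
    list(c0 = A / a3, c1 = B / a3, c2 = 0, quad = C / a3)
  } else {
    c1 <- C / b3
    c0 <- (B - a3 * c1) / b3
    c2 <- A - a3 * c0
    list(c0 = c0, c1 = c1, c2 = c2, quad = 0)
  }
}

#' Event hazard built from piecewise-linear demographic functions
#'
#' Represents an instantaneous event rate of the form
#' \deqn{h(t) = num_1(t) \, num_2(t) / den(t)} restricted to a time window,
#' with each component piecewise linear.  Coalescent hazards use
#' `num1 = num2 = NULL` (i.e. 1) and `den` the population function
#' \eqn{\nu(t)}; the per-pair rate is \eqn{1/\nu(t)} and callers scale by
#' the number of lineage pairs.  Backward migration hazards use
#' `num1 = m(t)` (emigrant fraction of the forward-time source side),
#' `num2 = \nu` of the backward-jump destination branch and `den` the total
#' \eqn{\nu} of the side the lineage currently occupies.
#'
#' The constructor precomputes the partition of the window into
#' sub-intervals on which all components are simultaneously linear,
#' the closed-form decomposition on each, and cumulative integrals at the
#' sub-interval boundaries.
#'
#' @param num1,num2 numerator [piecewise_linear()] factors or `NULL` for 1.
#' @param den denominator [piecewise_linear()] or `NULL` for 1; must be
#'   strictly positive wherever the numerator is nonzero.
#' @param window numeric length-2: the hazard is zero outside
#'   `[window[1], window[2]]`; `window[2]` may be `Inf`.
#' @return An object of class `"hazard"`.
#' @export
hazard <- function(num1 = NULL, num2 = NULL, den = NULL, window = c(0, Inf)) {
  stopifnot(length(window) == 2L, window[1] <= window[2], is.finite(window[1]))
  comps <- list(num1, num2, den)
  comps <- comps[!vapply(comps, is.null, logical(1L))]
  lo <- window[1]; hi <- window[2]
  bp <- sort(unique(unlist(lapply(comps, `[[`, "x"))))
  bp <- bp[bp > lo & bp < hi]
  bnd <- c(lo, bp, if (is.finite(hi)) hi)
  nseg <- length(bnd)            # last "segment" extends to hi (possibly Inf)
  # per-segment closed-form coefficients
  c0 <- c1 <- c2 <- qd <- A3 <- B3 <- numeric(nseg)
  haslog <- logical(nseg)
  for (k in seq_len(nseg)) {
    s <- bnd[k]
    e <- if (k < nseg) bnd[k + 1L] else hi
    p1 <- if (is.null(num1)) c(1, 0) else plf_linear_coefs(num1, s, e)
    p2 <- if (is.null(num2)) c(1, 0) else plf_linear_coefs(num2, s, e)
    p3 <- if (is.null(den))  c(1, 0) else plf_linear_coefs(den, s, e)
    numer_zero <- all(p1 == 0) || all(p2 == 0)
    if (numer_zero) next
    mid <- if (is.finite(e)) (s + e) / 2 else s + 1
    efin <- if (is.finite(e)) e else mid
    if (!is.null(den) && (p3[1] + p3[2] * s <= 0 || p3[1] + p3[2] * mid <= 0 ||
                          (e > s && p3[1] + p3[2] * efin <= 0)))
      stop("singular population: nu reaches zero on an occupied interval")
    d <- rational_decompose(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
    c0[k] <- d$c0; c1[k] <- d$c1; c2[k] <- d$c2; qd[k] <- d$quad
    A3[k] <- p3[1]; B3[k] <- p3[2]
    haslog[k] <- d$c2 != 0
  }
  h <- list(lo = lo, hi = hi, bnd = bnd, nseg = nseg,
            c0 = c0, c1 = c1, c2 = c2, qd = qd, a3 = A3, b3 = B3,
            haslog = haslog)
  # cumulative integral from lo at each boundary
  cum <- numeric(nseg)
  for (k in seq_len(nseg - 1L))
    cum[k + 1L] <- cum[k] + hz_seg_integral(h, k, bnd[k], bnd[k + 1L])
  h$cum <- cum
  # constant rate on the final segment (used when hi == Inf)
  h$rate_end <- hz_rate_at(h, nseg, bnd[nseg])
  class(h) <- "hazard"
  h
}

# integral of segment k's closed form over [s, t] (s, t inside the
# segment).  Written as a difference with log1p so that a nearly
# constant denominator (tiny b3, hence a huge c2/b3 factor) does not
# cancel catastrophically.
hz_seg_integral <- function(h, k, s, t) {
  dt <- t - s
  v <- h$c0[k] * dt + h$c1[k] / 2 * (t + s) * dt +
    h$qd[k] / 3 * (t * t + t * s + s * s) * dt
  if (h$haslog[k])
    v <- v + (h$c2[k] / h$b3[k]) *
      log1p(h$b3[k] * dt / (h$a3[k] + h$b3[k] * s))
  v
}

# instantaneous rate of segment k at time t
hz_rate_at <- function(h, k, t) {
  v <- h$c0[k] + h$c1[k] * t + h$qd[k] * t^2
  if (h$c2[k] != 0) v <- v + h$c2[k] / (h$a3[k] + h$b3[k] * t)
  v
}

# instantaneous hazard rate at arbitrary times (zero outside the window)
hazard_rate <- function(h, t, scale = 1) {
  out <- numeric(length(t))
  inside <- t >= h$lo & t <= h$hi
  if (any(inside)) {
    k <- findInterval(t[inside], h$bnd, rightmost.closed = FALSE)
    out[inside] <- mapply(function(kk, tt) hz_rate_at(h, kk, tt), k, t[inside])
  }
  out * scale
}

# cumulative integral of the (unscaled) hazard from window lo to t
hz_cum_at <- function(h, t) {
  if (t <= h$lo) return(0)
  if (t >= h$hi) t <- h$hi
  if (!is.finite(t)) stop("cumulative hazard at infinite time is not finite here")
  k <- findInterval(t, h$bnd, rightmost.closed = FALSE)
  k <- min(k, h$nseg)
  h$cum[k] + hz_seg_integral(h, k, h$bnd[k], t)
}

#' Integrate an event hazard over a time interval
#'
#' Exact analytic integral of the hazard rate on `[t0, t1]`, summed over
#' the sub-intervals on which all component functions are linear.
#'
#' @param h a [hazard()] object.
#' @param t0,t1 integration limits, `t0 <= t1`.
#' @param scale constant multiplier (e.g. the number of lineage pairs
#'   \eqn{\binom{l}{2}} for a coalescent hazard, or the lineage count for a
#'   migration hazard).
#' @return The nonnegative integral value.
#' @export
integrate_hazard <- function(h, t0, t1, scale = 1) {
  stopifnot(inherits(h, "hazard"), t0 <= t1)
  a <- max(t0, h$lo)
  b <- min(t1, h$hi)
  if (b <= a) return(0)
  if (!is.finite(b)) stop("upper limit must be finite (or below the window end)")
  scale * (hz_cum_at(h, b) - hz_cum_at(h, a))
}

#' Draw an event waiting time by inverse-transform sampling
#'
#' Solves \eqn{\int_{t_0}^{t} h(s)\,ds = -\log(1-u)} for \eqn{t}: the
#' waiting time of a non-homogeneous Poisson event with hazard `h`
#' (times `scale`), starting the clock at `t0`.  Returns `Inf` when the
#' total hazard available before `horizon` is smaller than the target, so
#' impossible events (zero scale, empty windows) naturally get an infinite
#' waiting time.
#'
#' Within the sub-interval whose cumulative hazard straddles the target the
#' closed-form cumulative (polynomial plus logarithmic terms) is inverted
#' by safeguarded root finding to near machine precision.
#'
#' @param h a [hazard()] object.
#' @param t0 starting time (present-backward).
#' @param u uniform variate in `[0, 1)`.
#' @param horizon events past this time are censored to `Inf`.
#' @param scale constant hazard multiplier, as in [integrate_hazard()].
#' @return Event time `>= t0`, or `Inf`.
#' @export
solve_waiting_time <- function(h, t0, u, horizon = Inf, scale = 1) {
  if (u < 0 || u >= 1) stop("u must lie in [0, 1)")
  if (scale <= 0) return(Inf)
  target <- -log1p(-u) / scale
  if (target == 0) return(hz_first_positive(h, t0))
  if (t0 >= h$hi) return(Inf)
  a <- max(t0, h$lo)
  base <- hz_cum_at(h, a)
  # cumulative available inside the window up to its (finite) end
  k0 <- findInterval(a, h$bnd, rightmost.closed = FALSE)
  k0 <- max(1L, min(k0, h$nseg))
  acc <- 0
  for (k in k0:h$nseg) {
    seg_hi <- if (k < h$nseg) h$bnd[k + 1L] else h$hi
    seg_lo <- max(a, h$bnd[k])
    if (is.finite(seg_hi)) {
      seg_int <- h$cum[k] + hz_seg_integral(h, k, h$bnd[k], seg_hi) -
        base - acc
      if (acc + seg_int >= target) {
        t <- hz_invert_segment(h, k, seg_lo, seg_hi, base + target)
        return(if (t <= horizon) t else Inf)
      }
      acc <- acc + seg_int
    } else {
      # final segment extends to infinity at constant rate
      r <- h$rate_end
      if (r <= 0) return(Inf)
      t <- seg_lo + (target - acc) / r
      return(if (t <= horizon) t else Inf)
    }
  }
  Inf  # window exhausted before reaching the target
}

# invert the cumulative hazard within segment k: find t in [lo, hi] with
# hz_cum_at(t) == want (want is in absolute cumulative units).  The
# cumulative is monotone and smooth, so Newton with a bisection safeguard
# converges quickly; the derivative is the closed-form rate itself.
hz_invert_segment <- function(h, k, lo, hi, want) {
  c0 <- h$c0[k]; c1h <- h$c1[k] / 2; qd3 <- h$qd[k] / 3
  c2 <- h$c2[k]; a3 <- h$a3[k]; b3 <- h$b3[k]
  haslog <- h$haslog[k]
  s <- h$bnd[k]; den_s <- a3 + b3 * s
  cumdiff <- function(t) {   # cum at t minus want, via stable differences
    dt <- t - s
    v <- h$cum[k] - want + c0 * dt + c1h * (t + s) * dt +
      qd3 * (t * t + t * s + s * s) * dt
    if (haslog) v + (c2 / b3) * log1p(b3 * dt / den_s) else v
  }
  if (cumdiff(lo) >= 0) return(lo)
  if (cumdiff(hi) <= 0) return(hi)
  a <- lo; b <- hi; t <- (lo + hi) / 2
  tol <- 1e-15 * (1 + abs(want))
  for (it in 1:100) {
    g <- cumdiff(t)
    if (abs(g) <= tol) break
    if (g > 0) b <- t else a <- t
    r <- (3 * qd3 * t + 2 * c1h) * t + c0
    if (haslog) r <- r + c2 / (a3 + b3 * t)
    tn <- if (r > 0) t - g / r else (a + b) / 2
    tn <- if (tn <= a || tn >= b) (a + b) / 2 else tn
    if (tn == t || b - a < 1e-14 * max(1, abs(b))) break
    t <- tn
  }
  t
}

# infimum time >= t0 with positive instantaneous hazard (u == 0 case)
hz_first_positive <- function(h, t0) {
  if (t0 >= h$hi) return(Inf)
  a <- max(t0, h$lo)
  k0 <- max(1L, min(findInterval(a, h$bnd), h$nseg))
  for (k in k0:h$nseg) {
    seg_lo <- max(a, h$bnd[k])
    seg_hi <- if (k < h$nseg) h$bnd[k + 1L] else min(h$hi, seg_lo + 1)
    if (hz_rate_at(h, k, seg_lo) > 0) return(seg_lo)
    mid <- (seg_lo + seg_hi) / 2
    if (hz_rate_at(h, k, mid) > 0 || hz_rate_at(h, k, seg_hi) > 0) {
      g <- function(t) hz_rate_at(h, k, t)
      tt <- seq(seg_lo, seg_hi, length.out = 65L)
      pos <- which(vapply(tt, g, 0) > 0)
      if (length(pos)) return(tt[pos[1L]])
    }
  }
  Inf
}
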
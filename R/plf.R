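#' Piecewise-linear function of time
#'
#' The backbone of all demographic quantities in the package: effective
#' population sizes \eqn{\nu(t)} and migration fractions \eqn{m(t)} are
#' nonnegative piecewise-linear functions of time (time runs backward from
#' the present, in the model's time unit, e.g. Myr).  The function is
#' linearly interpolated between breakpoints and extended as a constant
#' beyond the first and last breakpoint.
#'
#' @param breakpoints strictly increasing numeric vector of times.
#' @param values nonnegative values taken at the breakpoints.
#' @return An object of class `"plf"`.
#' @examples
#' f <- piecewise_linear(c(0, 1), c(2, 4))
#' plf_eval(f, 0.5)  # 3: linear interpolation
#' plf_eval(f, 5)    # 4: constant extension
#' @export
piecewise_linear <- function(breakpoints, values) {
  breakpoints <- as.numeric(breakpoints)
  values <- as.numeric(values)
  if (length(breakpoints) != length(values) || length(breakpoints) < 1L)
    stop("breakpoints and values must have equal, positive length")
  if (anyNA(breakpoints) || anyNA(values))
    stop("breakpoints and values must be finite")
  if (length(breakpoints) > 1L && any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing")
  if (any(values < 0))
    stop("values must be nonnegative")
  structure(list(x = breakpoints, y = values), class = "plf")
}

#' Constant function as a degenerate piecewise-linear function
#' @param value the constant (nonnegative) value.
#' @param at time at which the single breakpoint is placed (irrelevant for
#'   evaluation; kept for bookkeeping).
#' @export
plf_const <- function(value, at = 0) piecewise_linear(at, value)

#' Evaluate a piecewise-linear function
#'
#' @param f a [piecewise_linear()] object.
#' @param t numeric vector of times.
#' @return Values of `f` at `t`; linear interpolation between breakpoints,
#'   constant extension outside their range.
#' @export
plf_eval <- function(f, t) {
  stopifnot(inherits(f, "plf"))
  x <- f$x
  if (length(x) == 1L) return(rep.int(f$y, length(t)))
  tc <- pmin(pmax(t, x[1L]), x[length(x)])
  stats::approx(x, f$y, xout = tc, method = "linear", ties = "ordered")$y
}

#' @export
print.plf <- function(x, ...) {
  cat("piecewise-linear function,", length(x$x), "breakpoint(s)\n")
  print(data.frame(t = x$x, value = x$y), row.names = FALSE)
  invisible(x)
}

#' @export
as.function.plf <- function(x, ...) function(t) plf_eval(x, t)

# sum of piecewise-linear functions (again piecewise linear on the union
# of breakpoints, with constant extension preserved by evaluation)
plf_sum <- function(fs) {
  fs <- fs[!vapply(fs, is.null, logical(1L))]
  if (length(fs) == 0L) stop("nothing to sum")
  if (length(fs) == 1L) return(fs[[1L]])
  x <- sort(unique(unlist(lapply(fs, `[[`, "x"))))
  y <- rowSums(vapply(fs, plf_eval, numeric(length(x)), t = x))
  piecewise_linear(x, y)
}

# linear coefficients (a, b) of f(t) = a + b t on [s, e]; the interval must
# not straddle a breakpoint.  e may be Inf (constant extension).
plf_linear_coefs <- function(f, s, e) {
  vs <- plf_eval(f, s)
  if (!is.finite(e)) return(c(vs, 0))
  ve <- plf_eval(f, e)
  if (e <= s) return(c(vs, 0))
  b <- (ve - vs) / (e - s)
  c(vs - b * s, b)
}

#' Convert scaled population size to numbers of individuals
#'
#' Population sizes enter the coalescent as \eqn{\nu = N_e \tau}, the
#' effective size scaled by the generation time \eqn{\tau} expressed in the
#' model's time unit.  Given \eqn{\nu} and \eqn{\tau} this returns
#' \eqn{N_e = \nu / \tau}.  When time is measured in generations
#' (\eqn{\tau = 1}), \eqn{N_e} and \eqn{\nu} coincide.
#'
#' @param nu scaled population size (nonnegative).
#' @param tau generation time in the model's time unit (positive).
#' @return Effective population size in individuals.
#' @examples
#' pop_size_in_individuals(0.1, 1e-6)  # 1e5 individuals
#' @export
pop_size_in_individuals <- function(nu, tau) {
  if (!is.numeric(tau) || any(tau <= 0)) stop("invalid generation scale: tau must be > 0")
  if (any(nu < 0)) stop("nu must be nonnegative")
  nu / tau
}
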
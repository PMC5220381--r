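#' Fixed-point number format
#'
#' Describes a signed/unsigned two's-complement style fixed-point format with
#' \code{total_bits} total and \code{fraction_bits} fractional bits. Values
#' are held in R doubles as scaled integers; all representable magnitudes
#' stay well inside the exactly-representable integer range of a double.
#'
#' @param total_bits total word length (default 32).
#' @param fraction_bits fractional bits, \code{1 <= fraction_bits <
#'   total_bits} (default 16).
#' @param signed logical.
#' @return Object of class \code{fixed_format}.
#' @export
fixed_format <- function(total_bits = 32, fraction_bits = 16, signed = TRUE) {
  stopifnot(fraction_bits >= 1, fraction_bits < total_bits,
            total_bits <= 52)
  lim <- if (signed) c(-2^(total_bits - 1), 2^(total_bits - 1) - 1)
         else c(0, 2^total_bits - 1)
  structure(list(total_bits = total_bits, fraction_bits = fraction_bits,
                 signed = signed, int_min = lim[1], int_max = lim[2]),
            class = "fixed_format")
}

#' Quantize to / dequantize from fixed point
#'
#' Round-to-nearest conversion onto the \code{2^-fraction_bits} grid, so
#' \code{|fp_dequantize(fp_quantize(x)) - x| <= 2^-(fraction_bits+1)} for
#' in-range \code{x}. Out-of-range values saturate with a warning (the
#' hardware overflow policy).
#'
#' @param x numeric vector (real values for \code{fp_quantize}, scaled
#'   integers for \code{fp_dequantize}).
#' @param fmt a [fixed_format()].
#' @return \code{fp_quantize}: scaled integers; \code{fp_dequantize}: reals.
#' @export
fp_quantize <- function(x, fmt = fixed_format()) {
  q <- round(x * 2^fmt$fraction_bits)
  if (any(q < fmt$int_min | q > fmt$int_max)) {
    warning("fixed-point overflow: saturating")
    q <- pmin(pmax(q, fmt$int_min), fmt$int_max)
  }
  q
}

#' @rdname fp_quantize
#' @export
fp_dequantize <- function(x, fmt = fixed_format()) {
  x / 2^fmt$fraction_bits
}

# arithmetic shift of scaled integers (floor semantics, like hardware >>)
fp_shift <- function(q, s) {
  if (s >= 0) q * 2^s else floor(q / 2^(-s))
}

#' Evaluate a piecewise-linear function with shifts and adds only
#'
#' Emulates the hardware datapath for one segment evaluation: the quantized
#' input is shifted and accumulated per the slope's shift-add terms (no
#' multiplier), and the quantized intercept is added. The result deviates
#' from the floating evaluation by at most one truncation LSB per shift-add
#' term plus the intercept/input rounding, i.e. about
#' \code{(n_terms + 2) * 2^-fraction_bits}.
#'
#' @param plf a [piecewise_linear()] whose \code{shift_add} field is
#'   populated (e.g. built by [fit_piecewise()]).
#' @param v numeric vector of query points.
#' @param fmt a [fixed_format()].
#' @return dequantized values (reals on the fixed-point grid).
#' @export
fixed_evaluate_plf <- function(plf, v, fmt = fixed_format()) {
  stopifnot(inherits(plf, "plf"))
  if (is.null(plf$shift_add)) {
    stop("fixed_evaluate_plf: plf has no shift_add slope forms")
  }
  vc <- pmin(pmax(v, plf$domain[1]), plf$domain[2])
  idx <- findInterval(vc, plf$lo)
  idx[idx < 1L] <- 1L
  vq <- fp_quantize(vc, fmt)
  cq <- fp_quantize(plf$C, fmt)
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    sa <- plf$shift_add[[idx[i]]]
    acc <- cq[idx[i]]
    if (length(sa$shifts)) {
      for (j in seq_along(sa$shifts)) {
        acc <- acc + sa$signs[j] * fp_shift(vq[i], sa$shifts[j])
      }
    }
    out[i] <- acc
  }
  fp_dequantize(out, fmt)
}

# floor integer square root, exact for x < 2^52
isqrt <- function(x) {
  stopifnot(x >= 0, x < 2^52)
  s <- floor(sqrt(x))
  while ((s + 1)^2 <= x) s <- s + 1
  while (s^2 > x) s <- s - 1
  s
}

#' Cholesky factorization in emulated fixed-point arithmetic
#'
#' Mirrors a hardware Cholesky datapath whose square-root and divide units
#' produce integer results: before each square root or division the operand
#' is enlarged by a barrel shift of \code{prescale_bits}, and the integer
#' result is interpreted on a finer grid — factor entries carry
#' \code{(fraction_bits + prescale_bits)/2} fractional bits. The
#' reconstruction error of \eqn{L L^T} shrinks as \code{prescale_bits}
#' grows.
#'
#' @param P symmetric positive-definite matrix (entries representable in
#'   \code{fmt}).
#' @param fmt a [fixed_format()].
#' @param prescale_bits even, default \code{2 * fraction_bits}.
#' @return lower-triangular matrix of reals on the extended fixed-point
#'   grid; attribute \code{lsb} gives that grid's resolution.
#' @export
fixed_cholesky <- function(P, fmt = fixed_format(),
                           prescale_bits = 2 * fmt$fraction_bits) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P),
            prescale_bits %% 2 == 0, prescale_bits >= 0,
            max(abs(P - t(P))) < 1e-12)
  n <- nrow(P)
  F_ <- fmt$fraction_bits
  LF <- (F_ + prescale_bits) / 2
  stopifnot(LF == floor(LF))
  Pq <- matrix(fp_quantize(P, fmt), n, n)
  Lq <- matrix(0, n, n) # scaled by 2^LF
  # inputs are enlarged by the barrel shifter onto the 2^-2LF accumulator
  # grid, where products of factor entries are exact; the integer square
  # root and integer division then land results back on the 2^-LF grid
  for (j in seq_len(n)) {
    d <- fp_shift(Pq[j, j], 2 * LF - F_)
    for (k in seq_len(j - 1)) d <- d - Lq[j, k] * Lq[j, k]
    if (d <= 0) {
      stop("fixed_cholesky: non-positive pivot after quantization at column ", j)
    }
    Lq[j, j] <- isqrt(d)
    for (i in seq(j + 1, length.out = n - j)) {
      s <- fp_shift(Pq[i, j], 2 * LF - F_)
      for (k in seq_len(j - 1)) s <- s - Lq[i, k] * Lq[j, k]
      Lq[i, j] <- if (s >= 0) s %/% Lq[j, j] else -((-s) %/% Lq[j, j])
    }
  }
  L <- Lq / 2^LF
  attr(L, "lsb") <- 2^-LF
  L
}
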
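#' Piecewise-linear function with hardware-friendly slopes
#'
#' A continuous piecewise-linear map on a closed domain, stored as one row per
#' segment: \code{[v_lo, v_hi)} with value \eqn{K_i x + C_i}. Evaluation
#' outside the domain clamps to the boundary segment's endpoint value; a query
#' exactly on an interior breakpoint resolves to the right-hand segment.
#'
#' @param breakpoints interior breakpoints (strictly increasing, inside the
#'   domain); may be empty for a single segment.
#' @param slopes per-segment slopes \eqn{K_i} (length = n segments).
#' @param intercepts per-segment intercepts \eqn{C_i}. If only the first is
#'   supplied the rest are derived by continuity at each breakpoint.
#' @param domain length-2 numeric, the closed interval covered.
#' @param check_continuity require continuity at every breakpoint (within
#'   1e-9); set \code{FALSE} to represent deliberately discontinuous maps
#'   (a query on a jump then takes the right-hand segment's value).
#' @return Object of class \code{plf}.
#' @export
piecewise_linear <- function(slopes, intercepts, breakpoints = numeric(0),
                             domain = c(-120, 20), check_continuity = TRUE) {
  n <- length(slopes)
  stopifnot(n >= 1, length(breakpoints) == n - 1,
            domain[1] < domain[2],
            all(diff(c(domain[1], breakpoints, domain[2])) > 0))
  if (length(intercepts) == 1L && n > 1L) {
    intercepts <- chain_intercepts(slopes, intercepts, breakpoints)
  }
  stopifnot(length(intercepts) == n)
  lo <- c(domain[1], breakpoints)
  hi <- c(breakpoints, domain[2])
  # continuity check at interior breakpoints
  if (n > 1 && check_continuity) {
    left <- slopes[-n] * breakpoints + intercepts[-n]
    right <- slopes[-1] * breakpoints + intercepts[-1]
    if (any(abs(left - right) > 1e-9)) {
      stop("piecewise_linear: discontinuity at breakpoint ",
           breakpoints[which.max(abs(left - right))])
    }
  }
  structure(list(lo = lo, hi = hi, K = slopes, C = intercepts,
                 domain = domain, shift_add = NULL),
            class = "plf")
}

# derive C_2..C_n from continuity given C_1
chain_intercepts <- function(slopes, c1, breakpoints) {
  n <- length(slopes)
  C <- numeric(n)
  C[1] <- c1
  for (i in seq_len(n - 1)) {
    C[i + 1] <- C[i] + (slopes[i] - slopes[i + 1]) * breakpoints[i]
  }
  C
}

plf_matrix <- function(plf) {
  cbind(plf$lo, plf$hi, plf$K, plf$C, deparse.level = 0)
}

#' Evaluate a piecewise-linear function
#'
#' @param plf a [piecewise_linear()] object.
#' @param x numeric vector of query points.
#' @return numeric vector of values.
#' @export
plf_evaluate <- function(plf, x) {
  stopifnot(inherits(plf, "plf"))
  xc <- pmin(pmax(x, plf$domain[1]), plf$domain[2])
  # rightmost segment whose lower edge is <= x (ties go right)
  idx <- findInterval(xc, plf$lo, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  unname(plf$K[idx] * xc + plf$C[idx])
}

#' @export
print.plf <- function(x, ...) {
  cat(sprintf("<plf> %d segment(s) on [%g, %g]\n",
              length(x$K), x$domain[1], x$domain[2]))
  if (!is.null(x$shift_add)) cat("  slopes constrained to shift-add form\n")
  invisible(x)
}

#' Nearest shift-and-add representation of a slope
#'
#' Hardware multipliers are replaced by barrel shifts and adds, so every
#' slope must be a signed sum of at most \code{max_terms} powers of two,
#' \eqn{k = \sum \pm 2^{s}}, with shift exponents \eqn{s} inside
#' \code{shift_range}. The representable value nearest to \code{k} is found by
#' exhaustive enumeration; ties break toward fewer terms, then toward the
#' smaller absolute represented value.
#'
#' @param k the target slope.
#' @param max_terms maximum number of signed power-of-two terms (>= 1).
#' @param shift_range integer range of exponents, default \code{c(-10, 4)}.
#' @return Object of class \code{shift_add}: fields \code{value} (the
#'   represented slope, exact), \code{signs}, \code{shifts}.
#' @examples
#' quantize_slope(0.75)$value # 2^-1 + 2^-2 = 0.75 exactly
#' @export
quantize_slope <- function(k, max_terms = 3, shift_range = c(-10, 4)) {
  stopifnot(max_terms >= 1, length(shift_range) == 2)
  cand <- shift_add_candidates(max_terms, shift_range)
  err <- abs(cand$value - k)
  best <- which(err == min(err))
  if (length(best) > 1) { # fewer terms first, then smaller magnitude
    best <- best[order(cand$nterms[best], abs(cand$value[best]))][1]
  }
  terms <- cand$terms[[best]]
  structure(list(value = cand$value[best],
                 signs = terms$signs, shifts = terms$shifts,
                 target = k, error = cand$value[best] - k),
            class = "shift_add")
}

#' @export
print.shift_add <- function(x, ...) {
  if (length(x$shifts) == 0) {
    cat("<shift_add> 0\n")
  } else {
    cat("<shift_add>", paste0(ifelse(x$signs > 0, "+", "-"),
                              "2^", x$shifts, collapse = " "),
        "=", x$value, "\n")
  }
  invisible(x)
}

# Enumerate all representable values with <= max_terms signed powers of two.
# Cached per (max_terms, shift_range) in the package environment.
.sa_cache <- new.env(parent = emptyenv())
shift_add_candidates <- function(max_terms, shift_range) {
  key <- paste(max_terms, shift_range[1], shift_range[2], sep = ":")
  if (!is.null(.sa_cache[[key]])) return(.sa_cache[[key]])
  shifts <- seq(shift_range[1], shift_range[2])
  grow <- function(prev_vals, prev_terms) {
    out_v <- numeric(0); out_t <- list()
    for (i in seq_along(prev_vals)) {
      mx <- if (length(prev_terms[[i]]$shifts)) min(prev_terms[[i]]$shifts) else
        shift_range[2] + 1L
      for (s in shifts[shifts < mx]) { # strictly decreasing shifts: canonical
        for (sg in c(1L, -1L)) {
          out_v <- c(out_v, prev_vals[i] + sg * 2^s)
          out_t <- c(out_t, list(list(
            signs = c(prev_terms[[i]]$signs, sg),
            shifts = c(prev_terms[[i]]$shifts, s))))
        }
      }
    }
    list(v = out_v, t = out_t)
  }
  level_v <- 0; level_t <- list(list(signs = integer(0), shifts = integer(0)))
  all_v <- level_v; all_t <- level_t; all_n <- 0L
  for (m in seq_len(max_terms)) {
    g <- grow(level_v, level_t)
    level_v <- g$v; level_t <- g$t
    all_v <- c(all_v, level_v)
    all_t <- c(all_t, level_t)
    all_n <- c(all_n, rep(m, length(level_v)))
  }
  res <- list(value = all_v, terms = all_t, nterms = all_n)
  .sa_cache[[key]] <- res
  res
}

#' Fit a shift-add-constrained continuous piecewise-linear approximation
#'
#' Approximates a scalar map \code{f} on \code{domain} with \code{n_segments}
#' continuous linear pieces whose slopes are all representable in
#' shift-and-add form ([quantize_slope()]). Knots are placed by greedy
#' refinement: starting from one segment, the segment contributing the most
#' squared error is repeatedly split at its midpoint; after each refinement
#' the slopes are re-fit by least squares on a hinge basis, quantized, and the
#' free offset re-optimized, followed by a coordinate-descent pass over
#' neighbouring representable slope values. The best fit seen (by RMS error,
#' [err_cf()]) is retained, so increasing \code{n_segments} never worsens the
#' returned error.
#'
#' @param f vectorized scalar function to approximate.
#' @param domain length-2 interval.
#' @param n_segments number of linear pieces (>= 1).
#' @param max_terms,shift_range shift-add budget per slope.
#' @param M number of uniform sample points used to score fits.
#' @return A \code{plf} whose \code{shift_add} field stores one
#'   [quantize_slope()] form per segment; attribute \code{err_cf} holds the
#'   achieved RMS error.
#' @export
fit_piecewise <- function(f, domain, n_segments = 8,
                          max_terms = 3, shift_range = c(-10, 4),
                          M = 1000) {
  stopifnot(n_segments >= 1, M >= 2)
  x <- seq(domain[1], domain[2], length.out = M)
  y <- f(x)
  stopifnot(all(is.finite(y)))
  knots <- numeric(0)
  best <- NULL
  for (nseg in seq_len(n_segments)) {
    if (nseg > 1) {
      knots <- split_worst_segment(x, y, best$plf, knots, domain)
    }
    fit <- fit_with_knots(x, y, knots, domain, max_terms, shift_range)
    if (is.null(best) || fit$err <= best$err) best <- fit
  }
  plf <- best$plf
  attr(plf, "err_cf") <- best$err
  plf
}

# least-squares continuous PL fit on fixed knots, then slope quantization
fit_with_knots <- function(x, y, knots, domain, max_terms, shift_range) {
  n <- length(knots) + 1L
  # hinge basis: y ~ c + k1*x + sum_j d_j * pmax(x - knot_j, 0)
  X <- cbind(1, x)
  for (b in knots) X <- cbind(X, pmax(x - b, 0))
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  slopes_cont <- unname(cumsum(c(beta[2], if (n > 1) beta[-(1:2)] else NULL)))
  sa <- lapply(slopes_cont, quantize_slope, max_terms = max_terms,
               shift_range = shift_range)
  slopes <- vapply(sa, `[[`, numeric(1), "value")
  refit <- function(slopes) {
    # with slopes fixed and continuity enforced, only the offset is free
    C <- chain_intercepts(slopes, 0, knots)
    lo <- c(domain[1], knots)
    idx <- findInterval(x, lo)
    base <- slopes[idx] * x + C[idx]
    off <- mean(y - base)
    list(C = C + off, err = sqrt(mean((base + off - y)^2)))
  }
  cur <- refit(slopes)
  # coordinate descent over each slope's nearby representable values
  cand <- shift_add_candidates(max_terms, shift_range)
  ord <- order(cand$value)
  vals <- cand$value[ord]
  for (pass in 1:2) {
    improved <- FALSE
    for (j in seq_len(n)) {
      pos <- findInterval(slopes[j], vals)
      try_idx <- unique(pmin(pmax(seq(pos - 3, pos + 3), 1L), length(vals)))
      for (ti in try_idx) {
        trial <- slopes
        trial[j] <- vals[ti]
        r <- refit(trial)
        if (r$err < cur$err - 1e-15) {
          slopes <- trial; cur <- r; improved <- TRUE
          sa[[j]] <- cand$terms[[ord[ti]]]
          sa[[j]]$value <- vals[ti]
        }
      }
    }
    if (!improved) break
  }
  # normalize shift_add entries to full objects
  sa <- lapply(seq_len(n), function(j) {
    s <- sa[[j]]
    structure(list(value = slopes[j], signs = s$signs, shifts = s$shifts,
                   target = slopes[j], error = 0), class = "shift_add")
  })
  plf <- piecewise_linear(slopes, cur$C, knots, domain)
  plf$shift_add <- sa
  list(plf = plf, err = cur$err)
}

split_worst_segment <- function(x, y, plf, knots, domain) {
  res2 <- (plf_evaluate(plf, x) - y)^2
  edges <- c(domain[1], knots, domain[2])
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  sse <- tapply(res2, factor(idx, levels = seq_len(length(edges) - 1)),
                sum, default = 0)
  j <- which.max(sse)
  mid <- (edges[j] + edges[j + 1]) / 2
  sort(c(knots, mid))
}
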
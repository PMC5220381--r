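#' Build the cost-efficient (CETC) piecewise-linear TC function set
#'
#' Replaces each of the eight nonlinear terms of the reduced TC model —
#' \eqn{f_1 = m_\infty^3}, \eqn{f_2 = p_\infty^2} (voltage-dependent current
#' activations), \eqn{f_3(h) = (0.75(1-h))^4} (potassium activation tied to
#' \eqn{h}), \eqn{f_4 = h_\infty}, \eqn{f_5 = a_h}, \eqn{f_6 = b_h},
#' \eqn{f_7 = w_\infty} and \eqn{f_8 = 1/\tau_w} — by a continuous
#' piecewise-linear approximation whose slopes are all representable in
#' shift-and-add form, so that a hardware datapath needs no general
#' multipliers for the model constants. Fitting uses [fit_piecewise()];
#' alternatively an explicit coefficient table (e.g. hand-transcribed
#' segment tables, via [read_plf_tables()]) can be supplied and is used
#' verbatim.
#'
#' @param params a [tc_parameters()] with a closed-form gating set; its
#'   membrane constants are carried over unchanged.
#' @param n_segments segments per function (scalar or length-8 vector),
#'   default 8.
#' @param max_terms,shift_range shift-add budget per slope, see
#'   [quantize_slope()].
#' @param M sample points per function for fitting/scoring, default 1000.
#' @param v_domain voltage domain for the voltage-dependent functions (mV).
#' @param tables optional data.frame with columns
#'   \code{function_name, segment_index, v_lo, v_hi, K, C} giving explicit
#'   coefficients for all eight functions (\code{f1} ... \code{f8}).
#' @return A [tc_parameters()] whose function set is of class
#'   \code{cetc_set}; [approximation_report()] extracts the per-function
#'   error criteria.
#' @export
build_cetc <- function(params = tc_parameters(), n_segments = 8,
                       max_terms = 3, shift_range = c(-10, 4), M = 1000,
                       v_domain = c(-120, 20), tables = NULL) {
  stopifnot(inherits(params, "tc_parameters"),
            inherits(params$gating, "gating_set"))
  fn_names <- paste0("f", 1:8)
  domains <- c(rep(list(v_domain), 2), list(c(0, 1)), rep(list(v_domain), 5))
  originals <- lapply(1:8, function(i) {
    force(i)
    function(x) tc_f(params, i, x)
  })
  if (is.null(tables)) {
    n_segments <- rep_len(n_segments, 8)
    plfs <- lapply(1:8, function(i) {
      fit_piecewise(originals[[i]], domains[[i]], n_segments[i],
                    max_terms = max_terms, shift_range = shift_range, M = M)
    })
  } else {
    plfs <- lapply(fn_names, function(nm) {
      rows <- tables[tables$function_name == nm, , drop = FALSE]
      if (nrow(rows) == 0) stop("coefficient table missing function ", nm)
      rows <- rows[order(rows$segment_index), , drop = FALSE]
      piecewise_linear(rows$K, rows$C,
                       breakpoints = rows$v_lo[-1],
                       domain = c(rows$v_lo[1], rows$v_hi[nrow(rows)]))
    })
  }
  report <- data.frame(
    fn = fn_names,
    n_segments = vapply(plfs, function(p) length(p$K), integer(1)),
    err_cf = vapply(1:8, function(i)
      err_cf(plfs[[i]], originals[[i]], domains[[i]], M), numeric(1)),
    nerr_cf_pct = vapply(1:8, function(i)
      nerr_cf(plfs[[i]], originals[[i]], domains[[i]], M), numeric(1)),
    mae = vapply(1:8, function(i)
      mae_cf(plfs[[i]], originals[[i]], domains[[i]], M), numeric(1)),
    M = M)
  names(plfs) <- fn_names
  fns <- structure(list(tables = plfs, report = report,
                        source = params$gating),
                   class = "cetc_set")
  out <- params
  out$gating <- fns
  out
}

#' @export
print.cetc_set <- function(x, ...) {
  cat("<cetc_set> piecewise-linear TC function set (shift-add slopes)\n")
  cat(sprintf("  mean NERR_CF%% = %.4f over f1..f8 (M = %d)\n",
              mean(x$report$nerr_cf_pct), x$report$M[1]))
  invisible(x)
}

#' Approximation-error report of a CETC function set
#'
#' @param params a [tc_parameters()] built by [build_cetc()], or a
#'   \code{cetc_set}.
#' @return data.frame with one row per function: \code{fn, n_segments,
#'   err_cf, nerr_cf_pct, mae, M}.
#' @export
approximation_report <- function(params) {
  fns <- if (inherits(params, "tc_parameters")) params$gating else params
  stopifnot(inherits(fns, "cetc_set"))
  fns$report
}

#' Read / write CETC coefficient tables
#'
#' CSV exchange format for piecewise-linear coefficient tables, one row per
#' segment: \code{function_name, segment_index, v_lo, v_hi, K, C}.
#'
#' @param path CSV file path.
#' @return \code{read_plf_tables}: a data.frame suitable for the
#'   \code{tables} argument of [build_cetc()].
#' @export
read_plf_tables <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("function_name", "segment_index", "v_lo", "v_hi", "K", "C")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("coefficient table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}

#' @rdname read_plf_tables
#' @param params a [tc_parameters()] with a \code{cetc_set} function set.
#' @export
write_plf_tables <- function(params, path) {
  fns <- if (inherits(params, "tc_parameters")) params$gating else params
  stopifnot(inherits(fns, "cetc_set"))
  rows <- do.call(rbind, lapply(names(fns$tables), function(nm) {
    p <- fns$tables[[nm]]
    data.frame(function_name = nm, segment_index = seq_along(p$K),
               v_lo = p$lo, v_hi = p$hi, K = p$K, C = p$C)
  }))
  utils::write.csv(format(rows, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
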
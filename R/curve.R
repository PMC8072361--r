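#' Uniformly sampled concentration-time curve
#'
#' Container for a contrast-agent concentration-time curve sampled on a
#' uniform time grid, the common currency of all deconvolution routines in
#' this package. It holds the arterial input function \eqn{C_a(t)}, tissue
#' curves \eqn{C_t(t)} and fitted curves alike.
#'
#' @param times numeric vector of sample times in seconds, strictly
#'   increasing with a constant step.
#' @param values numeric vector of concentrations in mol/L, same length as
#'   `times`, all finite.
#' @return An object of class `perf_curve`: a list with elements `times`,
#'   `values` and the sampling interval `dt` (seconds).
#' @examples
#' cv <- perf_curve(seq(0, 10, by = 0.7), rexp(15))
#' cv$dt
#' @export
perf_curve <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2L)
    stop("a curve needs at least 2 samples")
  if (length(values) != length(times))
    stop("'times' and 'values' must have the same length")
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("curve times and values must be finite")
  steps <- diff(times)
  dt <- steps[1L]
  if (dt <= 0 || any(abs(steps - dt) > 1e-9))
    stop("'times' must be strictly increasing with a constant step (tol 1e-9)")
  structure(list(times = times, values = values, dt = dt),
            class = "perf_curve")
}

#' @export
print.perf_curve <- function(x, ...) {
  cat(sprintf("<perf_curve> %d samples, dt = %.4g s, t in [%.4g, %.4g] s\n",
              length(x$times), x$dt, x$times[1L], x$times[length(x$times)]))
  cat(sprintf("  values in [%.4g, %.4g] mol/L\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.perf_curve <- function(x, ...) {
  data.frame(time_s = x$times, conc_mol_per_L = x$values)
}

#' @export
plot.perf_curve <- function(x, ..., xlab = "time (s)",
                            ylab = "concentration (mol/L)", type = "l") {
  graphics::plot(x$times, x$values, xlab = xlab, ylab = ylab, type = type, ...)
}

#' @export
length.perf_curve <- function(x) length(x$times)

stopifnot_curve <- function(x, what = "curve") {
  if (!inherits(x, "perf_curve"))
    stop(sprintf("'%s' must be a perf_curve", what))
  invisible(x)
}

#' Read and write single-curve CSV files
#'
#' Curves travel as two-column CSV (`time_s`, `conc_mol_per_L`) with a
#' one-line header. Values round-trip to at least 1e-12 relative accuracy.
#' A file whose header lacks the units suffix is accepted with a warning
#' (mol/L assumed).
#'
#' @param path file path.
#' @return `read_curve()` returns a [perf_curve]; `write_curve()` returns
#'   `path` invisibly.
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("curve CSV needs two columns: time_s, conc_mol_per_L")
  nm <- names(df)
  if (!identical(nm[1:2], c("time_s", "conc_mol_per_L"))) {
    if (identical(nm[1L], "time_s")) {
      warning("no units in concentration header; assuming mol/L")
    } else {
      stop(sprintf("malformed curve CSV header: %s", paste(nm, collapse = ",")))
    }
  }
  tm <- as.numeric(df[[1L]])
  vl <- as.numeric(df[[2L]])
  bad <- which(!is.finite(tm) | !is.finite(vl))
  if (length(bad))
    stop(sprintf("non-finite value in curve CSV at data row %d", bad[1L]))
  if (any(diff(tm) <= 0))
    stop(sprintf("non-monotone time in curve CSV at data row %d",
                 which(diff(tm) <= 0)[1L] + 1L))
  perf_curve(tm, vl)
}

#' @rdname read_curve
#' @param curve a [perf_curve].
#' @export
write_curve <- function(curve, path) {
  stopifnot_curve(curve)
  df <- as.data.frame(curve)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
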
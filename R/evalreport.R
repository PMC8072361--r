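#' Ordinary least squares agreement regression
#'
#' Regression of MBF estimates on the ground truth: slope, intercept and
#' coefficient of determination (squared Pearson correlation).
#'
#' @param estimates,truth numeric vectors of equal length >= 3.
#' @return List of class `regression_stats`: `slope`, `intercept`
#'   (ml/min/g), `r2`.
#' @export
regression_stats <- function(estimates, truth) {
  if (length(estimates) != length(truth)) stop("length mismatch")
  if (length(truth) < 3L) stop("need at least 3 points")
  if (stats::var(truth) == 0) stop("constant truth: regression undefined")
  fit <- stats::lm.fit(cbind(1, truth), estimates)
  r <- stats::cor(estimates, truth)
  structure(list(slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 r2 = r^2),
            class = "regression_stats")
}

#' @export
print.regression_stats <- function(x, ...) {
  cat(sprintf("slope %.4f, intercept %.4f, r2 %.4f\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between estimates and truth as the product of the Pearson
#' correlation `rho` (precision) and the bias-correction factor `C_b`
#' (accuracy): `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with
#' population (1/n) moments. The 95\% confidence interval is obtained on the
#' Fisher z scale with standard error `1/sqrt(n - 3)`.
#'
#' @param estimates,truth numeric vectors of equal length >= 3.
#' @return List of class `agreement_stats`: `ccc`, `ccc_ci_low`,
#'   `ccc_ci_high`, `rho`, `cb`.
#' @export
lin_ccc <- function(estimates, truth) {
  x <- as.numeric(estimates); y <- as.numeric(truth)
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 3L) stop("need at least 3 points")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 || sy2 == 0) stop("zero variance: CCC undefined")
  sxy <- mean((x - mx) * (y - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  rho <- sxy / sqrt(sx2 * sy2)
  z <- atanh(ccc)
  se <- 1 / sqrt(n - 3)
  structure(list(ccc = ccc,
                 ccc_ci_low = tanh(z - 1.959964 * se),
                 ccc_ci_high = tanh(z + 1.959964 * se),
                 rho = rho, cb = ccc / rho),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("CCC %.4f (%.4f-%.4f), rho %.4f, Cb %.4f\n",
              x$ccc, x$ccc_ci_low, x$ccc_ci_high, x$rho, x$cb))
  invisible(x)
}

#' Per-tile relative error of MBF estimates
#'
#' Precision map of the phantom analysis: for each tile (one (Fp, Vp)
#' combination), the sample standard deviation (n-1 denominator) of the MBF
#' estimates of its noise realizations divided by the true MBF, in percent;
#' summarised by the average and maximum over tiles.
#'
#' @param estimates numeric matrix, one tile per row, one realization per
#'   column (>= 2 columns).
#' @param truth_mbf true MBF per tile (vector, length = rows of
#'   `estimates`).
#' @return List of class `relative_error_summary`: `map` (percent, per
#'   tile), `avg`, `max`.
#' @export
relative_error_summary <- function(estimates, truth_mbf) {
  estimates <- as.matrix(estimates)
  if (ncol(estimates) < 2L) stop("each tile needs >= 2 estimates")
  if (nrow(estimates) != length(truth_mbf)) stop("tile count mismatch")
  map <- 100 * apply(estimates, 1L, stats::sd) / truth_mbf
  structure(list(map = map, avg = mean(map), max = max(map)),
            class = "relative_error_summary")
}

#' @export
print.relative_error_summary <- function(x, ...) {
  cat(sprintf("relative error: avg %.2f%%, max %.2f%% over %d tiles\n",
              x$avg, x$max, length(x$map)))
  invisible(x)
}

#' Bolus arrival delay by the 10%-of-peak rule
#'
#' Measures the delay between contrast arrival in the artery and in the
#' tissue as the time between the moments each curve first reaches 10\% of
#' its own peak value, located sub-sample by linear interpolation (the
#' threshold is relative, so the measure is invariant to curve scaling).
#'
#' @param aif,tissue [perf_curve]s with positive peaks.
#' @return Delay in seconds (tissue arrival minus arterial arrival).
#' @export
measure_bat_10pct <- function(aif, tissue) {
  crossing_time <- function(cv) {
    v <- cv$values
    pk <- max(v)
    if (pk <= 0) stop("curve has no positive peak")
    thr <- 0.1 * pk
    i <- which(v >= thr)[1L]
    if (is.na(i)) stop("curve never crosses its 10% threshold")
    if (i == 1L) return(cv$times[1L])
    # linear interpolation between the last sub- and first supra-threshold
    t0 <- cv$times[i - 1L]; t1 <- cv$times[i]
    v0 <- v[i - 1L]; v1 <- v[i]
    t0 + (thr - v0) / (v1 - v0) * (t1 - t0)
  }
  crossing_time(tissue) - crossing_time(aif)
}

#' MBF histograms per region
#'
#' Bins an MBF map into fixed-width classes anchored at zero (clinical
#' display convention: 0.2 ml/min/g bins), optionally split by a region
#' label map. Empty regions yield empty histograms, not errors.
#'
#' @param mbf_map numeric vector or matrix of MBF values.
#' @param region_masks optional label map (same shape); `NA` labels are
#'   dropped.
#' @param bin_width histogram class width, ml/min/g.
#' @return Named list, one element per region: list with `breaks`, `counts`,
#'   `n`.
#' @export
mbf_histogram <- function(mbf_map, region_masks = NULL, bin_width = 0.2) {
  v <- as.numeric(mbf_map)
  if (is.null(region_masks)) {
    labs <- rep("all", length(v))
  } else {
    labs <- as.character(as.vector(region_masks))
    if (length(labs) != length(v)) stop("mask shape mismatch")
  }
  keep <- !is.na(labs)
  v <- v[keep]; labs <- labs[keep]
  regions <- sort(unique(labs))
  out <- lapply(regions, function(rg) {
    x <- v[labs == rg]
    if (!length(x)) {
      return(list(breaks = numeric(0), counts = integer(0), n = 0L))
    }
    nb <- floor(max(x) / bin_width) + 1L
    breaks <- seq(0, by = bin_width, length.out = nb + 1L)
    counts <- tabulate(pmin(floor(x / bin_width) + 1L, nb), nbins = nb)
    list(breaks = breaks, counts = counts, n = length(x))
  })
  names(out) <- regions
  out
}

#' Assemble the method x scale x delay comparison report
#'
#' Collects the per-condition agreement results into the nested comparison
#' layout (one row per method, noise scale and delay; regression,
#' concordance and relative-error columns plus runtime). Missing cells are
#' kept as explicit gap rows (`gap = TRUE`, statistics `NA`), never silently
#' dropped.
#'
#' @param results data.frame with columns `method`, `scale`, `delay_s` and
#'   any of `r2`, `slope`, `intercept`, `ccc`, `rho`, `cb`, `relerr_avg`,
#'   `relerr_max`, `runtime_s`.
#' @param methods,scales,delays expected levels of the three layout axes;
#'   default to the levels present in `results`. Passing the full design
#'   makes withheld or disabled cells appear as gap rows.
#' @return Object of class `comparison_report`: the completed data.frame
#'   (`$table`) ordered by method, scale, delay.
#' @export
compile_comparison_tables <- function(results, methods = NULL, scales = NULL,
                                      delays = NULL) {
  need <- c("method", "scale", "delay_s")
  if (!all(need %in% names(results)))
    stop("results must have method, scale and delay_s columns")
  stat_cols <- c("r2", "slope", "intercept", "ccc", "rho", "cb",
                 "relerr_avg", "relerr_max", "runtime_s")
  for (cc in stat_cols) if (!cc %in% names(results)) results[[cc]] <- NA_real_
  grid <- expand.grid(method = if (is.null(methods)) unique(results$method)
                               else methods,
                      scale = if (is.null(scales)) unique(results$scale)
                              else scales,
                      delay_s = if (is.null(delays))
                                  sort(unique(results$delay_s)) else delays,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- merge(grid, results[, c(need, stat_cols)], by = need,
               all.x = TRUE, sort = FALSE)
  tab <- tab[, c(need, stat_cols)]
  tab <- tab[order(tab$method, tab$scale, tab$delay_s), , drop = FALSE]
  rownames(tab) <- NULL
  tab$gap <- !stats::complete.cases(tab[, c("r2", "slope", "ccc")])
  structure(list(table = tab), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab)
  invisible(x)
}

#' Serialize a comparison report
#'
#' Writes `comparison_tables.csv` and `agreement.json` into `dir`.
#' Regenerating from the same results is byte-identical.
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "comparison_tables.csv")
  utils::write.csv(report$table, csv, row.names = FALSE, na = "GAP")
  js <- file.path(dir, "agreement.json")
  jsonlite::write_json(report$table, js, auto_unbox = TRUE, digits = NA,
                       na = "string", pretty = TRUE)
  invisible(c(csv, js))
}
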
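#' Saturation-recovery signal model parameters
#'
#' Parameters of the saturation-recovery signal equation
#' \eqn{S_N(R_1) = S_0 (1 - e^{-TD \cdot R_1})} used to convert the arterial
#' input signal to longitudinal relaxation rate, plus the linear relaxivity
#' relation used to convert \eqn{R_1} to gadolinium concentration.
#'
#' @param S0 proton-density weighted signal (arbitrary units), > 0.
#' @param TD saturation delay time in seconds, > 0 (AIF acquisition: 5 ms).
#' @param R1_baseline pre-contrast relaxation rate, 1/s.
#' @param relaxivity_r1 contrast agent longitudinal relaxivity in
#'   L/(mmol s); default 3.5, a conventional value for gadoterate at 3 T.
#' @return A list of class `sat_signal_params`.
#' @export
sat_signal_params <- function(S0, TD = 0.005, R1_baseline = 0.8,
                              relaxivity_r1 = 3.5) {
  if (S0 <= 0) stop("S0 must be > 0")
  if (TD <= 0) stop("TD must be > 0")
  if (relaxivity_r1 <= 0) stop("relaxivity_r1 must be > 0")
  structure(list(S0 = S0, TD = TD, R1_baseline = R1_baseline,
                 relaxivity_r1 = relaxivity_r1),
            class = "sat_signal_params")
}

#' Invert the saturation-recovery signal equation
#'
#' Solves \eqn{S_N = S_0(1 - e^{-TD \cdot R_1})} for \eqn{R_1}:
#' \eqn{R_1 = -\log(1 - S_N/S_0)/TD}. Signals at or above `S0` are
#' inconsistent with the model (saturation clipping) and raise an error.
#'
#' @param SN measured signal(s), `0 <= SN < S0`.
#' @param p a [sat_signal_params()].
#' @return Relaxation rate(s) \eqn{R_1} in 1/s.
#' @export
r1_from_saturation_signal <- function(SN, p) {
  if (!inherits(p, "sat_signal_params")) stop("'p' must be sat_signal_params")
  if (any(SN < 0)) stop("invalid signal: SN < 0")
  if (any(SN >= p$S0))
    stop("saturation clipping: SN >= S0 is inconsistent with the model")
  -log1p(-SN / p$S0) / p$TD
}

#' Convert relaxation rate to contrast-agent concentration
#'
#' Linear relaxivity relation \eqn{C = (R_1 - R_{1,base})/r_1}, floored at
#' zero. Rates slightly below baseline (noise) yield zero with a warning
#' attribute rather than a negative concentration.
#'
#' @param R1 relaxation rate(s), 1/s, >= 0.
#' @param p a [sat_signal_params()].
#' @return Concentration(s) in mmol/L, with attribute `floored` giving the
#'   indices clipped to zero (if any).
#' @export
concentration_from_r1 <- function(R1, p) {
  if (!inherits(p, "sat_signal_params")) stop("'p' must be sat_signal_params")
  if (any(R1 < 0)) stop("R1 must be >= 0")
  conc <- (R1 - p$R1_baseline) / p$relaxivity_r1
  neg <- which(conc < 0)
  conc[neg] <- 0
  if (length(neg)) attr(conc, "floored") <- neg
  conc
}
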
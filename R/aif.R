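#' Population arterial input function
#'
#' Bi-exponential population plasma curve
#' \deqn{C_p(t) = D\,(a_1 e^{-m_1 t} + a_2 e^{-m_2 t})}
#' with dose `D` in mmol/kg and Weinmann-type constants as defaults. A
#' population curve is used because per-patient AIF measurement is not part
#' of the standard clinical breast protocol.
#'
#' @param dose contrast dose in mmol/kg (default 0.1, Gd-DTPA standard).
#' @param a1,a2 amplitudes in kg/L.
#' @param m1,m2 decay rates in 1/min.
#' @return object of class `population_aif`.
#' @references Weinmann-type bi-exponential plasma clearance constants.
#' @export
population_aif <- function(dose = 0.1, a1 = 3.99, a2 = 4.78,
                           m1 = 0.144, m2 = 0.0111) {
  vals <- c(dose = dose, a1 = a1, a2 = a2, m1 = m1, m2 = m2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all AIF parameters must be positive and finite")
  structure(as.list(vals), class = "population_aif")
}

#' Plasma contrast concentration
#'
#' Evaluates the population AIF at times `t`.
#'
#' @param t time in minutes (vectorized); must be nonnegative.
#' @param aif a [population_aif()].
#' @return plasma concentration (mM-equivalent), same length as `t`.
#' @examples
#' aif_concentration(0, population_aif())  # dose * (a1 + a2)
#' @export
aif_concentration <- function(t, aif = population_aif()) {
  if (any(t < 0)) stop("time must be nonnegative")
  aif$dose * (aif$a1 * exp(-aif$m1 * t) + aif$a2 * exp(-aif$m2 * t))
}
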
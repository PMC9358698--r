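# Seasonal temperature and light drivers, Arrhenius rate correction and
# producer self-shading.

#' Seasonal forcing parameter set
#'
#' Cosine annual cycles for water temperature and surface irradiance, the
#' Arrhenius correction constants, and the self-shading strength.  The
#' defaults describe a temperate coastal sea: temperatures from a southern
#' North Sea monitoring station, irradiance from a Dutch coastal weather
#' station.
#'
#' @param T_min,T_max Annual minimum and maximum daily temperature (deg C).
#' @param t_Tmax Day of year of maximum temperature (d).
#' @param T_A Arrhenius temperature (K).
#' @param T_1 Reference temperature (K) at which rate parameters are
#'   stated.
#' @param JL_min,JL_max Annual minimum and maximum daily irradiance
#'   (MJ/m^2/d).
#' @param t_JLmax Day of year of maximum irradiance (d).
#' @param K_S Self-shading strength (L per umol C of producer structure).
#' @return A list of class \code{"forcing_params"}.
#' @export
forcing_params <- function(T_min = 2.85, T_max = 19.6, t_Tmax = 225,
                           T_A = 8000, T_1 = 293,
                           JL_min = 0.98, JL_max = 20.88, t_JLmax = 170,
                           K_S = 0.1) {
  if (T_max < T_min) stop("`T_max` must be >= `T_min`", call. = FALSE)
  if (JL_max < JL_min) stop("`JL_max` must be >= `JL_min`", call. = FALSE)
  if (T_A < 0) stop("`T_A` must be >= 0", call. = FALSE)
  if (T_1 <= 0) stop("`T_1` must be > 0", call. = FALSE)
  if (JL_min < 0) stop("irradiance must be >= 0", call. = FALSE)
  structure(list(T_min = T_min, T_max = T_max, t_Tmax = t_Tmax,
                 T_A = T_A, T_1 = T_1, JL_min = JL_min, JL_max = JL_max,
                 t_JLmax = t_JLmax, K_S = K_S),
            class = "forcing_params")
}

#' Seasonal water temperature
#'
#' Cosine annual cycle between \code{T_min} and \code{T_max}, peaking at
#' day \code{t_Tmax}, with a fixed 365-day year:
#' \deqn{T(t) = 273.15 + T_{min} + 0.5 (T_{max} - T_{min})
#'   (1 + \cos((t - t_{Tmax}) 2\pi/365)).}
#'
#' @param t Time (day); day-of-year phase, any non-negative value.
#' @param fp A [forcing_params()] object.
#' @return Absolute temperature (K).
#' @export
seasonal_temperature <- function(t, fp) {
  273.15 + fp$T_min + 0.5 * (fp$T_max - fp$T_min) *
    (1 + cos((t - fp$t_Tmax) * 2 * pi / 365))
}

#' Van 't Hoff-Arrhenius rate correction factor
#'
#' \eqn{\exp(T_A / T_1 - T_A / T)}: the factor by which every metabolic
#' rate stated at the reference temperature \code{T_1} is multiplied at
#' temperature \code{T}.  Equal to 1 at the reference temperature and
#' monotone increasing in \code{T}.
#'
#' @param T_kelvin Absolute temperature (K), \code{> 0}.
#' @param fp A [forcing_params()] object.
#' @return Dimensionless correction factor.
#' @export
arrhenius_factor <- function(T_kelvin, fp) {
  if (any(T_kelvin <= 0))
    stop("absolute temperature must be > 0", call. = FALSE)
  exp(fp$T_A / fp$T_1 - fp$T_A / T_kelvin)
}

#' Seasonal surface irradiance
#'
#' Cosine annual cycle between \code{JL_min} and \code{JL_max}, peaking at
#' day \code{t_JLmax}; same form as [seasonal_temperature()].
#'
#' @inheritParams seasonal_temperature
#' @return Incoming irradiance (MJ/m^2/d).
#' @export
seasonal_irradiance <- function(t, fp) {
  fp$JL_min + 0.5 * (fp$JL_max - fp$JL_min) *
    (1 + cos((t - fp$t_JLmax) * 2 * pi / 365))
}

#' Light available to the producer after self-shading
#'
#' Exponential attenuation of the incoming light by the producer's own
#' standing stock: \eqn{J_L = J_{L,in} \exp(-K_S M_{VP})}.  The negative
#' exponent makes available light decrease with producer biomass, which is
#' what self-shading means; with \code{K_S > 0} the factor is strictly
#' below 1 for any positive stock.
#'
#' @param JL_in Incoming irradiance (MJ/m^2/d), \code{>= 0}.
#' @param M_VP Producer structural mass (umol C/L), \code{>= 0}.
#' @param fp A [forcing_params()] object.
#' @return Available irradiance (MJ/m^2/d), \code{<= JL_in}.
#' @export
self_shaded_light <- function(JL_in, M_VP, fp) {
  if (any(JL_in < 0) || any(M_VP < 0))
    stop("irradiance and biomass must be >= 0", call. = FALSE)
  JL_in * exp(-fp$K_S * M_VP)
}
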
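# shared physical constants and small helpers

#' Thermal voltage RT/F in millivolts
#'
#' @param temperature_C temperature in degrees Celsius.
#' @return RT/F in mV (25.69 mV at 25 degrees C).
#' @export
rt_over_f <- function(temperature_C = 25) {
  R <- 8.314462618   # J / (mol K)
  FARADAY <- 96485.33212 # C / mol
  1000 * R * (temperature_C + 273.15) / FARADAY
}

# stop() with a consistent call-less style
abort_pc <- function(...) stop(..., call. = FALSE)

is_strictly_increasing <- function(x) all(diff(x) > 0)

# format numbers for lossless text round-trips
num_fmt <- function(x) formatC(x, format = "e", digits = 16)
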
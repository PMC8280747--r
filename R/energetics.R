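#' Free-energy difference from a binding-constant ratio
#'
#' Converts the ratio of two association constants into the corresponding
#' free-energy difference, `R T ln(K_high / K_low)`, in kJ/mol.  With a
#' thousand-fold vs ten-fold constant the gap is about 11 kJ/mol; a
#' ten-fold ratio alone gives about 5.7 kJ/mol at 298.15 K.  Negative when
#' `k_high < k_low`.
#'
#' @param k_high,k_low Association constants, per molar (> 0).
#' @param temperature Temperature, K (> 0; default 298.15).
#' @return Free-energy difference, kJ/mol.
#' @export
#' @examples
#' delta_g_from_ratio(1e3, 10)   # ~11.4 kJ/mol
#' delta_g_from_ratio(100, 10)   # ~5.7 kJ/mol
delta_g_from_ratio <- function(k_high, k_low, temperature = 298.15) {
  if (any(c(k_high, k_low, temperature) <= 0)) {
    abort("binding constants and temperature must be > 0")
  }
  R <- 8.314462618 # J / (mol K)
  R * temperature * log(k_high / k_low) / 1000
}
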
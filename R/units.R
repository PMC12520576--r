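# Unit helpers. User-facing interfaces speak um / mm / Hz / V / mL/h;
# everything internal is SI (m, s, kg, N). Conversions are exact
# multiplications so round-trips are bit-stable.

um_to_m <- function(x) x * 1e-6
m_to_um <- function(x) x * 1e6
mm_to_m <- function(x) x * 1e-3
m_to_mm <- function(x) x * 1e3

# mL/h -> m^3/s
mlh_to_m3s <- function(x) x * 1e-6 / 3600
m3s_to_mlh <- function(x) x * 3600 / 1e-6

# cells/mL -> cells/m^3
per_ml_to_per_m3 <- function(x) x * 1e6

#' Derive a reproducible sub-stream seed for a named stage
#'
#' One master seed drives a simulation; each stage (spectrum, satellites,
#' noise, ...) draws from its own deterministic sub-stream so that changing
#' e.g. the noise model does not perturb the sampled wavelengths.
#'
#' @param seed master integer seed
#' @param stage character stage label
#' @return an integer seed in [0, 2^31)
#' @keywords internal
sub_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}
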
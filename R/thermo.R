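## Conversion of state populations into free-energy differences.

#' Free-energy difference between two conformational equilibria
#'
#' For two conditions a and b, each an equilibrium between an on- and an
#' off-state with on-state fraction f, the difference between the ddG
#' values of the off -> on transition is
#' RT [ ln(f_a / (1 - f_a)) - ln(f_b / (1 - f_b)) ].
#' The uncertainty is propagated to first order from the two population
#' SDs (d ddG / d f = RT / (f (1 - f))), reported both in quadrature and
#' as the linear sum (the conservative bound).
#'
#' @param fA on-state fraction under condition a (open interval (0, 1)).
#' @param fB on-state fraction under condition b.
#' @param sdA,sdB standard deviations of the fractions (default 0).
#' @param temperature temperature in K (default 328.15, i.e. 55 C, the
#'   temperature of the NMR and SANS measurements).
#' @param R gas constant in kcal/(mol K) (default 1.9872e-3).
#' @return list with \code{ddG} (kcal/mol), \code{errQuadrature},
#'   \code{errLinear}, \code{temperature}.
#' @examples
#' ddgFromPopulations(0.66, 0.34)$ddG   # ~0.865 kcal/mol
#' @export
ddgFromPopulations <- function(fA, fB, sdA = 0, sdB = 0,
                               temperature = 328.15, R = 1.9872e-3) {
  if (fA <= 0 || fA >= 1 || fB <= 0 || fB >= 1)
    stop("fractions must lie strictly between 0 and 1")
  if (temperature <= 0) stop("temperature must be > 0")
  RT <- R * temperature
  ddg <- RT * (log(fA / (1 - fA)) - log(fB / (1 - fB)))
  dA <- RT / (fA * (1 - fA)) * sdA
  dB <- RT / (fB * (1 - fB)) * sdB
  list(ddG = ddg, errQuadrature = sqrt(dA^2 + dB^2), errLinear = dA + dB,
       temperature = temperature)
}
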
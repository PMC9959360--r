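#' Polya-Gamma PG(1, z) random draws
#'
#' Exact rejection sampler for the Polya-Gamma distribution with shape 1,
#' the augmentation variable of Bernoulli logistic likelihoods: with
#' omega ~ PG(1, x'beta), the conditional for the regression coefficients
#' becomes exactly Gaussian. Moments for reference:
#' E omega = tanh(z/2)/(2z) and
#' Var omega = (sinh(z) - z) sech^2(z/2) / (4 z^3).
#'
#' @param z numeric vector of tilting parameters (one draw per element).
#' @return numeric vector of PG(1, z) draws.
#' @export
rpg <- function(z) {
  rpg_cpp(as.numeric(z))
}
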
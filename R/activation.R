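#' Sigmoid firing-rate activation
#'
#' The logistic firing-rate nonlinearity `r = 1 / (1 + exp(-slope * (input -
#' bias)))`, strictly increasing in the input with range (0, 1).  Default
#' slope 2 and bias 0.6 are used by every sigmoid-rate circuit in this
#' package.
#'
#' @param input Numeric vector of input drives.
#' @param slope Positive slope parameter (default 2).
#' @param bias Bias parameter (default 0.6).
#' @return Firing rates in (0, 1), same length as `input`.
#' @examples
#' sigmoid_rate(0.6) # 0.5 (input equals bias)
#' sigmoid_rate(1.1) # 1 / (1 + exp(-1))
#' @export
sigmoid_rate <- function(input, slope = 2, bias = 0.6) {
  if (!is.numeric(slope) || length(slope) != 1 || slope <= 0) {
    abort("`slope` must be a single positive number.")
  }
  if (any(!is.finite(input))) {
    abort("`input` must be finite.")
  }
  1 / (1 + exp(-slope * (input - bias)))
}

#' Softplus activation of the fly steering model
#'
#' The scaled softplus `f(x) = scale * log(1 + exp(slope * (x - shift)))`
#' used by the fly (PFL3) steering neurons.  Numerically stable for large
#' inputs.
#'
#' @param x Numeric vector of input drives.
#' @param scale,slope,shift Softplus parameters; defaults are the fly-model
#'   constants 29.23, 2.17 and 0.7.
#' @return Non-negative rates, same length as `x`.
#' @examples
#' fly_softplus(0.7) # 29.23 * log(2)
#' @export
fly_softplus <- function(x, scale = 29.23, slope = 2.17, shift = 0.7) {
  if (any(!is.finite(x))) {
    abort("`x` must be finite.")
  }
  t <- slope * (x - shift)
  scale * ifelse(t > 30, t + log1p(exp(-t)), log1p(exp(t)))
}
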
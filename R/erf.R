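#' Error function
#'
#' The standard mathematical error function
#' \eqn{\mathrm{erf}(x) = (2/\sqrt{\pi})\int_0^x e^{-u^2}\,du},
#' computed through the normal CDF as `2 * pnorm(x * sqrt(2)) - 1`.
#' `erf(beta)` is the week-to-week weight-persistence coefficient of the
#' body-weight recursion.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length; values in \[-1, 1\].
#' @seealso [weight_step()], [continuous_weight()]
#' @examples
#' erf(0)        # 0
#' erf(1.7096)   # persistence used by the fitted group model, ~0.984
#' @export
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Inverse error function
#'
#' @param p numeric vector in (-1, 1).
#' @return numeric vector with `erf(erfinv(p)) == p`.
#' @export
erfinv <- function(p) {
  stopifnot(is.numeric(p), all(abs(p) < 1))
  qnorm((p + 1) / 2) / sqrt(2)
}
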
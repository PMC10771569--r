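#' Conductivity models
#'
#' Electrical conductivity of a hydrogel or tissue region, either constant
#' or increasing with the local electric-field magnitude. The
#' field-dependent form captures the conductivity rise caused by membrane
#' electroporation: a smooth logistic transition from the low-field value
#' \code{sigma0} to the fully electroporated value \code{sigmaf}, centered
#' at \code{E_center} with width \code{E_width}.
#'
#' @param sigma0 Low-field conductivity (S/m). Default 0.4 S/m, the
#'   baseline liver value used for protocol screening.
#' @param sigmaf High-field (electroporated) conductivity (S/m). Default
#'   1.6 S/m. Must satisfy \code{sigmaf >= sigma0}.
#' @param form \code{"constant"} (always returns \code{sigma0}) or
#'   \code{"field_dependent"}.
#' @param E_center Transition midpoint (V/cm); at this field magnitude the
#'   conductivity is exactly \code{(sigma0 + sigmaf)/2}. Default 500 V/cm,
#'   inside the reversible-to-irreversible electroporation range.
#' @param E_width Transition width (V/cm), the logistic scale parameter.
#' @return An object of class \code{conductivity_model}.
#' @examples
#' m <- conductivity_model(form = "field_dependent")
#' sigma_of_E(m, 0)     # ~0.4
#' sigma_of_E(m, 500)   # 1.0, the midpoint
#' sigma_of_E(m, 5000)  # ~1.6
#' @export
conductivity_model <- function(sigma0 = 0.4, sigmaf = sigma0,
                               form = c("constant", "field_dependent"),
                               E_center = 500, E_width = 100) {
  form <- match.arg(form)
  if (!is.finite(sigma0) || sigma0 <= 0)
    stop("sigma0 must be a positive finite conductivity (S/m)")
  if (!is.finite(sigmaf) || sigmaf < sigma0)
    stop("sigmaf must be finite and >= sigma0")
  if (form == "field_dependent" && (!is.finite(E_width) || E_width <= 0))
    stop("E_width must be > 0 (V/cm)")
  structure(
    list(form = form, sigma0 = sigma0, sigmaf = sigmaf,
         E_center = E_center, E_width = E_width),
    class = "conductivity_model")
}

#' Evaluate conductivity at a field magnitude
#'
#' @param model A \code{\link{conductivity_model}}.
#' @param E Electric-field magnitude(s), V/cm; must be non-negative.
#' @return Conductivity in S/m, same length as \code{E}; always inside
#'   \code{[sigma0, sigmaf]} and non-decreasing in \code{E}.
#' @export
sigma_of_E <- function(model, E) {
  stopifnot(inherits(model, "conductivity_model"))
  if (any(!is.finite(E)) || any(E < 0))
    stop("E must be finite and >= 0 (V/cm)")
  if (model$form == "constant")
    return(rep(model$sigma0, length(E)))
  s <- stats::plogis((E - model$E_center) / model$E_width)
  model$sigma0 + (model$sigmaf - model$sigma0) * s
}

#' @export
print.conductivity_model <- function(x, ...) {
  if (x$form == "constant") {
    cat(sprintf("<conductivity_model> constant, sigma = %.4g S/m\n", x$sigma0))
  } else {
    cat(sprintf(
      "<conductivity_model> field-dependent, %.3g -> %.3g S/m (midpoint %g V/cm, width %g V/cm)\n",
      x$sigma0, x$sigmaf, x$E_center, x$E_width))
  }
  invisible(x)
}
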
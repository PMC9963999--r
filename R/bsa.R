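#' Body surface area from height and weight
#'
#' Computes BSA by one of three published formulas. Mosteller is the default
#' throughout the package (dominant in athlete pre-participation screening);
#' the formula used is recorded in every coefficient file so fitted models
#' remain self-describing.
#'
#' @param height Height in cm (vectorised).
#' @param weight Weight in kg (vectorised).
#' @param formula One of `"mosteller"`, `"dubois"`, `"haycock"`.
#'
#' @return BSA in m^2.
#'
#' @details
#' * Mosteller: \eqn{\sqrt{height \cdot weight / 3600}}
#' * DuBois: \eqn{0.007184 \cdot height^{0.725} \cdot weight^{0.425}}
#' * Haycock: \eqn{0.024265 \cdot height^{0.3964} \cdot weight^{0.5378}}
#'
#' @examples
#' compute_bsa(180, 72)                      # 1.897 m^2
#' compute_bsa(170, 60, formula = "haycock")
#' @export
compute_bsa <- function(height, weight,
                        formula = c("mosteller", "dubois", "haycock")) {
  formula <- match.arg(formula)
  if (any(!is.finite(height)) || any(!is.finite(weight)) ||
      any(height <= 0) || any(weight <= 0)) {
    abort("`height` and `weight` must be finite and strictly positive.")
  }
  switch(formula,
    mosteller = sqrt(height * weight / 3600),
    dubois    = 0.007184 * height^0.725 * weight^0.425,
    haycock   = 0.024265 * height^0.3964 * weight^0.5378
  )
}
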
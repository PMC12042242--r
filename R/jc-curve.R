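#' Critical current density curve of a bulk superconductor
#'
#' Describes how the critical current density Jc of the superconducting
#' material depends on the local magnetic flux density magnitude. Two models
#' are supported: a field-independent (`constant`) Jc, and the Kim model
#' `Jc(B) = Jc0 * B0 / (B0 + |B|)` in which Jc falls to half its zero-field
#' value at `|B| = B0`.
#'
#' @param model `"constant"` or `"kim"`.
#' @param Jc0 zero-field critical current density (A/m^2), positive.
#' @param B0 Kim half-decay field (T), required (positive) for the Kim model.
#' @return an object of class `jc_curve`.
#' @examples
#' jc <- jc_curve("kim", Jc0 = 2e8, B0 = 1.5)
#' eval_jc(jc, c(0, 1.5, 3))
#' @export
jc_curve <- function(model = c("constant", "kim"), Jc0, B0 = NULL) {
  model <- match.arg(model)
  .chk(is.numeric(Jc0) && length(Jc0) == 1 && Jc0 > 0, "Jc0 must be a positive scalar")
  if (model == "kim") {
    .chk(is.numeric(B0) && length(B0) == 1 && B0 > 0,
         "B0 must be a positive scalar for the Kim model")
  }
  structure(list(model = model, Jc0 = Jc0, B0 = B0), class = "jc_curve")
}

#' Evaluate a Jc curve at given flux density magnitudes
#'
#' @param jc a [jc_curve()].
#' @param B flux density magnitudes (T); absolute value is taken.
#' @return critical current densities (A/m^2), positive and non-increasing
#'   in `|B|`.
#' @export
eval_jc <- function(jc, B) {
  stopifnot(inherits(jc, "jc_curve"))
  B <- abs(B)
  switch(jc$model,
    constant = rep(jc$Jc0, length(B)),
    kim = jc$Jc0 * jc$B0 / (jc$B0 + B)
  )
}

#' @export
print.jc_curve <- function(x, ...) {
  cat("<jc_curve>", x$model, " Jc0 =", format(x$Jc0, digits = 4), "A/m^2")
  if (x$model == "kim") cat("  B0 =", x$B0, "T")
  cat("\n")
  invisible(x)
}
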
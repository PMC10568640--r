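#' Intensity-scale transforms
#'
#' Flow intensities in relative fluorescence units (RFU) span several
#' decades; density estimation and display work in a compressed space.
#' Three scales are supported:
#'
#' * `linear` — identity.
#' * `log10` — `log10(max(v, floor))`; the floor keeps zero/near-zero
#'   background events finite.
#' * `biexponential` — scaled inverse hyperbolic sine,
#'   `asinh(v / cofactor) / ln(10)`. Log-like above the cofactor, linear
#'   through zero, and closed-form invertible, which is what a log-like
#'   display scale needs for reporting cutpoints back in RFU.
#'
#' @param kind One of `"linear"`, `"log10"`, `"biexponential"`.
#' @param cofactor Positive RFU; biexponential compression scale
#'   (default 5 RFU).
#' @param floor Positive RFU; lower clamp for `log10` (default 0.1 RFU).
#' @return An object of class `transform_spec`.
#' @examples
#' sp <- transform_spec("biexponential", cofactor = 5)
#' apply_transform(c(0, 10, 1e4), sp)
#' @export
transform_spec <- function(kind = c("linear", "log10", "biexponential"),
                           cofactor = 5, floor = 0.1) {
  kind <- match.arg(kind)
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    md_stop("cofactor must be a positive scalar", "myodiff_config_error")
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    md_stop("floor must be a positive scalar", "myodiff_config_error")
  structure(list(kind = kind, cofactor = cofactor, floor = floor),
            class = "transform_spec")
}

#' Apply an intensity transform
#'
#' @param values Numeric vector of intensities (RFU). Must be finite.
#' @param spec A [transform_spec()].
#' @return Transformed numeric vector, monotone non-decreasing in `values`.
#' @export
apply_transform <- function(values, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  if (any(!is.finite(values)))
    md_stop("values must be finite", "myodiff_input_error")
  switch(spec$kind,
    linear = values,
    log10 = log10(pmax(values, spec$floor)),
    biexponential = asinh(values / spec$cofactor) / log(10)
  )
}

#' Invert an intensity transform
#'
#' Maps values from transformed space back to RFU; used to report density
#' cutpoints found in biexponential space on the instrument's linear scale.
#' The `log10` transform is invertible only above its floor.
#'
#' @param values Numeric vector in transformed units.
#' @param spec A [transform_spec()].
#' @return Numeric vector of intensities (RFU).
#' @export
invert_transform <- function(values, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  switch(spec$kind,
    linear = values,
    log10 = {
      out <- 10^values
      # tolerate round-off at the floor image itself
      if (any(out < spec$floor * (1 - 1e-9)))
        md_stop("log10 inversion requested below the floor image",
                "myodiff_domain_error")
      out
    },
    biexponential = sinh(values * log(10)) * spec$cofactor
  )
}
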
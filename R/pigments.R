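#' Photosynthetic pigment contents from absorbance readings
#'
#' Evaluates the standard spectrophotometric equations for chlorophyll
#' *a*, chlorophyll *b* and total carotenoids from absorbances at
#' 470 nm, 646.8 nm and 663.2 nm:
#' \deqn{Chl\,a = 12.25 A_{663.2} - 2.79 A_{646.8}}
#' \deqn{Chl\,b = 21.5 A_{646.8} - 5.1 A_{663.2}}
#' \deqn{Carotenoids = (100 A_{470} - 1.82\,Chl\,a - 85.02\,Chl\,b)/198}
#'
#' Physically impossible readings can yield negative contents; these are
#' returned as-is with a warning rather than clamped, so data problems
#' stay visible.
#'
#' @param a470,a646_8,a663_2 Non-negative absorbance readings
#'   (vectorized; recycled to a common length).
#' @return Data frame with columns `chl_a`, `chl_b`, `carotenoids` (same
#'   units as the calibration, typically ug/ml of extract).
#' @examples
#' pigment_contents(0.8, 0.3, 0.6)
#' @export
pigment_contents <- function(a470, a646_8, a663_2) {
  n <- max(length(a470), length(a646_8), length(a663_2))
  a470 <- rep_len(a470, n)
  a646_8 <- rep_len(a646_8, n)
  a663_2 <- rep_len(a663_2, n)
  if (any(a470 < 0) || any(a646_8 < 0) || any(a663_2 < 0))
    snet_stop("absorbance readings must be non-negative",
              "saltnet_domain_error")
  chl_a <- 12.25 * a663_2 - 2.79 * a646_8
  chl_b <- 21.5 * a646_8 - 5.1 * a663_2
  car <- (100 * a470 - 1.82 * chl_a - 85.02 * chl_b) / 198
  if (any(chl_a < 0) || any(chl_b < 0) || any(car < 0))
    snet_warn("negative pigment content(s); check the readings")
  data.frame(chl_a = chl_a, chl_b = chl_b, carotenoids = car)
}
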
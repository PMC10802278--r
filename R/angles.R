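#' Reduce an angle to a canonical range
#'
#' All angular bookkeeping in the package funnels through these two
#' reducers so that repeated wrapping cannot accumulate sub-0.1 degree
#' drift. Angles are stored in degrees throughout.
#'
#' @param x numeric vector of angles in degrees.
#' @return `wrap_360()` maps into `[0, 360)`; `wrap_180()` maps into
#'   `(-180, 180]`.
#' @examples
#' wrap_360(-166.7)   # 193.3
#' wrap_180(-333.4)   # 26.6
#' @export
wrap_360 <- function(x) {
  y <- x %% 360
  # guard against -1e-14 %% 360 == 360 under floating point
  y[y >= 360] <- y[y >= 360] - 360
  y
}

#' @rdname wrap_360
#' @export
wrap_180 <- function(x) {
  y <- wrap_360(x)
  y[y > 180] <- y[y > 180] - 360
  y
}

deg2rad <- function(x) x * pi / 180
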
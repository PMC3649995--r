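#' Prior grid over effect size and heterogeneity
#'
#' Builds the grid of `(phi, omega)` prior standard deviations for the
#' two-level normal prior on standardized effects: active-tissue effects are
#' `b_s ~ N(bbar, phi^2)` around a shared mean `bbar ~ N(0, omega^2)`. The
#' grid is the Cartesian product of a set of total effect sizes
#' (`sqrt(phi^2 + omega^2)`) and a set of heterogeneity fractions
#' (`phi^2 / (phi^2 + omega^2)`); a heterogeneity of 0 is the fixed-effects
#' model (identical effects in all active tissues). Grid weights are equal.
#'
#' The `"default"` grid allows only modest heterogeneity and is meant for
#' full configuration averaging; the `"lite"` grid spans heterogeneity up to
#' 1 to compensate for averaging over only the consistent and singleton
#' configurations.
#'
#' @param kind `"default"` or `"lite"`.
#' @param sizes Total standardized effect sizes (overrides the default set).
#' @param heterogeneity Heterogeneity fractions in \[0, 1\] (overrides the
#'   kind-specific set).
#' @return Tibble of class `bf_grid` with columns `phi`, `omega`, `weight`.
#' @examples
#' build_grid("default")
#' @export
build_grid <- function(kind = c("default", "lite"),
                       sizes = c(0.1, 0.2, 0.4, 0.8, 1.6),
                       heterogeneity = NULL) {
  kind <- match.arg(kind)
  if (is.null(heterogeneity)) {
    heterogeneity <- if (kind == "default") c(0, 0.25, 0.5) else c(0, 0.25, 0.5, 0.75, 1)
  }
  if (any(sizes < 0) || any(heterogeneity < 0) || any(heterogeneity > 1)) {
    stop("sizes must be >= 0 and heterogeneity fractions in [0, 1]")
  }
  gp <- tidyr::expand_grid(size = sizes, het = heterogeneity)
  grid <- tibble::tibble(
    phi = sqrt(gp$het) * gp$size,
    omega = sqrt(1 - gp$het) * gp$size,
    weight = 1 / nrow(gp)
  )
  class(grid) <- c("bf_grid", class(grid))
  grid
}

validate_grid <- function(grid) {
  stopifnot(is.data.frame(grid), all(c("phi", "omega", "weight") %in% names(grid)))
  if (any(grid$phi < 0) || any(grid$omega < 0)) stop("negative grid entries")
  if (abs(sum(grid$weight) - 1) > 1e-8) stop("grid weights must sum to 1")
  grid
}
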
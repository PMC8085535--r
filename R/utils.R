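# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tkr <- function(fmt, ..., class = "tkrfem_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_tkr("`%s` must be a finite numeric scalar", name)
  if (strict_lower && x <= lower)
    stop_tkr("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_tkr("`%s` must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stop_tkr("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

#' Round half away from zero
#'
#' Presentation rounding used for the sensitivity tables: ties round away
#' from zero (so 13.505 -> 13.51 and -8.195 -> -8.20), unlike base
#' [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' round_half_up(c(2.675, -2.675), 2)
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  y <- abs(x) * p
  # nudge values sitting a few ulps below a tie boundary (binary floats
  # cannot represent most decimal ties exactly)
  sign(x) * floor(y + 0.5 + y * 1e-12) / p
}

# 3x3 rotation matrix, right-handed, angle in degrees (Rodrigues)
rotation_matrix <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop_tkr("rotation axis has zero length")
  a <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# apply rigid transform: rotation R about pivot, then translation tr
transform_points <- function(pts, R = diag(3), pivot = c(0, 0, 0),
                             translation = c(0, 0, 0)) {
  sweep(sweep(pts, 2, pivot) %*% t(R), 2, pivot + translation, `+`)
}

# shortest decimal representation that round-trips to the same double
fmt_num <- function(x) {
  s <- sprintf("%.15g", x)
  long <- as.numeric(s) != x
  s[long] <- sprintf("%.17g", x[long])
  s
}
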
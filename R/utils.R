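#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

warn_ <- function(...) warning(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("`%s` must be a finite numeric scalar", name)
  if (positive && x <= 0)
    stop_("`%s` must be > 0", name)
  invisible(x)
}

## Orthonormal tangent basis at a unit direction `n` (3-vector).
tangent_basis <- function(n) {
  n <- n / sqrt(sum(n^2))
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    n[2] * e1[3] - n[3] * e1[2],
    n[3] * e1[1] - n[1] * e1[3],
    n[1] * e1[2] - n[2] * e1[1]
  )
  list(e1 = e1, e2 = e2, n = n)
}

## Place a point at tangent-plane offset (u, v) mm from the point R*n on a
## sphere of radius R (mm), re-projected onto the sphere.
sphere_offset <- function(n, u, v, radius) {
  b <- tangent_basis(n)
  p <- radius * b$n + u * b$e1 + v * b$e2
  radius * p / sqrt(sum(p^2))
}

euclid <- function(a, b) sqrt(sum((a - b)^2))
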
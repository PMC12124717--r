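# Internal numerical helpers and unit constants.

# CODATA-based conversion constants
.hartree_to_kcal <- 627.509474
.bohr_to_angstrom <- 0.529177211

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

# deterministic unit vector perpendicular to u: start from the coordinate
# axis least aligned with u and Gram-Schmidt it
perpendicular_axis <- function(u) {
  ax <- diag(3)[, which.min(abs(u))]
  unit_vector(ax - sum(ax * u) * u)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x)
}
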
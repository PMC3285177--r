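# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so callers can distinguish failure modes programmatically.
ck_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "catchkin_error", "error")))
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) ck_stop("cannot normalize a zero-length vector", "catchkin_degenerate")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# deg <-> rad
deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi
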
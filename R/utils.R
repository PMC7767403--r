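# Internal helpers shared across modules.

# Deterministically derive a 32-bit sub-seed from a base seed and a list of
# labels/indices, so every replicate / system / channel gets its own stream.
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    v <- if (is.character(p)) {
      codes <- utf8ToInt(p)
      sum(codes * seq_along(codes))
    } else {
      as.numeric(p)
    }
    # multiplicative congruential mix; doubles stay exact (< 2^53)
    h <- (h * 48271 + v + 1) %% 2147483647
  }
  as.integer(h)
}

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

# Rotation matrix about the z axis, degrees.
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0,
           sin(th),  cos(th), 0,
           0,        0,       1), 3, 3, byrow = TRUE)
}

# Rodrigues rotation matrix from an axis-angle vector (angle = |v| radians).
rot_axis_angle <- function(v) {
  th <- vec_norm(v)
  if (th < 1e-15) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
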
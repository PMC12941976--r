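# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_validation <- function(...) {
  stop(structure(class = c("xai_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
assert_finite <- function(x, what = "values") {
  bad <- which(!is.finite(x))
  if (length(bad)) {
    stop_validation(what, " contain non-finite entries (first offending index: ",
                    bad[1L], ")")
  }
  invisible(x)
}

# Morton (z-order) code for 3D coordinates quantised to `bits` bits per axis.
# Coordinates are mapped to [0, 2^bits - 1] over their joint bounding box.
# 10 bits per axis -> 30-bit codes, safely inside double precision integers.
morton_order <- function(points, bits = 10L) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  n_levels <- 2^bits
  rng <- apply(points, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1
  q <- sweep(sweep(points, 2L, rng[1L, ], "-"), 2L, span, "/")
  q <- pmin(floor(q * n_levels), n_levels - 1L)
  code <- numeric(nrow(points))
  for (b in seq_len(bits) - 1L) {
    bit <- floor(q / 2^b) %% 2
    code <- code + bit[, 1L] * 2^(3 * b + 2) + bit[, 2L] * 2^(3 * b + 1) +
      bit[, 3L] * 2^(3 * b)
  }
  order(code, seq_along(code))
}

# Shift a 3D array by integer offsets with zero padding (used by the small
# convolution fixtures).
shift3d <- function(x, dz, dy, dx) {
  d <- dim(x)
  out <- array(0, d)
  src <- list(seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L]))
  off <- c(dz, dy, dx)
  dst <- src
  for (ax in 1:3) {
    s <- src[[ax]] - off[ax]
    keep <- s >= 1L & s <= d[ax]
    src[[ax]] <- s[keep]
    dst[[ax]] <- which(keep)
  }
  if (all(lengths(src) > 0L)) {
    out[dst[[1L]], dst[[2L]], dst[[3L]]] <- x[src[[1L]], src[[2L]], src[[3L]]]
  }
  out
}

# "Same"-padded 3D cross-correlation with a (k,k,k) kernel, implemented as a
# sum of shifted copies; exact and fast enough for fixture-scale grids.
conv3d_same <- function(x, kernel) {
  k <- dim(kernel)
  stopifnot(length(k) == 3L)
  c0 <- (k + 1L) %/% 2L
  out <- array(0, dim(x))
  for (i in seq_len(k[1L])) for (j in seq_len(k[2L])) for (l in seq_len(k[3L])) {
    w <- kernel[i, j, l]
    if (w != 0) out <- out + w * shift3d(x, c0[1L] - i, c0[2L] - j, c0[3L] - l)
  }
  out
}

# Adjoint of conv3d_same: propagates an upstream gradient back to the input.
conv3d_same_backward <- function(grad_out, kernel) {
  k <- dim(kernel)
  c0 <- (k + 1L) %/% 2L
  out <- array(0, dim(grad_out))
  for (i in seq_len(k[1L])) for (j in seq_len(k[2L])) for (l in seq_len(k[3L])) {
    w <- kernel[i, j, l]
    if (w != 0) out <- out + w * shift3d(grad_out, i - c0[1L], j - c0[2L], l - c0[3L])
  }
  out
}

# Non-overlapping average pooling by integer factor f along each axis.
avgpool3d <- function(x, f) {
  d <- dim(x)
  stopifnot(all(d %% f == 0L))
  dn <- d %/% f
  idx <- lapply(dn, function(n) rep(seq_len(n), each = f))
  # collapse by summing within blocks via rowsum-style aperm reshaping
  out <- array(x, c(f, dn[1L], f, dn[2L], f, dn[3L]))
  out <- apply(out, c(2L, 4L, 6L), sum) / f^3
  array(out, dn)
}

# Adjoint of avgpool3d: spreads gradient uniformly over each block.
avgpool3d_backward <- function(grad_out, f) {
  dn <- dim(grad_out)
  g <- grad_out / f^3
  g <- g[rep(seq_len(dn[1L]), each = f), rep(seq_len(dn[2L]), each = f),
         rep(seq_len(dn[3L]), each = f), drop = FALSE]
  array(g, dn * f)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
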
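# Independent oracles and small fixture builders shared across the suite.

# Direct-summation 3D convolution, O(everything); trusted reference for the
# fast kernel on tiny inputs.
oracle_conv3d <- function(x, w, b, stride = 1L, pad = NULL) {
  k <- dim(w)[1]; ci <- dim(w)[4]; co <- dim(w)[5]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  d <- dim(x)
  od <- (d[1:3] + 2L * pad - k) %/% stride + 1L
  y <- array(0, c(od, co))
  for (c2 in 1:co) for (oz in 1:od[3]) for (oy in 1:od[2]) for (ox in 1:od[1]) {
    acc <- b[c2]
    for (c1 in 1:ci) for (kz in 1:k) for (ky in 1:k) for (kx in 1:k) {
      ix <- (ox - 1L) * stride + kx - pad
      iy <- (oy - 1L) * stride + ky - pad
      iz <- (oz - 1L) * stride + kz - pad
      if (ix >= 1 && ix <= d[1] && iy >= 1 && iy <= d[2] && iz >= 1 && iz <= d[3])
        acc <- acc + x[ix, iy, iz, c1] * w[kx, ky, kz, c1, c2]
    }
    y[ox, oy, oz, c2] <- acc
  }
  y
}

# Exhaustive pairwise Hausdorff distance between foreground voxel centres.
oracle_hausdorff <- function(pred, gt, spacing) {
  coords <- function(m) {
    idx <- which(m > 0.5, arr.ind = TRUE)
    sweep(idx - 1, 2, spacing, "*")
  }
  a <- coords(gt); b <- coords(pred)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0                         # floating cancellation
  dmat <- sqrt(d2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# Central finite-difference gradient of a scalar-valued function of one array.
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_mask <- function(shape, p = 0.3) {
  m <- array(as.numeric(runif(prod(shape)) < p), shape)
  if (sum(m) == 0) m[ceiling(shape[1] / 2), 1, 1] <- 1
  m
}

# Small in-memory phantom training set on a 16-divisible grid.
tiny_cases <- function(n = 2, seed = 7, shape = c(32L, 32L, 16L)) {
  cfg <- tiny_phantom_config(shape = shape)
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(cfg, seed = seed + i)
    pp <- preprocess_case(ph$image, ph$label,
                          preprocess_config(target_shape = shape))
    list(image = pp$image, label = pp$label)
  })
}
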
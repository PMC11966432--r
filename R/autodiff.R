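# Minimal reverse-mode automatic differentiation tape.
#
# Every forward pass builds a fresh tape: a list of nodes in creation order.
# A node is an environment holding `v` (the value, an (X,Y,Z,C) array or a
# scalar), `g` (the accumulated gradient, filled during the backward sweep),
# `bw` (a closure that, given the node's gradient, pushes gradients to its
# parents), and `id` (position on the tape, which is already a topological
# order).  Heavy kernels live in src/; everything channel-wise or elementwise
# stays vectorised R.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

nd_new <- function(tape, value, bw = NULL, name = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$bw <- bw
  nd$name <- name
  tape$n <- tape$n + 1L
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

nd_leaf <- function(tape, value, name = NULL) nd_new(tape, value, NULL, name)

nd_accum <- function(nd, g) {
  if (is.null(nd$g)) nd$g <- g else nd$g <- nd$g + g
  invisible(NULL)
}

#' @noRd
tape_backward <- function(tape, loss_node, seed = 1) {
  loss_node$g <- seed
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd$g)
  }
  invisible(NULL)
}

vdim <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("tensor has no dim attribute")
  d
}

as4d <- function(a) {
  d <- dim(a)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 3L) dim(a) <- c(d, 1L)
  a
}

# ---- convolution -----------------------------------------------------------

conv_out_dim <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

#' Strided 3D convolution node: x (X,Y,Z,Ci), w (k,k,k,Ci,Co), b (Co).
#' @noRd
op_conv3d <- function(tape, x, w, b, stride = 1L, pad = NULL) {
  wd <- vdim(w$v)
  k <- wd[1]; ci <- wd[4]; co <- wd[5]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  xd <- vdim(x$v)
  stopifnot(xd[4] == ci)
  yd <- c(conv_out_dim(xd[1], k, stride, pad),
          conv_out_dim(xd[2], k, stride, pad),
          conv_out_dim(xd[3], k, stride, pad), co)
  y <- cpp_conv3d(x$v, as.integer(xd), w$v, as.integer(k), as.integer(ci),
                  as.integer(co), b$v, as.integer(stride), as.integer(pad))
  dim(y) <- yd
  nd_new(tape, y, function(g) {
    gx <- cpp_conv3d_bwd_x(g, as.integer(yd), w$v, as.integer(k),
                           as.integer(ci), as.integer(co), as.integer(xd),
                           as.integer(stride), as.integer(pad))
    dim(gx) <- xd
    nd_accum(x, gx)
    gw <- cpp_conv3d_bwd_w(x$v, as.integer(xd), g, as.integer(yd),
                           as.integer(k), as.integer(ci), as.integer(co),
                           as.integer(stride), as.integer(pad))
    dim(gw) <- wd
    nd_accum(w, gw)
    gm <- g
    dim(gm) <- c(prod(yd[1:3]), yd[4])
    nd_accum(b, .colSums(gm, prod(yd[1:3]), yd[4]))
  })
}

#' Stride-2 transposed 3D convolution that exactly doubles each spatial axis
#' (odd kernel, padding (k-1)/2, implicit output padding 1).
#' w is (k,k,k,Ci,Co) with Ci the input (deep) channels.
#' @noRd
op_convtranspose3d <- function(tape, x, w, b, stride = 2L) {
  wd <- vdim(w$v)
  k <- wd[1]; ci <- wd[4]; co <- wd[5]
  pad <- (k - 1L) %/% 2L
  xd <- vdim(x$v)
  stopifnot(xd[4] == ci)
  yd <- c(xd[1:3] * stride, co)
  # Transposed conv forward = input-gradient of the matching strided conv,
  # with the channel axes of the kernel swapped.
  wt <- aperm(w$v, c(1L, 2L, 3L, 5L, 4L))
  y <- cpp_conv3d_bwd_x(x$v, as.integer(xd), wt, as.integer(k),
                        as.integer(co), as.integer(ci), as.integer(yd),
                        as.integer(stride), as.integer(pad))
  dim(y) <- yd
  bfull <- rep(b$v, each = prod(yd[1:3]))
  y <- y + bfull
  nd_new(tape, y, function(g) {
    gx <- cpp_conv3d(g, as.integer(yd), wt, as.integer(k), as.integer(co),
                     as.integer(ci), numeric(ci), as.integer(stride),
                     as.integer(pad))
    dim(gx) <- xd
    nd_accum(x, gx)
    gwt <- cpp_conv3d_bwd_w(g, as.integer(yd), x$v, as.integer(xd),
                            as.integer(k), as.integer(co), as.integer(ci),
                            as.integer(stride), as.integer(pad))
    dim(gwt) <- c(k, k, k, co, ci)
    nd_accum(w, aperm(gwt, c(1L, 2L, 3L, 5L, 4L)))
    gm <- g
    dim(gm) <- c(prod(yd[1:3]), yd[4])
    nd_accum(b, .colSums(gm, prod(yd[1:3]), yd[4]))
  })
}

# ---- elementwise / channel-wise -------------------------------------------

#' PReLU with one learned slope per channel (slope node `a`, length C).
#' @noRd
op_prelu <- function(tape, x, a) {
  xd <- vdim(x$v)
  nc <- xd[4]
  nsp <- prod(xd[1:3])
  av <- rep(a$v, each = nsp)
  pos <- x$v > 0
  y <- ifelse(pos, x$v, av * x$v)
  dim(y) <- xd
  nd_new(tape, y, function(g) {
    gx <- ifelse(pos, g, av * g)
    dim(gx) <- xd
    nd_accum(x, gx)
    gneg <- ifelse(pos, 0, g * x$v)
    dim(gneg) <- c(nsp, nc)
    nd_accum(a, .colSums(gneg, nsp, nc))
  })
}

#' @noRd
op_relu <- function(tape, x) {
  pos <- x$v > 0
  y <- x$v * pos
  nd_new(tape, y, function(g) nd_accum(x, g * pos))
}

#' @noRd
op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$v))
  nd_new(tape, y, function(g) nd_accum(x, g * y * (1 - y)))
}

#' Instance normalisation with learned per-channel scale and shift: each
#' channel is standardised over its spatial voxels.  Safe at batch size 1.
#' @noRd
op_instnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xd <- vdim(x$v)
  nsp <- prod(xd[1:3]); nc <- xd[4]
  xm <- x$v
  dim(xm) <- c(nsp, nc)
  mu <- .colMeans(xm, nsp, nc)
  xc <- sweep(xm, 2L, mu, "-")
  va <- .colMeans(xc * xc, nsp, nc)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  y <- sweep(xhat, 2L, gamma$v, "*")
  y <- sweep(y, 2L, beta$v, "+")
  dim(y) <- xd
  nd_new(tape, y, function(g) {
    gm <- g
    dim(gm) <- c(nsp, nc)
    nd_accum(beta, .colSums(gm, nsp, nc))
    nd_accum(gamma, .colSums(gm * xhat, nsp, nc))
    gh <- sweep(gm, 2L, gamma$v, "*")
    m1 <- .colMeans(gh, nsp, nc)
    m2 <- .colMeans(gh * xhat, nsp, nc)
    gx <- sweep(gh, 2L, m1, "-") - sweep(xhat, 2L, m2, "*")
    gx <- sweep(gx, 2L, istd, "*")
    dim(gx) <- xd
    nd_accum(x, gx)
  })
}

#' Inverted dropout; identity when training is FALSE or rate is 0.
#' @noRd
op_dropout <- function(tape, x, rate, training) {
  if (!training || rate <= 0) return(x)
  keep <- (stats::runif(length(x$v)) >= rate) / (1 - rate)
  dim(keep) <- vdim(x$v)
  y <- x$v * keep
  nd_new(tape, y, function(g) nd_accum(x, g * keep))
}

#' @noRd
op_add <- function(tape, x, y) {
  stopifnot(identical(vdim(x$v), vdim(y$v)))
  nd_new(tape, x$v + y$v, function(g) { nd_accum(x, g); nd_accum(y, g) })
}

#' Channel concatenation.
#' @noRd
op_concat_c <- function(tape, x, y) {
  xd <- vdim(x$v); yd <- vdim(y$v)
  stopifnot(identical(xd[1:3], yd[1:3]))
  v <- c(x$v, y$v)
  dim(v) <- c(xd[1:3], xd[4] + yd[4])
  nx <- length(x$v)
  nd_new(tape, v, function(g) {
    gx <- g[seq_len(nx)]; dim(gx) <- xd
    gy <- g[nx + seq_len(length(y$v))]; dim(gy) <- yd
    nd_accum(x, gx)
    nd_accum(y, gy)
  })
}

#' Multiply a (X,Y,Z,C) tensor by a single-channel (X,Y,Z,1) coefficient map,
#' broadcast over channels (the attention-gate product).
#' @noRd
op_mul_bcast <- function(tape, x, alpha) {
  xd <- vdim(x$v); ad <- vdim(alpha$v)
  stopifnot(identical(xd[1:3], ad[1:3]), ad[4] == 1L)
  av <- as.vector(alpha$v)
  y <- x$v * av          # recycles alpha over the channel axis
  nd_new(tape, y, function(g) {
    gx <- g * av
    dim(gx) <- xd
    nd_accum(x, gx)
    gm <- g * x$v
    dim(gm) <- c(prod(xd[1:3]), xd[4])
    ga <- .rowSums(gm, prod(xd[1:3]), xd[4])
    dim(ga) <- ad
    nd_accum(alpha, ga)
  })
}

#' Trilinear resize to `outdims` with per-axis source scale factors.
#' @noRd
op_resize_trilinear <- function(tape, x, outdims) {
  xd <- vdim(x$v)
  scale <- xd[1:3] / outdims
  y <- cpp_resize3d(x$v, as.integer(xd), as.integer(outdims),
                    as.numeric(scale), FALSE)
  dim(y) <- c(outdims, xd[4])
  nd_new(tape, y, function(g) {
    gx <- cpp_resize3d_adj(g, as.integer(c(outdims, xd[4])),
                           as.integer(xd), as.numeric(scale))
    dim(gx) <- xd
    nd_accum(x, gx)
  })
}

#' Channel softmax with max-subtraction stabilisation.
#' @noRd
op_softmax_c <- function(tape, x) {
  xd <- vdim(x$v)
  nsp <- prod(xd[1:3]); nc <- xd[4]
  xm <- x$v
  dim(xm) <- c(nsp, nc)
  mx <- do.call(pmax, lapply(seq_len(nc), function(j) xm[, j]))
  e <- exp(xm - mx)
  p <- e / .rowSums(e, nsp, nc)
  dim(p) <- xd
  nd_new(tape, p, function(g) {
    gm <- g; dim(gm) <- c(nsp, nc)
    pm <- p; dim(pm) <- c(nsp, nc)
    dot <- .rowSums(gm * pm, nsp, nc)
    gx <- pm * (gm - dot)
    dim(gx) <- xd
    nd_accum(x, gx)
  })
}

# ---- losses (scalar-valued nodes) -----------------------------------------

#' Squared-denominator soft Dice loss on the foreground-probability channel.
#' @noRd
op_dice_loss <- function(tape, p, g_arr, smooth = 1e-5) {
  pd <- vdim(p$v)
  pf <- p$v[, , , pd[4], drop = FALSE]     # foreground = last channel
  gv <- as.numeric(g_arr)
  pv <- as.numeric(pf)
  num <- 2 * sum(pv * gv) + smooth
  den <- sum(pv * pv) + sum(gv * gv) + smooth
  loss <- 1 - num / den
  nd_new(tape, loss, function(g) {
    dfg <- -(2 * gv * den - num * 2 * pv) / (den * den) * g
    gp <- array(0, pd)
    gp[, , , pd[4]] <- dfg
    nd_accum(p, gp)
  })
}

#' Mean negative log-likelihood of the true class, probability floor 1e-12.
#' @noRd
op_nll_loss <- function(tape, p, labels, floor = 1e-12) {
  pd <- vdim(p$v)
  nsp <- prod(pd[1:3])
  lab <- as.integer(as.numeric(labels))    # 0/1
  pm <- p$v
  dim(pm) <- c(nsp, pd[4])
  idx <- cbind(seq_len(nsp), lab + 1L)
  pt <- pm[idx]
  ptc <- pmax(pt, floor)
  loss <- -mean(log(ptc))
  nd_new(tape, loss, function(g) {
    live <- pt > floor                     # clamped voxels get no gradient
    gv <- numeric(nsp)
    gv[live] <- (-1 / (nsp * ptc[live])) * g
    gm <- matrix(0, nsp, pd[4])
    gm[idx] <- gv
    dim(gm) <- pd
    nd_accum(p, gm)
  })
}

#' Weighted sum of scalar nodes: main + sum(eta * branches).
#' @noRd
op_weighted_sum <- function(tape, main, branches, eta) {
  stopifnot(length(branches) == length(eta))
  total <- main$v + if (length(branches)) sum(eta * vapply(branches, function(b) b$v, 0)) else 0
  nd_new(tape, total, function(g) {
    nd_accum(main, g)
    for (i in seq_along(branches)) nd_accum(branches[[i]], eta[i] * g)
  })
}
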
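# The network primitives: forward values against direct-summation oracles,
# gradients against central finite differences.

grad_check <- function(build_loss, params, tol = 1e-4) {
  # build_loss(param_arrays) must build a tape and return list(tape, loss, nodes)
  r <- build_loss(params)
  vnetseg:::tape_backward(r$tape, r$loss)
  for (nm in names(r$nodes)) {
    ana <- r$nodes[[nm]]$g
    num <- numeric_grad(function(p) {
      q <- params; q[[nm]] <- p
      build_loss(q)$loss$v
    }, params[[nm]])
    expect_lt(max(abs(ana - num)), tol * max(1, max(abs(num))),
              label = sprintf("gradient wrt %s", nm))
  }
}

test_that("strided convolution matches the direct-summation oracle", {
  set.seed(1)
  for (cse in list(list(d = c(5, 4, 3, 2), co = 3, k = 3, s = 1),
                   list(d = c(6, 6, 4, 1), co = 2, k = 3, s = 2),
                   list(d = c(7, 5, 5, 2), co = 1, k = 5, s = 1))) {
    x <- array(rnorm(prod(cse$d)), cse$d)
    w <- array(rnorm(cse$k^3 * cse$d[4] * cse$co), c(rep(cse$k, 3), cse$d[4], cse$co))
    b <- rnorm(cse$co)
    tape <- vnetseg:::new_tape()
    y <- vnetseg:::op_conv3d(tape, vnetseg:::nd_leaf(tape, x),
                             vnetseg:::nd_leaf(tape, w), vnetseg:::nd_leaf(tape, b),
                             cse$s)
    expect_equal(y$v, oracle_conv3d(x, w, b, cse$s), tolerance = 1e-10)
  }
})

test_that("convolution gradients agree with finite differences", {
  set.seed(2)
  params <- list(x = array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2)),
                 w = array(rnorm(27 * 2 * 2) * 0.3, c(3, 3, 3, 2, 2)),
                 b = rnorm(2) * 0.1)
  for (s in c(1L, 2L)) {
    grad_check(function(p) {
      tape <- vnetseg:::new_tape()
      nodes <- lapply(p, function(a) vnetseg:::nd_leaf(tape, a))
      y <- vnetseg:::op_conv3d(tape, nodes$x, nodes$w, nodes$b, s)
      loss <- vnetseg:::nd_new(tape, sum(y$v * sin(seq_along(y$v))),
                               local({
                                 yy <- y
                                 function(g) vnetseg:::nd_accum(yy, array(g * sin(seq_along(yy$v)), dim(yy$v)))
                               }))
      list(tape = tape, loss = loss, nodes = nodes)
    }, params)
  }
})

test_that("transposed convolution doubles each axis and its gradients check out", {
  set.seed(3)
  params <- list(x = array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2)),
                 w = array(rnorm(27 * 2 * 3) * 0.3, c(3, 3, 3, 2, 3)),
                 b = rnorm(3) * 0.1)
  tape <- vnetseg:::new_tape()
  nodes <- lapply(params, function(a) vnetseg:::nd_leaf(tape, a))
  y <- vnetseg:::op_convtranspose3d(tape, nodes$x, nodes$w, nodes$b)
  expect_identical(dim(y$v), c(6L, 6L, 4L, 3L))
  grad_check(function(p) {
    tp <- vnetseg:::new_tape()
    nds <- lapply(p, function(a) vnetseg:::nd_leaf(tp, a))
    yy <- vnetseg:::op_convtranspose3d(tp, nds$x, nds$w, nds$b)
    loss <- vnetseg:::nd_new(tp, sum(yy$v * cos(seq_along(yy$v))),
                             local({
                               zz <- yy
                               function(g) vnetseg:::nd_accum(zz, array(g * cos(seq_along(zz$v)), dim(zz$v)))
                             }))
    list(tape = tp, loss = loss, nodes = nds)
  }, params)
})

test_that("elementwise and normalisation ops pass finite-difference checks", {
  set.seed(4)
  x0 <- array(rnorm(4 * 3 * 2 * 3), c(4, 3, 2, 3))
  params <- list(x = x0, a = c(0.25, 0.1, 0.4), gamma = c(1.1, 0.9, 1.0),
                 beta = c(0.1, -0.2, 0))
  grad_check(function(p) {
    tp <- vnetseg:::new_tape()
    nds <- lapply(p, function(v) vnetseg:::nd_leaf(tp, v))
    h <- vnetseg:::op_prelu(tp, nds$x, nds$a)
    h <- vnetseg:::op_instnorm(tp, h, nds$gamma, nds$beta)
    h <- vnetseg:::op_sigmoid(tp, h)
    loss <- vnetseg:::nd_new(tp, sum(h$v * sin(seq_along(h$v))),
                             local({
                               hh <- h
                               function(g) vnetseg:::nd_accum(hh, array(g * sin(seq_along(hh$v)), dim(hh$v)))
                             }))
    list(tape = tp, loss = loss, nodes = nds)
  }, params, tol = 5e-4)
})

test_that("softmax + dice and nll loss gradients check out", {
  set.seed(5)
  g <- random_mask(c(3, 3, 2))
  params <- list(x = array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2)))
  for (lossfun in c("dice", "nll")) {
    grad_check(function(p) {
      tp <- vnetseg:::new_tape()
      nds <- list(x = vnetseg:::nd_leaf(tp, p$x))
      pr <- vnetseg:::op_softmax_c(tp, nds$x)
      loss <- if (lossfun == "dice") vnetseg:::op_dice_loss(tp, pr, g)
      else vnetseg:::op_nll_loss(tp, pr, g)
      list(tape = tp, loss = loss, nodes = nds)
    }, params, tol = 5e-4)
  }
})

test_that("trilinear resize is an exact identity at scale 1 and adjoint-consistent", {
  set.seed(6)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  tp <- vnetseg:::new_tape()
  y <- vnetseg:::op_resize_trilinear(tp, vnetseg:::nd_leaf(tp, x), c(4L, 4L, 2L))
  expect_equal(y$v, x, tolerance = 1e-12)
  # adjoint identity <Ax, y> == <x, A'y>
  xs <- array(rnorm(3 * 3 * 2), c(3, 3, 2, 1))
  ys <- array(rnorm(6 * 6 * 4), c(6, 6, 4, 1))
  sc <- c(3, 3, 2) / c(6, 6, 4)
  ax <- vnetseg:::cpp_resize3d(xs, dim(xs), c(6L, 6L, 4L), sc, FALSE)
  aty <- vnetseg:::cpp_resize3d_adj(ys, c(6L, 6L, 4L, 1L), dim(xs), sc)
  expect_equal(sum(ax * ys), sum(xs * aty), tolerance = 1e-10)
})

test_that("attention-gate graph gradients flow to all gate parameters", {
  set.seed(7)
  g <- array(rnorm(2 * 2 * 1 * 3), c(2, 2, 1, 3))
  xl <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  spec <- attention_gate_spec(gate_channels = 3, skip_channels = 2)
  pp <- vnetseg:::init_attention_params(spec, seed = 1)
  flat <- list(x = xl,
               wg.w = pp$wg$w, wg.b = pp$wg$b,
               wx.w = pp$wx$w, wx.b = pp$wx$b,
               psi.w = pp$psi$w, psi.b = pp$psi$b)
  grad_check(function(p) {
    tp <- vnetseg:::new_tape()
    nds <- lapply(p, function(v) vnetseg:::nd_leaf(tp, v))
    P <- list("ag.wg.w" = nds$wg.w, "ag.wg.b" = nds$wg.b,
              "ag.wx.w" = nds$wx.w, "ag.wx.b" = nds$wx.b,
              "ag.psi.w" = nds$psi.w, "ag.psi.b" = nds$psi.b)
    res <- vnetseg:::graph_attention_gate(tp, P, "ag", vnetseg:::nd_leaf(tp, g), nds$x)
    h <- res$gated
    loss <- vnetseg:::nd_new(tp, sum(h$v * sin(seq_along(h$v))),
                             local({
                               hh <- h
                               function(gr) vnetseg:::nd_accum(hh, array(gr * sin(seq_along(hh$v)), dim(hh$v)))
                             }))
    list(tape = tp, loss = loss, nodes = nds)
  }, flat, tol = 5e-4)
})
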
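# Architecture: stage shapes and channel counts, attention-gate behaviour,
# deep-supervision heads, forward determinism, prediction tie rule and
# checkpoint round trips.  Full-channel forwards run at 32x32x16; the
# 128x128x48 geometry is checked by the analytic trace (pure shape algebra).

test_that("the default architecture trace reproduces the stage table", {
  tr <- trace_shapes(network_config(), c(128L, 128L, 48L))
  enc <- tr[grepl("Left", tr$stage), ]
  expect_equal(enc$size_x, c(128, 64, 32, 16, 8))
  expect_equal(enc$size_y, c(128, 64, 32, 16, 8))
  expect_equal(enc$size_z, c(48, 24, 12, 6, 3))
  expect_equal(enc$channels, c(16, 32, 64, 128, 256))
  dec <- tr[grepl("Right", tr$stage), ]
  expect_equal(dec$size_x, c(16, 32, 64, 128))
  expect_equal(dec$channels, c(128, 64, 32, 16))
  out <- tr[tr$stage == "output", ]
  expect_equal(unlist(out[, c("size_x", "size_y", "size_z", "channels")],
                      use.names = FALSE), c(128, 128, 48, 16))
})

test_that("config invariants are enforced", {
  expect_error(network_config(stage_channels = c(16, 32, 64, 128)), "5 stages")
  expect_error(network_config(stage_channels = c(16, 16, 64, 128, 256)), "strictly")
  expect_error(network_config(convs_per_stage = rep(1, 8)), "9 entries")
  expect_error(network_config(kernel_size = 4), "3 or 5")
  expect_error(network_config(dropout_rate = 1), "\\[0, 1\\)")
})

test_that("forward output sizes match the input for divisible-by-16 grids", {
  net <- build_network(tiny_network_config(), seed = 1)
  fo <- forward(net, array(rnorm(32 * 32 * 16), c(32, 32, 16)))
  expect_identical(dim(fo$main_logits), c(32L, 32L, 16L, 2L))
  expect_length(fo$branch_probabilities, 3)
  for (b in fo$branch_probabilities) {
    expect_identical(dim(b), c(32L, 32L, 16L, 2L))
    expect_equal(apply(b, 1:3, sum), array(1, c(32, 32, 16)), tolerance = 1e-5)
  }
  expect_error(forward(net, array(0, c(30, 32, 16))), "axis x")
  expect_error(forward(net, array(0, c(32, 32, 20))), "axis z")
})

test_that("randomised configs preserve input size and branch count", {
  set.seed(51)
  for (i in 1:3) {
    ch <- sort(sample(2:24, 5))
    while (any(diff(ch) <= 0)) ch <- sort(sample(2:40, 5))
    ds <- sort(sample(1:4, sample(0:3, 1)), decreasing = TRUE)
    cfg <- network_config(stage_channels = ch,
                          convs_per_stage = sample(1:2, 9, replace = TRUE),
                          deep_supervision_stages = ds,
                          use_attention_gates = sample(c(TRUE, FALSE), 1),
                          use_residual = sample(c(TRUE, FALSE), 1))
    d <- c(16L, 32L, 16L)
    fo <- forward(build_network(cfg, seed = i), array(rnorm(prod(d)), d))
    expect_identical(dim(fo$main_logits), c(d, 2L))
    expect_length(fo$branch_probabilities, length(ds))
  }
})

test_that("deep supervision off yields no branch maps", {
  cfg <- tiny_network_config(deep_supervision_stages = integer())
  fo <- forward(build_network(cfg, 1), array(rnorm(32 * 32 * 16), c(32, 32, 16)))
  expect_length(fo$branch_probabilities, 0)
})

test_that("inference is deterministic and dropout only acts in training", {
  net <- build_network(tiny_network_config(dropout_rate = 0.3), seed = 2)
  x <- array(rnorm(32 * 32 * 16), c(32, 32, 16))
  f1 <- forward(net, x); f2 <- forward(net, x)
  expect_identical(f1$main_logits, f2$main_logits)
  set.seed(1); t1 <- forward(net, x, training = TRUE)
  set.seed(2); t2 <- forward(net, x, training = TRUE)
  expect_false(identical(t1$main_logits, t2$main_logits))
})

test_that("attention coefficients lie strictly in (0,1) and gate as specified", {
  net <- build_network(tiny_network_config(), seed = 3)
  fo <- forward(net, array(rnorm(32 * 32 * 16), c(32, 32, 16)),
                collect_attention = TRUE)
  expect_length(fo$attention, 4)
  for (a in fo$attention) {
    expect_gt(min(a), 0)
    expect_lt(max(a), 1)
  }

  # zero weights -> alpha == 0.5 everywhere -> gated = x/2
  spec <- attention_gate_spec(gate_channels = 3, skip_channels = 2)
  zero <- list(wg = list(w = array(0, c(1, 1, 1, 3, 1)), b = 0),
               wx = list(w = array(0, c(1, 1, 1, 2, 1)), b = 0),
               psi = list(w = array(0, c(1, 1, 1, 1, 1)), b = 0))
  g <- array(rnorm(2 * 2 * 1 * 3), c(2, 2, 1, 3))
  xl <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  r <- attention_gate(g, xl, attention_gate_spec(3, 2, 1), params = zero)
  expect_equal(r$alpha, array(0.5, c(4, 4, 2, 1)))
  expect_equal(r$gated, 0.5 * xl)

  # large negative projection bias -> background suppression limit
  neg <- zero; neg$psi$b <- -50
  r2 <- attention_gate(g, xl, attention_gate_spec(3, 2, 1), params = neg)
  expect_lt(max(abs(r2$gated)), 1e-15)

  # shapes at adjacent stage sizes: 128ch 16x16x6 gating 64ch 32x32x12
  g3 <- array(rnorm(16 * 16 * 6 * 8), c(16, 16, 6, 8))
  x3 <- array(rnorm(32 * 32 * 12 * 4), c(32, 32, 12, 4))
  r3 <- attention_gate(g3, x3, attention_gate_spec(8, 4), seed = 5)
  expect_identical(dim(r3$gated), dim(x3))
})

test_that("disabling attention gates reduces to plain skip concatenation", {
  cfg_on <- tiny_network_config(dropout_rate = 0)
  cfg_off <- tiny_network_config(dropout_rate = 0, use_attention_gates = FALSE)
  x <- array(rnorm(32 * 32 * 16), c(32, 32, 16))
  net_on <- build_network(cfg_on, seed = 4)
  # strip the gate parameters and rebuild without gates: shared weights
  net_off <- build_network(cfg_off, seed = 4)
  shared <- intersect(names(net_on$params), names(net_off$params))
  net_off$params[shared] <- net_on$params[shared]
  fo_on <- forward(net_on, x)
  fo_off <- forward(net_off, x)
  expect_identical(dim(fo_on$main_logits), dim(fo_off$main_logits))
  expect_false(identical(fo_on$main_logits, fo_off$main_logits))
})

test_that("deep-supervision heads upsample to full size with unit channel sums", {
  f <- array(rnorm(4 * 4 * 2 * 6), c(4, 4, 2, 6))
  p8 <- deep_supervision_head(f, 8, num_classes = 2, seed = 6)
  expect_identical(dim(p8), c(32L, 32L, 16L, 2L))
  expect_equal(apply(p8, 1:3, sum), array(1, c(32, 32, 16)), tolerance = 1e-5)
  p1 <- deep_supervision_head(f, 1, num_classes = 2, seed = 6)
  expect_identical(dim(p1), c(4L, 4L, 2L, 2L))
  expect_error(deep_supervision_head(f, 3), "power of two")
})

test_that("predict_mask applies argmax with ties to background", {
  d <- c(2, 2, 1)
  mk <- function(fg) { a <- array(0, c(d, 2)); a[, , , 2] <- fg; a[, , , 1] <- 1 - fg; a }
  expect_equal(predict_mask(mk(array(0.9, d)))$data, array(1, d))
  expect_equal(predict_mask(mk(array(0.5, d)))$data, array(0, d))
  mixed <- mk(array(c(0.2, 0.7, 0.5, 0.5), d))
  expect_equal(as.vector(predict_mask(mixed)$data), c(0, 1, 0, 0))
  expect_error(predict_mask(array(0, c(2, 2, 1, 3))), "\\(X,Y,Z,2\\)")
})

test_that("checkpoints round-trip weights and configuration", {
  net <- build_network(tiny_network_config(kernel_size = 5,
                                           deep_supervision_stages = c(3L, 2L)),
                       seed = 7)
  f <- tempfile()
  save_checkpoint(net, f)
  back <- load_checkpoint(f)
  expect_equal(back$config, net$config)
  expect_equal(back$params, net$params)
  x <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  expect_identical(forward(net, x)$main_logits, forward(back, x)$main_logits)
})
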
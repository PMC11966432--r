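# The attention-gated, deeply supervised 3D V-Net.
#
# Five encoder stages (channels doubling 16..256, stride-2 downsampling
# convolutions between them), four decoder stages each opened by a stride-2
# transposed convolution and a concatenation with the (attention-gated)
# encoder skip, and a final full-resolution stage projecting to two class
# logits.  Every convolution is followed by a parametric rectifier (PReLU),
# an instance normalisation (safe at batch size 1) and dropout.  Auxiliary
# deep-supervision heads upsample intermediate decoder features to full size
# and emit softmax probability maps.

#' Network configuration
#'
#' Houses the architecture hyperparameters: per-stage channel counts
#' (ascending down the encoder), convolutions per stage over the nine stages
#' (4 encoder + bottom + 4 decoder), kernel size, dropout rate, the
#' attention-gate and residual-connection switches and the set of decoder
#' stages carrying deep-supervision heads.
#'
#' @param stage_channels Five strictly increasing channel counts, one per
#'   resolution level (default 16, 32, 64, 128, 256).
#' @param convs_per_stage Nine convolution counts, ordered encoder stages
#'   1-4, bottom, decoder stages 4-1 (default `c(1,2,3,3,2,2,2,2,2)`).
#' @param kernel_size Odd convolution kernel edge, 3 or 5.
#' @param dropout_rate Dropout probability after each convolution (default
#'   0.01).
#' @param use_attention_gates Gate the encoder skips before concatenation?
#' @param deep_supervision_stages Decoder stages (by depth: 4 = 1/8
#'   resolution, 2 = 1/2) with auxiliary heads; default `c(4, 3, 2)` -- every
#'   decoder stage but the last.
#' @param in_channels Input channels (single-sequence MRI: 1).
#' @param num_classes Output classes (background/lesion: 2).
#' @param use_residual Keep the element-wise residual connection within each
#'   stage (as in the underlying V-Net)?
#' @return A `network_config` list.
#' @export
network_config <- function(stage_channels = c(16L, 32L, 64L, 128L, 256L),
                           convs_per_stage = c(1L, 2L, 3L, 3L, 2L, 2L, 2L, 2L, 2L),
                           kernel_size = 3L,
                           dropout_rate = 0.01,
                           use_attention_gates = TRUE,
                           deep_supervision_stages = c(4L, 3L, 2L),
                           in_channels = 1L,
                           num_classes = 2L,
                           use_residual = TRUE) {
  stage_channels <- as.integer(stage_channels)
  convs_per_stage <- as.integer(convs_per_stage)
  if (length(stage_channels) != 5L)
    stop("stage_channels must list exactly 5 stages")
  if (any(diff(stage_channels) <= 0))
    stop("stage_channels must increase strictly down the encoder")
  if (length(convs_per_stage) != 9L || any(convs_per_stage < 1L))
    stop("convs_per_stage must have 9 entries, each >= 1")
  if (!kernel_size %in% c(3L, 5L)) stop("kernel_size must be 3 or 5")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must lie in [0, 1)")
  deep_supervision_stages <- as.integer(deep_supervision_stages)
  if (length(deep_supervision_stages) &&
      !all(deep_supervision_stages %in% 1:4))
    stop("deep_supervision_stages must be decoder stages in 1..4")
  structure(list(stage_channels = stage_channels,
                 convs_per_stage = convs_per_stage,
                 kernel_size = as.integer(kernel_size),
                 dropout_rate = dropout_rate,
                 use_attention_gates = isTRUE(use_attention_gates),
                 deep_supervision_stages = deep_supervision_stages,
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 use_residual = isTRUE(use_residual)),
            class = "network_config")
}

#' A small configuration for desk-scale experiments
#'
#' Same topology as the default network with channel counts reduced to
#' 4..32, sized for 32x32x16 inputs on one CPU.
#'
#' @param ... Overrides passed to [network_config()].
#' @return A `network_config`.
#' @export
tiny_network_config <- function(...) {
  args <- modifyList(list(stage_channels = c(4L, 8L, 16L, 24L, 32L)), list(...))
  do.call(network_config, args)
}

# ---- parameter initialisation ---------------------------------------------

he_init <- function(shape, fan_in) array(rnorm(prod(shape), 0, sqrt(2 / fan_in)), shape)

conv_unit_params <- function(k, ci, co, norm = TRUE, act = TRUE) {
  p <- list(w = he_init(c(k, k, k, ci, co), k^3 * ci), b = numeric(co))
  if (act) p$a <- rep(0.25, co)
  if (norm) { p$gamma <- rep(1, co); p$beta <- numeric(co) }
  p
}

ds_head_channels <- function(ch_start, n_up) {
  ch <- ch_start
  out <- integer(0)
  for (t in seq_len(n_up)) {
    ch <- max(2L, ch %/% 2L)
    out <- c(out, ch)
  }
  out
}

init_params <- function(config) {
  ch <- config$stage_channels
  k <- config$kernel_size
  cps <- config$convs_per_stage
  P <- list()
  add <- function(name, p) for (nm in names(p)) P[[paste0(name, ".", nm)]] <<- p[[nm]]
  # encoder
  for (i in 1:5) {
    cin <- if (i == 1L) config$in_channels else ch[i]
    for (j in seq_len(cps[i])) {
      add(sprintf("enc%d.conv%d", i, j),
          conv_unit_params(k, if (j == 1L) cin else ch[i], ch[i]))
    }
    if (config$use_residual && cin != ch[i])
      add(sprintf("enc%d.proj", i), conv_unit_params(1L, cin, ch[i], norm = FALSE, act = FALSE))
    if (i < 5L) add(sprintf("down%d", i), conv_unit_params(k, ch[i], ch[i + 1L]))
  }
  # decoder
  for (jj in 4:1) {
    add(sprintf("up%d", jj), conv_unit_params(k, ch[jj + 1L], ch[jj]))
    if (config$use_attention_gates) {
      fi <- max(1L, ch[jj] %/% 2L)
      add(sprintf("ag%d.wg", jj), conv_unit_params(1L, ch[jj + 1L], fi, norm = FALSE, act = FALSE))
      add(sprintf("ag%d.wx", jj), conv_unit_params(1L, ch[jj], fi, norm = FALSE, act = FALSE))
      add(sprintf("ag%d.psi", jj), conv_unit_params(1L, fi, 1L, norm = FALSE, act = FALSE))
    }
    nidx <- 10L - jj                     # decoder stage jj -> tuple position 6..9
    for (j in seq_len(cps[nidx])) {
      add(sprintf("dec%d.conv%d", jj, j),
          conv_unit_params(k, if (j == 1L) 2L * ch[jj] else ch[jj], ch[jj]))
    }
    if (config$use_residual)
      add(sprintf("dec%d.proj", jj), conv_unit_params(1L, 2L * ch[jj], ch[jj], norm = FALSE, act = FALSE))
    if (jj %in% config$deep_supervision_stages) {
      hc <- ds_head_channels(ch[jj], jj - 1L)
      cin <- ch[jj]
      for (t in seq_len(jj - 1L)) {
        add(sprintf("head%d.up%d", jj, t),
            conv_unit_params(k, cin, hc[t], norm = FALSE))
        cin <- hc[t]
      }
      add(sprintf("head%d.proj", jj), conv_unit_params(1L, cin, config$num_classes,
                                                       norm = FALSE, act = FALSE))
    }
  }
  # full-resolution output stage (Table-2 style: one k^3 conv at stage-1
  # width, then a 1x1x1 projection to class logits)
  add("out.conv", conv_unit_params(k, ch[1], ch[1]))
  add("out.proj", conv_unit_params(1L, ch[1], config$num_classes, norm = FALSE, act = FALSE))
  P
}

#' Build a network
#'
#' Initialises all weights (He-scaled Gaussian fan-in initialisation, PReLU
#' slopes 0.25, unit norm scales) for the configured architecture.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `vnet` object (configuration + named parameter list).
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  params <- with_preserved_rng(seed, init_params(config))
  structure(list(config = config, params = params), class = "vnet")
}

#' @export
print.vnet <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<vnet channels %s, kernel %d^3, %s attention, %d supervised stages, %s parameters>\n",
              paste(x$config$stage_channels, collapse = "/"),
              x$config$kernel_size,
              if (x$config$use_attention_gates) "with" else "without",
              length(x$config$deep_supervision_stages),
              format(np, big.mark = ",")))
  invisible(x)
}

# ---- graph construction ----------------------------------------------------

leaf_params <- function(tape, params) {
  P <- list()
  for (nm in names(params)) P[[nm]] <- nd_leaf(tape, params[[nm]], nm)
  P
}

graph_conv_unit <- function(tape, P, name, x, stride = 1L, dropout = 0,
                            training = FALSE) {
  y <- op_conv3d(tape, x, P[[paste0(name, ".w")]], P[[paste0(name, ".b")]], stride)
  y <- op_prelu(tape, y, P[[paste0(name, ".a")]])
  y <- op_instnorm(tape, y, P[[paste0(name, ".gamma")]], P[[paste0(name, ".beta")]])
  op_dropout(tape, y, dropout, training)
}

graph_conv_block <- function(tape, P, prefix, x, nconvs, config, training) {
  h <- x
  for (j in seq_len(nconvs))
    h <- graph_conv_unit(tape, P, sprintf("%s.conv%d", prefix, j), h,
                         dropout = config$dropout_rate, training = training)
  if (config$use_residual) {
    pr <- paste0(prefix, ".proj.w")
    skip <- if (!is.null(P[[pr]]))
      op_conv3d(tape, x, P[[pr]], P[[paste0(prefix, ".proj.b")]], 1L)
    else x
    h <- op_add(tape, h, skip)
  }
  h
}

graph_attention_gate <- function(tape, P, name, g, xl) {
  pg <- op_conv3d(tape, g, P[[paste0(name, ".wg.w")]], P[[paste0(name, ".wg.b")]], 1L)
  px <- op_conv3d(tape, xl, P[[paste0(name, ".wx.w")]], P[[paste0(name, ".wx.b")]], 2L, pad = 0L)
  a <- op_relu(tape, op_add(tape, pg, px))
  a <- op_conv3d(tape, a, P[[paste0(name, ".psi.w")]], P[[paste0(name, ".psi.b")]], 1L)
  a <- op_sigmoid(tape, a)
  a_up <- op_resize_trilinear(tape, a, vdim(xl$v)[1:3])
  list(gated = op_mul_bcast(tape, xl, a_up), alpha = a_up)
}

graph_ds_head <- function(tape, P, name, x, n_up, training) {
  h <- x
  for (t in seq_len(n_up)) {
    h <- op_convtranspose3d(tape, h, P[[sprintf("%s.up%d.w", name, t)]],
                            P[[sprintf("%s.up%d.b", name, t)]])
    h <- op_prelu(tape, h, P[[sprintf("%s.up%d.a", name, t)]])
  }
  h <- op_conv3d(tape, h, P[[paste0(name, ".proj.w")]], P[[paste0(name, ".proj.b")]], 1L)
  op_softmax_c(tape, h)
}

forward_graph <- function(tape, P, x_arr, config, training = FALSE) {
  cps <- config$convs_per_stage
  x <- nd_leaf(tape, as4d(x_arr), "input")
  enc <- vector("list", 5L)
  cur <- x
  for (i in 1:5) {
    cur <- graph_conv_block(tape, P, sprintf("enc%d", i), cur, cps[i], config, training)
    enc[[i]] <- cur
    if (i < 5L)
      cur <- graph_conv_unit(tape, P, sprintf("down%d", i), cur, stride = 2L,
                             dropout = config$dropout_rate, training = training)
  }
  d <- enc[[5]]
  branches <- list()
  alphas <- list()
  for (jj in 4:1) {
    skip <- enc[[jj]]
    if (config$use_attention_gates) {
      ag <- graph_attention_gate(tape, P, sprintf("ag%d", jj), d, skip)
      skip <- ag$gated
      alphas[[sprintf("stage%d", jj)]] <- ag$alpha
    }
    up <- op_convtranspose3d(tape, d, P[[sprintf("up%d.w", jj)]], P[[sprintf("up%d.b", jj)]])
    up <- op_prelu(tape, up, P[[sprintf("up%d.a", jj)]])
    up <- op_instnorm(tape, up, P[[sprintf("up%d.gamma", jj)]], P[[sprintf("up%d.beta", jj)]])
    cat_ <- op_concat_c(tape, up, skip)
    d <- graph_conv_block(tape, P, sprintf("dec%d", jj), cat_, cps[10L - jj], config, training)
    if (jj %in% config$deep_supervision_stages)
      branches[[sprintf("stage%d", jj)]] <-
        graph_ds_head(tape, P, sprintf("head%d", jj), d, jj - 1L, training)
  }
  h <- graph_conv_unit(tape, P, "out.conv", d, dropout = config$dropout_rate,
                       training = training)
  logits <- op_conv3d(tape, h, P[["out.proj.w"]], P[["out.proj.b"]], 1L)
  list(logits = logits, branches = branches, alphas = alphas)
}

check_input_dims <- function(d) {
  ax <- c("x", "y", "z")
  bad <- which(d[1:3] %% 16L != 0L)
  if (length(bad))
    stop(sprintf("input axis %s (%d voxels) is not divisible by 16",
                 ax[bad[1]], d[bad[1]]))
}

#' Run the network forward
#'
#' @param net A `vnet` from [build_network()] or [load_checkpoint()].
#' @param image An [image_volume] or 3D array with every spatial axis
#'   divisible by 16.
#' @param training Logical; enables dropout (inference is deterministic).
#' @param collect_attention Also return the upsampled attention-coefficient
#'   maps?
#' @return A `forward_output` list: `main_logits` ((X,Y,Z,2) pre-softmax),
#'   `branch_probabilities` (named list of full-size (X,Y,Z,2) softmax maps,
#'   one per supervised decoder stage) and optionally `attention`.
#' @export
forward <- function(net, image, training = FALSE, collect_attention = FALSE) {
  stopifnot(inherits(net, "vnet"))
  x <- if (inherits(image, "image_volume")) image$data else image
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("input must be a single-channel 3D volume")
  check_input_dims(d)
  tape <- new_tape()
  P <- leaf_params(tape, net$params)
  out <- forward_graph(tape, P, x, net$config, training)
  res <- list(main_logits = out$logits$v,
              branch_probabilities = lapply(out$branches, function(b) b$v))
  if (collect_attention) res$attention <- lapply(out$alphas, function(a) a$v)
  structure(res, class = "forward_output")
}

#' Threshold class scores into a binary mask
#'
#' Per-voxel argmax over the two class channels; exact ties are assigned to
#' background (a conservative rule that matters for the overlap counts).
#' Accepts either softmax probabilities or raw logits -- the argmax is
#' identical.
#'
#' @param scores (X,Y,Z,2) array: channel 1 background, channel 2 lesion.
#' @param spacing Voxel spacing recorded on the returned mask.
#' @return A [label_volume].
#' @export
predict_mask <- function(scores, spacing = c(1, 1, 1)) {
  d <- dim(scores)
  if (is.null(d) || length(d) != 4L || d[4] != 2L)
    stop("scores must be an (X,Y,Z,2) array")
  m <- (scores[, , , 2] > scores[, , , 1]) * 1.0
  dim(m) <- d[1:3]
  label_volume(m, spacing)
}

#' Analytic per-stage shape/channel trace
#'
#' Pure shape algebra for the configured architecture: encoder stage i sits
#' at `input / 2^(i-1)` with `stage_channels[i]` channels, mirrored by the
#' decoder, with a full-resolution output stage at stage-1 width.
#'
#' @param config A [network_config()].
#' @param input_size Length-3 input grid (each axis divisible by 16).
#' @return A data.frame with columns `stage`, `size_x`, `size_y`, `size_z`,
#'   `channels`.
#' @export
trace_shapes <- function(config = network_config(), input_size = c(128L, 128L, 48L)) {
  input_size <- as.integer(input_size)
  check_input_dims(input_size)
  ch <- config$stage_channels
  rows <- list()
  for (i in 1:5) {
    s <- input_size %/% 2L^(i - 1L)
    rows[[length(rows) + 1L]] <- data.frame(stage = sprintf("Left-S %d", i),
                                            size_x = s[1], size_y = s[2], size_z = s[3],
                                            channels = ch[i])
  }
  for (jj in 4:1) {
    s <- input_size %/% 2L^(jj - 1L)
    rows[[length(rows) + 1L]] <- data.frame(stage = sprintf("Right-S %d", jj),
                                            size_x = s[1], size_y = s[2], size_z = s[3],
                                            channels = ch[jj])
  }
  rows[[length(rows) + 1L]] <- data.frame(stage = "output",
                                          size_x = input_size[1], size_y = input_size[2],
                                          size_z = input_size[3], channels = ch[1])
  do.call(rbind, rows)
}

# ---- standalone module surfaces -------------------------------------------

#' Attention-gate specification
#'
#' @param gate_channels Channels of the gating (decoder) feature map.
#' @param skip_channels Channels of the encoder skip map.
#' @param inter_channels Width of the joint projection space (default
#'   `skip_channels %/% 2`, minimum 1).
#' @return An `attention_gate_spec` list.
#' @export
attention_gate_spec <- function(gate_channels, skip_channels,
                                inter_channels = max(1L, skip_channels %/% 2L)) {
  if (gate_channels < 1L || skip_channels < 1L || inter_channels < 1L)
    stop("all channel counts must be >= 1")
  structure(list(gate_channels = as.integer(gate_channels),
                 skip_channels = as.integer(skip_channels),
                 inter_channels = as.integer(inter_channels)),
            class = "attention_gate_spec")
}

init_attention_params <- function(spec, seed = NULL) {
  f <- function() list(
    wg = conv_unit_params(1L, spec$gate_channels, spec$inter_channels, norm = FALSE, act = FALSE),
    wx = conv_unit_params(1L, spec$skip_channels, spec$inter_channels, norm = FALSE, act = FALSE),
    psi = conv_unit_params(1L, spec$inter_channels, 1L, norm = FALSE, act = FALSE))
  if (is.null(seed)) f() else with_preserved_rng(seed, f())
}

#' Apply a standalone attention gate
#'
#' Both maps are projected to the joint width by 1x1x1 convolutions (the
#' skip map with stride 2, onto the gating grid), added, rectified, projected
#' to one channel and squashed by a sigmoid; the resulting coefficient map
#' `alpha` (values strictly in (0,1)) is resampled trilinearly to the skip
#' grid and multiplied into the skip features channel-wise.
#'
#' @param g Gating feature map, (X,Y,Z,C_g) array at the coarser grid.
#' @param x_l Skip feature map, (2X,2Y,2Z,C_x) array.
#' @param spec An [attention_gate_spec()].
#' @param params Optional parameter list (as from the internal initialiser);
#'   fresh He-initialised weights are drawn when omitted.
#' @param seed Seed for fresh weights.
#' @return List with `gated` (same shape as `x_l`) and `alpha`
#'   ((2X,2Y,2Z,1) coefficients).
#' @export
attention_gate <- function(g, x_l, spec, params = NULL, seed = 1L) {
  stopifnot(inherits(spec, "attention_gate_spec"))
  gd <- dim(g); xd <- dim(x_l)
  if (length(gd) != 4L || length(xd) != 4L) stop("feature maps must be (X,Y,Z,C) arrays")
  if (gd[4] != spec$gate_channels || xd[4] != spec$skip_channels)
    stop("channel counts disagree with the spec")
  if (any(xd[1:3] < gd[1:3])) stop("the gating map must not exceed the skip map spatially")
  if (is.null(params)) params <- init_attention_params(spec, seed)
  tape <- new_tape()
  P <- list()
  for (blk in names(params)) for (nm in names(params[[blk]]))
    P[[paste0("ag.", blk, ".", nm)]] <- nd_leaf(tape, params[[blk]][[nm]])
  res <- graph_attention_gate(tape, P, "ag", nd_leaf(tape, g), nd_leaf(tape, x_l))
  list(gated = res$gated$v, alpha = res$alpha$v)
}

#' Apply a standalone deep-supervision head
#'
#' Repeated stride-2 transposed convolutions (one per factor of 2, each
#' followed by a PReLU) bring the stage features to full size, then a 1x1x1
#' projection to `num_classes` channels and a softmax.
#'
#' @param stage_features (X,Y,Z,C) array of decoder-stage features.
#' @param upsample_factor Power of two relating stage to input resolution.
#' @param num_classes Output channels.
#' @param kernel_size Transposed-convolution kernel edge.
#' @param params Optional parameter list; fresh weights drawn when omitted.
#' @param seed Seed for fresh weights.
#' @return Softmax probability map at `upsample_factor` times the spatial
#'   size (channel sums 1).
#' @export
deep_supervision_head <- function(stage_features, upsample_factor, num_classes = 2L,
                                  kernel_size = 3L, params = NULL, seed = 1L) {
  d <- dim(stage_features)
  if (length(d) != 4L) stop("stage_features must be an (X,Y,Z,C) array")
  lf <- log2(upsample_factor)
  if (upsample_factor < 1 || abs(lf - round(lf)) > 1e-9)
    stop("upsample_factor must be a power of two")
  n_up <- as.integer(round(lf))
  if (is.null(params)) {
    hc <- ds_head_channels(d[4], n_up)
    cin <- d[4]
    params <- with_preserved_rng(seed, {
      pp <- list()
      for (t in seq_len(n_up)) {
        pp[[sprintf("up%d", t)]] <- conv_unit_params(kernel_size, cin, hc[t], norm = FALSE)
        cin <- hc[t]
      }
      pp$proj <- conv_unit_params(1L, cin, as.integer(num_classes), norm = FALSE, act = FALSE)
      pp
    })
  }
  tape <- new_tape()
  P <- list()
  for (blk in names(params)) for (nm in names(params[[blk]]))
    P[[paste0("head.", blk, ".", nm)]] <- nd_leaf(tape, params[[blk]][[nm]])
  graph_ds_head(tape, P, "head", nd_leaf(tape, stage_features), n_up, FALSE)$v
}

# ---- checkpoints -----------------------------------------------------------

#' Save network weights and configuration to a single file
#' @param net A `vnet`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "vnet"))
  saveRDS(list(config = unclass(net$config), params = net$params,
               format = "vnetseg-checkpoint-1"), path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path Checkpoint file.
#' @return A `vnet` with the stored weights and configuration.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "vnetseg-checkpoint-1")) stop("not a recognised checkpoint")
  cfg <- do.call(network_config, ck$config[setdiff(names(ck$config), character())])
  structure(list(config = cfg, params = ck$params), class = "vnet")
}
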
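# Training loop: Adam at an exponentially decaying learning rate, batch-1
# iteration over preprocessed cases, the deep-supervision combined objective,
# best-checkpoint selection by validation DSC, dataset splitting, and a
# scaled-down ablation harness over structure tuples and kernel sizes.

#' Training configuration
#'
#' The recipe: Adam (first-moment decay 0.9), initial learning rate 2e-4
#' decaying exponentially by 0.999 per epoch, batch size 1, Dice objective.
#' The full-scale schedule runs 600 epochs; desk-scale experiments use far
#' fewer, so pass `epochs` explicitly.
#'
#' @param lr0 Initial learning rate (> 0).
#' @param lr_decay Per-epoch multiplicative decay in (0, 1].
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Cases per optimizer step (>= 1; gradients are averaged).
#' @param adam_beta1 Adam first-moment decay ("momentum").
#' @param seed Integer seed controlling init, shuffling, dropout and
#'   augmentation.
#' @param augment Add Gaussian noise to training images each epoch?
#' @param augment_sigma Noise sd used when `augment` is on.
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 2e-4, lr_decay = 0.999, epochs = 600L,
                         batch_size = 1L, adam_beta1 = 0.9, seed = 1L,
                         augment = FALSE, augment_sigma = 0.05) {
  if (lr0 <= 0) stop("lr0 must be > 0")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must lie in (0, 1]")
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(lr0 = lr0, lr_decay = lr_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), adam_beta1 = adam_beta1,
                 seed = as.integer(seed), augment = isTRUE(augment),
                 augment_sigma = augment_sigma),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' `lr(epoch) = lr0 * lr_decay^epoch`.
#'
#' @param config A [train_config()].
#' @param epoch Integer >= 0.
#' @return The learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  if (epoch < 0) stop("epoch must be >= 0")
  config$lr0 * config$lr_decay^epoch
}

#' Split case ids into train / validation / test partitions
#'
#' Deterministic seeded shuffle, then floor allocation by the given ratios
#' with all remainders granted to the training partition; the partitions are
#' disjoint and exhaustive.  245 cases at 6:2:2 give exactly 147/49/49.
#'
#' @param case_ids Non-empty vector of identifiers.
#' @param ratios Three positive weights (train, validation, test).
#' @param seed Shuffle seed.
#' @return List of id vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(case_ids, ratios = c(6, 2, 2), seed = 1L) {
  if (!length(case_ids)) stop("case list is empty")
  if (length(ratios) != 3L || any(ratios <= 0)) stop("ratios must be three positive values")
  n <- length(case_ids)
  if (n < 3L) stop("fewer cases than partitions")
  perm <- with_preserved_rng(seed, sample.int(n))
  ids <- case_ids[perm]
  s <- sum(ratios)
  n_val <- floor(n * ratios[2] / s)
  n_test <- floor(n * ratios[3] / s)
  n_train <- n - n_val - n_test
  list(train = ids[seq_len(n_train)],
       validation = ids[n_train + seq_len(n_val)],
       test = ids[n_train + n_val + seq_len(n_test)])
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- loss graph ------------------------------------------------------------

graph_case_loss <- function(tape, P, image_arr, label_arr, config, ds_spec, eta,
                            training = TRUE) {
  out <- forward_graph(tape, P, image_arr, config, training)
  probs <- op_softmax_c(tape, out$logits)
  base <- function(p) {
    switch(ds_spec$base_loss,
           dice = op_dice_loss(tape, p, label_arr),
           nll = op_nll_loss(tape, p, label_arr),
           `dice+nll` = op_weighted_sum(tape, op_dice_loss(tape, p, label_arr),
                                        list(op_nll_loss(tape, p, label_arr)), 1))
  }
  main <- base(probs)
  br_nodes <- list()
  br_eta <- numeric()
  for (i in seq_along(ds_spec$stage_ids)) {
    key <- sprintf("stage%d", ds_spec$stage_ids[i])
    if (!is.null(out$branches[[key]])) {
      br_nodes[[length(br_nodes) + 1L]] <- base(out$branches[[key]])
      br_eta <- c(br_eta, eta[i])
    }
  }
  total <- op_weighted_sum(tape, main, br_nodes, br_eta)
  list(total = total, main = main, branches = br_nodes)
}

case_arrays <- function(case) {
  img <- if (inherits(case$image, "image_volume")) case$image$data else case$image
  lab <- if (inherits(case$label, "label_volume")) case$label$data else case$label
  list(image = img, label = lab)
}

#' Train a network
#'
#' Iterates the training cases at batch size `batch_size` (gradients
#' averaged within a batch), computing the combined deep-supervision
#' objective with epoch-decayed balance weights and taking an Adam step at
#' the epoch's learning rate.  When a validation set is supplied, mean
#' validation DSC is computed each epoch and the best-scoring weights are
#' retained (and written to `out_dir/checkpoints/best` when `out_dir` is
#' set, alongside `last` and a per-step `metrics.csv`).
#'
#' @param dataset Non-empty list of preprocessed cases, each a list with
#'   `image` and `label` on a grid divisible by 16.
#' @param net_config A [network_config()].
#' @param tconfig A [train_config()].
#' @param ds_spec A [deep_supervision_spec()].
#' @param val_dataset Optional list of cases for model selection.
#' @param out_dir Optional run directory.
#' @param max_steps Optional cap on total optimizer steps.
#' @param verbose Print per-epoch progress?
#' @return List: `net` (final weights), `best_net` (best-validation weights,
#'   or final when no validation set), `history` (per-step data.frame),
#'   `val_history`, `steps`.
#' @export
train <- function(dataset, net_config = tiny_network_config(),
                  tconfig = train_config(epochs = 5L),
                  ds_spec = deep_supervision_spec(),
                  val_dataset = NULL, out_dir = NULL, max_steps = Inf,
                  verbose = FALSE) {
  if (!length(dataset)) stop("empty dataset")
  set.seed(tconfig$seed)
  net <- build_network(net_config, seed = tconfig$seed)
  params <- net$params
  state <- adam_init(params)
  history <- list()
  val_history <- list()
  best <- list(dsc = -Inf, params = params, epoch = NA_integer_)
  steps <- 0L
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "checkpoints"), recursive = TRUE, showWarnings = FALSE)
  }
  for (epoch in seq_len(tconfig$epochs)) {
    if (steps >= max_steps) break
    lr <- lr_at_epoch(tconfig, epoch - 1L)
    eta <- eta_at_epoch(ds_spec, epoch - 1L)
    order_ <- sample.int(length(dataset))
    bi <- 0L
    acc <- NULL
    acc_n <- 0L
    batch_losses <- c(total = 0, main = 0)
    for (ci in order_) {
      if (steps >= max_steps) break
      case <- case_arrays(dataset[[ci]])
      img <- case$image
      if (tconfig$augment && tconfig$augment_sigma > 0)
        img <- img + rnorm(length(img), 0, tconfig$augment_sigma)
      tape <- new_tape()
      P <- leaf_params(tape, params)
      ls <- graph_case_loss(tape, P, img, case$label, net_config, ds_spec, eta)
      if (!is.finite(ls$total$v))
        stop(sprintf("non-finite loss at epoch %d (total=%g, main=%g)",
                     epoch, ls$total$v, ls$main$v))
      tape_backward(tape, ls$total)
      g <- lapply(P, function(nd) nd$g)
      if (is.null(acc)) acc <- g
      else for (nm in names(acc)) if (!is.null(g[[nm]]))
        acc[[nm]] <- (acc[[nm]] %||% 0) + g[[nm]]
      acc_n <- acc_n + 1L
      batch_losses <- batch_losses + c(ls$total$v, ls$main$v)
      bi <- bi + 1L
      if (bi == tconfig$batch_size || ci == order_[length(order_)]) {
        acc <- lapply(acc, function(a) if (is.null(a)) NULL else a / acc_n)
        upd <- adam_step(params, acc, state, lr, tconfig$adam_beta1)
        params <- upd$params
        state <- upd$state
        steps <- steps + 1L
        history[[length(history) + 1L]] <- data.frame(
          epoch = epoch, step = steps, lr = lr,
          loss = unname(batch_losses[1]) / acc_n,
          main_loss = unname(batch_losses[2]) / acc_n,
          n_branches = length(ls$branches))
        bi <- 0L; acc <- NULL; acc_n <- 0L
        batch_losses <- c(total = 0, main = 0)
      }
    }
    net$params <- params
    if (!is.null(val_dataset) && length(val_dataset)) {
      vds <- vapply(val_dataset, function(vc) {
        ca <- case_arrays(vc)
        fo <- forward(net, ca$image)
        pm <- predict_mask(fo$main_logits)
        dsc(confusion_counts(pm$data, ca$label))
      }, 0)
      vmean <- mean(vds)
      val_history[[length(val_history) + 1L]] <-
        data.frame(epoch = epoch, val_dsc = vmean)
      if (vmean > best$dsc) {
        best <- list(dsc = vmean, params = params, epoch = epoch)
        if (!is.null(out_dir))
          save_checkpoint(structure(list(config = net_config, params = params),
                                    class = "vnet"),
                          file.path(out_dir, "checkpoints", "best"))
      }
      if (verbose) message(sprintf("epoch %3d  lr %.3g  loss %.4f  val DSC %.4f",
                                   epoch, lr, history[[length(history)]]$loss, vmean))
    } else if (verbose) {
      message(sprintf("epoch %3d  lr %.3g  loss %.4f", epoch, lr,
                      history[[length(history)]]$loss))
    }
  }
  net$params <- params
  history <- do.call(rbind, history)
  val_history <- if (length(val_history)) do.call(rbind, val_history) else NULL
  if (!is.null(out_dir)) {
    save_checkpoint(net, file.path(out_dir, "checkpoints", "last"))
    write.csv(history, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  }
  best_net <- if (is.finite(best$dsc))
    structure(list(config = net_config, params = best$params), class = "vnet")
  else net
  list(net = net, best_net = best_net, history = history,
       val_history = val_history, steps = steps,
       best_epoch = best$epoch)
}

#' Ablation harness over structure tuples and kernel sizes
#'
#' Trains one model per grid entry under identical seeds and data, evaluates
#' on the test cases and reports mean and sd of DSC, IOU, sensitivity,
#' precision and HD(mm) -- the desk-scale analogue of a structure/kernel
#' ablation table.  No claim is made of matching any full-scale result.
#'
#' @param grid List of variants, each a list with `structure` (9-long
#'   convolutions-per-stage tuple) and `kernel_size` (3 or 5).
#' @param dataset Training cases (preprocessed).
#' @param test_dataset Held-out cases for the metric columns.
#' @param net_config Base [network_config()] the variants modify.
#' @param tconfig A [train_config()].
#' @param ds_spec A [deep_supervision_spec()].
#' @return A data.frame: one row per variant with `mean`/`sd` columns per
#'   metric.
#' @export
ablation_harness <- function(grid, dataset, test_dataset,
                             net_config = tiny_network_config(),
                             tconfig = train_config(epochs = 2L),
                             ds_spec = deep_supervision_spec()) {
  if (!length(grid)) stop("empty ablation grid")
  rows <- lapply(grid, function(variant) {
    cfg <- network_config(
      stage_channels = net_config$stage_channels,
      convs_per_stage = variant$structure %||% net_config$convs_per_stage,
      kernel_size = variant$kernel_size %||% net_config$kernel_size,
      dropout_rate = net_config$dropout_rate,
      use_attention_gates = net_config$use_attention_gates,
      deep_supervision_stages = net_config$deep_supervision_stages,
      in_channels = net_config$in_channels,
      num_classes = net_config$num_classes,
      use_residual = net_config$use_residual)
    fit <- train(dataset, cfg, tconfig, ds_spec)
    reports <- lapply(test_dataset, function(tc) {
      ca <- case_arrays(tc)
      fo <- forward(fit$net, ca$image)
      pm <- predict_mask(fo$main_logits)
      sp <- if (inherits(tc$label, "label_volume")) tc$label$spacing else c(1, 1, 1)
      evaluate_case(pm$data, ca$label, sp)
    })
    agg <- aggregate_reports(reports)
    out <- data.frame(structure = paste(cfg$convs_per_stage, collapse = ","),
                      kernel_size = cfg$kernel_size)
    for (i in seq_len(nrow(agg))) {
      out[[paste0(agg$metric[i], "_mean")]] <- agg$mean[i]
      out[[paste0(agg$metric[i], "_sd")]] <- agg$sd[i]
    }
    out
  })
  do.call(rbind, rows)
}
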
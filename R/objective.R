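# Training objectives: stabilised softmax, voxel-mean negative
# log-likelihood, squared-denominator soft Dice, and the deep-supervision
# combined loss with per-epoch decaying balance weights.
#
# These are the plain-numeric definitions; the trainer's differentiable graph
# ops reuse the same formulas and are cross-checked against these in tests.

#' Deep-supervision specification
#'
#' Describes which decoder stages carry auxiliary loss heads and how their
#' balance weights decay.  Stage ids follow decoder depth: stage 4 sits at
#' 1/8 of the input resolution, stage 3 at 1/4, stage 2 at 1/2.  The default
#' supervises those three stages with initial weights 0.5, 0.25, 0.125
#' (deepest to shallowest) decaying by a factor 0.99 per epoch.
#'
#' @param stage_ids Ordered decoder stages carrying branch heads.
#' @param eta0 Initial balance weight per stage (same length, all >= 0).
#' @param eta_decay Multiplicative per-epoch decay factor in (0, 1].
#' @param base_loss Loss used for main and branch terms: `"dice"`, `"nll"`
#'   or `"dice+nll"`.
#' @return A `deep_supervision_spec` list.
#' @export
deep_supervision_spec <- function(stage_ids = c(4L, 3L, 2L),
                                  eta0 = c(0.5, 0.25, 0.125),
                                  eta_decay = 0.99,
                                  base_loss = c("dice", "nll", "dice+nll")) {
  base_loss <- match.arg(base_loss)
  stage_ids <- as.integer(stage_ids)
  if (length(eta0) != length(stage_ids))
    stop("eta0 must have one weight per supervised stage")
  if (any(eta0 < 0)) stop("balance weights must be >= 0")
  if (eta_decay <= 0 || eta_decay > 1) stop("eta_decay must lie in (0, 1]")
  structure(list(stage_ids = stage_ids, eta0 = as.numeric(eta0),
                 eta_decay = eta_decay, base_loss = base_loss),
            class = "deep_supervision_spec")
}

#' Balance weights at a given epoch
#'
#' `eta_m(epoch) = eta0_m * eta_decay^epoch`.
#'
#' @param spec A [deep_supervision_spec].
#' @param epoch Integer >= 0.
#' @return Numeric vector of weights, one per supervised stage.
#' @export
eta_at_epoch <- function(spec, epoch) {
  stopifnot(inherits(spec, "deep_supervision_spec"))
  if (epoch < 0) stop("epoch must be >= 0")
  spec$eta0 * spec$eta_decay^epoch
}

#' Numerically stable channel softmax
#'
#' Exponential normalisation over the last array axis (the class channel),
#' stabilised by per-voxel max subtraction so arbitrarily large logits do not
#' overflow.
#'
#' @param logits Array whose last axis indexes classes (e.g. (X,Y,Z,C)), or
#'   a matrix (voxels x classes).
#' @return Probabilities of the same shape; channel sums are 1.
#' @export
softmax_probabilities <- function(logits) {
  if (any(!is.finite(logits))) stop("non-finite logits")
  d <- dim(logits)
  if (is.null(d)) { d <- c(1L, length(logits)); dim(logits) <- d }
  nc <- d[length(d)]
  nsp <- prod(d[-length(d)])
  m <- logits
  dim(m) <- c(nsp, nc)
  mx <- do.call(pmax, lapply(seq_len(nc), function(j) m[, j]))
  e <- exp(m - mx)
  p <- e / .rowSums(e, nsp, nc)
  dim(p) <- d
  p
}

check_binary_labels <- function(labels) {
  v <- as.numeric(labels)
  if (!all(v %in% c(0, 1))) stop("labels must lie in {0, 1}")
  v
}

#' Mean negative log-likelihood loss
#'
#' The mean over voxels of the negative log of the probability assigned to
#' the true class, with a probability floor of 1e-12.  The mean (rather than
#' a sum over voxels) makes the loss magnitude independent of crop size.
#'
#' @param probabilities (X,Y,Z,C) class-probability array (C >= 2; class 1 =
#'   background in channel 1, foreground in channel 2) or (voxels x C)
#'   matrix.
#' @param labels Binary array of true classes matching the spatial grid.
#' @param floor Probability floor.
#' @return Scalar loss >= 0.
#' @export
nll_loss <- function(probabilities, labels, floor = 1e-12) {
  lab <- check_binary_labels(labels)
  d <- dim(probabilities)
  nc <- d[length(d)]
  nsp <- prod(d[-length(d)])
  if (nsp != length(lab)) stop("probability and label grids differ")
  m <- probabilities
  dim(m) <- c(nsp, nc)
  pt <- m[cbind(seq_len(nsp), as.integer(lab) + 1L)]
  -mean(log(pmax(pt, floor)))
}

#' Soft Dice loss (squared-denominator form)
#'
#' `1 - (2 sum(p g) + s) / (sum(p^2) + sum(g^2) + s)` over the foreground
#' channel, the overlap objective suited to segmenting lesions that occupy a
#' tiny fraction of the volume.
#'
#' @param probabilities Foreground probabilities in \[0, 1\]: a 3D array, or
#'   an (X,Y,Z,C) array whose last channel is foreground.
#' @param labels Binary reference mask of the same spatial grid.
#' @param smooth Smoothing constant `s`.
#' @return Scalar loss in \[0, 1\] (up to the smooth term).
#' @export
dice_loss <- function(probabilities, labels, smooth = 1e-5) {
  g <- check_binary_labels(labels)
  p <- probabilities
  d <- dim(p)
  if (!is.null(d) && length(d) == 4L) p <- p[, , , d[4]]
  p <- as.numeric(p)
  if (length(p) != length(g)) stop("probability and label grids differ")
  num <- 2 * sum(p * g) + smooth
  den <- sum(p * p) + sum(g * g) + smooth
  1 - num / den
}

#' Deep-supervision combined loss
#'
#' `total = main + sum(eta_m * branch_m)`, returning the per-term breakdown
#' for logging.
#'
#' @param main_loss Scalar main-branch loss.
#' @param branch_losses Numeric vector of auxiliary losses (may be empty).
#' @param eta Balance weights, same length as `branch_losses`.
#' @return List with `total`, `main`, `branch`, `eta`, `weighted_branch`.
#' @export
combined_loss <- function(main_loss, branch_losses = numeric(), eta = numeric()) {
  if (length(branch_losses) != length(eta))
    stop("branch_losses and eta must have equal length")
  if (any(!is.finite(c(main_loss, branch_losses, eta))))
    stop("non-finite loss terms")
  wb <- eta * branch_losses
  list(total = main_loss + sum(wb), main = main_loss,
       branch = branch_losses, eta = eta, weighted_branch = wb)
}
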
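## Joint training engine for the Jensen-Shannon bound: hand-written
## backpropagation for the inner-product critic and Adam ascent. The same
## gradient pass also returns the gradient of the bound with respect to the
## activity batch, which the layer-wise circuit optimizer chains into W, E,
## or G.

adamInit <- function(params) {
  zeroes <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zeroes, v = zeroes, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## One Adam ascent step; returns updated params and state.
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] +
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

## Adam-style preconditioning of a single gradient array (used for the
## circuit duals before the mirror-descent step).
adamPrecond <- function(grad, state, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  dir <- (state$m / (1 - beta1^state$t)) /
    (sqrt(state$v / (1 - beta2^state$t)) + eps)
  list(dir = dir, state = state)
}

adamPrecondInit <- function(shape) {
  list(m = array(0, dim = shape), v = array(0, dim = shape), t = 0L)
}

## Forward + backward pass of the Jensen-Shannon objective on one batch.
##
## Computes the bound log 2 - (mean softplus(-v_joint) + mean softplus(
## v_shuffled)) / 2 (the standard-JSD normalization of the variational
## objective) and its gradients with respect to the critic parameters and
## the activity matrix. The shuffled pairs reuse the chi embeddings of the
## joint batch via the permutation, so each network runs forward and
## backward once.
boundStepGrads <- function(critic, act, stim, perm) {
  cx <- stimInput(critic, stim)
  b <- nrow(act)
  if (critic$architecture == "joint") {
    fwJ <- mlpForward(critic$chi, cbind(act, cx))
    fwS <- mlpForward(critic$chi, cbind(act[perm, , drop = FALSE], cx))
    vJ <- drop(fwJ$out); vS <- drop(fwS$out)
    value <- ln2 - (mean(softplus(-vJ)) + mean(softplus(vS))) / 2
    dvJ <- matrix(sigmoid(-vJ) / (2 * b), b, 1L)
    dvS <- matrix(-sigmoid(vS) / (2 * b), b, 1L)
    bkJ <- mlpBackward(critic$chi, fwJ, dvJ)
    bkS <- mlpBackward(critic$chi, fwS, dvS)
    grads <- mapply(`+`, bkJ$grads, bkS$grads, SIMPLIFY = FALSE)
    dAct <- bkJ$dX[, seq_len(ncol(act)), drop = FALSE]
    dActS <- bkS$dX[, seq_len(ncol(act)), drop = FALSE]
    dAct[perm, ] <- dAct[perm, , drop = FALSE] + dActS
    return(list(value = value, chiGrads = grads, psiGrads = NULL,
                dAct = dAct))
  }
  fc <- mlpForward(critic$chi, act)
  fp <- mlpForward(critic$psi, cx)
  vJ <- rowSums(fc$out * fp$out)
  chiPerm <- fc$out[perm, , drop = FALSE]
  vS <- rowSums(chiPerm * fp$out)
  value <- ln2 - (mean(softplus(-vJ)) + mean(softplus(vS))) / 2
  dvJ <- sigmoid(-vJ) / (2 * b)        # d value / d vJ_i
  dvS <- -sigmoid(vS) / (2 * b)
  dChiOut <- fp$out * dvJ
  dChiOut[perm, ] <- dChiOut[perm, , drop = FALSE] + fp$out * dvS
  dPsiOut <- fc$out * dvJ + chiPerm * dvS
  bc <- mlpBackward(critic$chi, fc, dChiOut)
  bp <- mlpBackward(critic$psi, fp, dPsiOut)
  list(value = value, chiGrads = bc$grads, psiGrads = bp$grads,
       dAct = bc$dX)
}

## Apply one Adam step to both critic networks.
criticAscend <- function(critic, grads, states, lr) {
  up <- adamStep(critic$chi, grads$chiGrads, states$chi, lr)
  critic$chi <- up$params; states$chi <- up$state
  if (!is.null(critic$psi)) {
    up <- adamStep(critic$psi, grads$psiGrads, states$psi, lr)
    critic$psi <- up$params; states$psi <- up$state
  }
  list(critic = critic, states = states)
}

criticStatesInit <- function(critic) {
  list(chi = adamInit(critic$chi),
       psi = if (is.null(critic$psi)) NULL else adamInit(critic$psi))
}

#' Train a Jensen-Shannon critic on paired samples
#'
#' Fits the inner-product critic to a fixed dataset of (activity, stimulus)
#' pairs by stochastic ascent on the variational Jensen-Shannon bound, then
#' evaluates the trained bound on the full dataset with a fresh shuffle.
#' This is the estimator used on its own (dependence measurement between
#' two sample sets); the circuit optimizers embed the same gradient engine.
#'
#' @param x Matrix of activity samples (rows).
#' @param y Matrix of stimulus samples, same number of rows.
#' @param nSteps Number of ascent steps.
#' @param batchSize Minibatch size.
#' @param hidden Hidden width of the critic networks.
#' @param embedDim Embedding dimension.
#' @param learningRate Adam step size.
#' @param stimTransform Input transform for the stimulus branch.
#' @param evalShuffles Number of fresh permutations averaged in the final
#'   evaluation.
#' @param seed Integer seed.
#' @return A list with `bound` (list `value`, `nJoint`, `nMarginal`),
#'   `critic`, and `trace` (per-step minibatch bound values).
#' @export
trainJsdCritic <- function(x, y, nSteps = 600L, batchSize = 256L,
                           hidden = 64L, embedDim = 32L,
                           learningRate = 1e-3,
                           stimTransform = "identity",
                           evalShuffles = 8L, seed = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 2L)
  critic <- initCritic(ncol(x), ncol(y), hidden = hidden,
                       embedDim = embedDim, stimTransform = stimTransform,
                       seed = deriveSeed(seed, "critic-init"))
  states <- criticStatesInit(critic)
  n <- nrow(x)
  trace <- numeric(nSteps)
  withSeed(deriveSeed(seed, "critic-train"), {
    for (s in seq_len(nSteps)) {
      idx <- if (n > batchSize) sample.int(n, batchSize) else seq_len(n)
      perm <- sample.int(length(idx))
      gr <- boundStepGrads(critic, x[idx, , drop = FALSE],
                           y[idx, , drop = FALSE], perm)
      trace[s] <- gr$value
      up <- criticAscend(critic, gr, states, learningRate)
      critic <- up$critic; states <- up$states
    }
  })
  value <- evaluateBound(critic, x, y, evalShuffles,
                         deriveSeed(seed, "critic-eval"))
  list(bound = list(value = value, nJoint = n,
                    nMarginal = n * evalShuffles),
       critic = critic, trace = trace)
}

#' Evaluate a critic's Jensen-Shannon bound on a dataset
#'
#' Computes the bound on the given (activity, stimulus) pairs, averaging
#' the product-of-marginals term over several independent shuffles. Use
#' held-out pairs to obtain an unbiased estimate of the trained critic's
#' bound (evaluating on the training set inherits its adaptation noise).
#'
#' @param critic A trained critic.
#' @param x,y Paired sample matrices.
#' @param nShuffles Independent permutations averaged for the marginal
#'   term.
#' @param seed Integer seed for the permutations.
#' @return The bound estimate in nats.
#' @export
evaluateJsdBound <- function(critic, x, y, nShuffles = 8L, seed = 1L) {
  evaluateBound(critic, as.matrix(x), as.matrix(y), nShuffles, seed)
}

## Full-data bound with several independent shuffles for the marginal term.
evaluateBound <- function(critic, x, y, nShuffles = 8L, seed = 1L) {
  tj <- criticScore(critic, x, y)
  marg <- withSeed(seed, {
    vapply(seq_len(nShuffles), function(i) {
      perm <- sample.int(nrow(x))
      ts <- criticScore(critic, x[perm, , drop = FALSE], y)
      mean(softplus(qsquashInverse(ts)) - ln2)
    }, numeric(1))
  })
  (mean(tj) - mean(marg)) / 2
}
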
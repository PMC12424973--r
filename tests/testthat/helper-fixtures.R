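## Small fixtures shared across test files.

smallSpec <- function(seed = 1L, ...) {
  environmentSpec(nOdorants = 40L, nBlocks = 4L, seed = seed, ...)
}

## A fixed positive sensing matrix with a known log-normal shape.
fixtureSensing <- function(M = 6L, N = 120L, seed = 3L, logSD = 1) {
  set.seed(seed)
  matrix(exp(logSD * rnorm(M * N)), M, N)
}

## Brute-force union length of Hill response windows on a log10 grid.
bruteDynamicRange <- function(W, n, loResp, hiResp, gridStep = 1e-3) {
  xLo <- (loResp / (1 - loResp))^(1 / n)
  xHi <- (hiResp / (1 - hiResp))^(1 / n)
  sapply(seq_len(ncol(W)), function(j) {
    w <- W[, j]
    lims <- range(c(log10(xLo / w), log10(xHi / w)))
    grid <- seq(lims[1] - 0.5, lims[2] + 0.5, by = gridStep)
    conc <- 10^grid
    covered <- rep(FALSE, length(grid))
    for (wi in w) {
      resp <- hillActivation(wi * conc, n)
      covered <- covered | (resp >= loResp & resp <= hiResp)
    }
    sum(covered) * gridStep
  })
}

## Exhaustive Jensen-Shannon divergence between a discrete joint pmf and
## the product of its marginals (nats).
discreteJSD <- function(joint) {
  joint <- joint / sum(joint)
  prod <- outer(rowSums(joint), colSums(joint))
  m <- (joint + prod) / 2
  kl <- function(p, q) {
    ok <- p > 0
    sum(p[ok] * log(p[ok] / q[ok]))
  }
  0.5 * kl(joint, m) + 0.5 * kl(prod, m)
}
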
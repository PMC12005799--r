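# Internal numeric helpers shared by the neural-network modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with the usual max-shift for stability.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# PReLU with a single learnable slope per layer.
prelu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

# Backward pass of prelu: returns grad wrt pre-activation and wrt slope.
prelu_backward <- function(grad_out, pre, slope) {
  neg <- pre < 0
  gx <- grad_out
  gx[neg] <- gx[neg] * slope
  list(grad_pre = gx, grad_slope = sum(grad_out[neg] * pre[neg]))
}

# Glorot-uniform weight init, seeded by the caller's RNG state.
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Minimal Adam optimizer over a named list of numeric arrays.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
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

# Dense pairwise Euclidean distance matrix (zero diagonal).
pairwise_dist <- function(x) {
  x <- as.matrix(x)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  d
}

# Min-max normalize the off-diagonal entries of a distance matrix to [0, 1].
# Returns the scaled matrix plus the constants, which gradient code treats as
# fixed. Degenerate (constant) matrices normalize to all-zero.
minmax_offdiag <- function(d) {
  n <- nrow(d)
  off <- d[row(d) != col(d)]
  if (length(off) == 0L) {
    return(list(scaled = d * 0, lo = 0, span = 1))
  }
  lo <- min(off)
  hi <- max(off)
  span <- hi - lo
  if (span <= 0) {
    return(list(scaled = d * 0, lo = lo, span = 1))
  }
  s <- (d - lo) / span
  diag(s) <- 0
  s[s < 0] <- 0
  list(scaled = s, lo = lo, span = span)
}

# Gradient of sum_ij C_ij * u_ij wrt the raw distance matrix E, where
# u = (E - lo)/(hi - lo) is the off-diagonal min-max normalization of E
# (mm = minmax_offdiag(E)). Beyond the direct C/span term, lo and hi are
# attained at specific pairs, so dL/dlo and dL/dhi are routed to the first
# argmin/argmax pair (split over its two symmetric entries).
dmat_through_minmax <- function(C, E, mm) {
  span <- mm$span
  W <- C / span
  lo <- mm$lo
  hi <- lo + span
  offmask <- row(E) != col(E)
  g_hi <- -sum(C * (E - lo)) / span^2
  g_lo <- sum(C * (E - hi)) / span^2
  imax <- which(offmask & E == max(E[offmask]))[1L]
  imin <- which(offmask & E == min(E[offmask]))[1L]
  n <- nrow(E)
  mirror <- function(ix) {
    i <- (ix - 1L) %% n + 1L
    j <- (ix - 1L) %/% n + 1L
    (i - 1L) * n + j
  }
  W[imax] <- W[imax] + g_hi / 2
  W[mirror(imax)] <- W[mirror(imax)] + g_hi / 2
  W[imin] <- W[imin] + g_lo / 2
  W[mirror(imin)] <- W[mirror(imin)] + g_lo / 2
  W
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
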
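# Internal helpers shared across modules: deterministic seed substreams,
# grouped (segment) reductions used by the attention layers, and a small
# Adam optimizer operating on named lists of numeric arrays.

#' Derive a deterministic substream seed
#'
#' All randomness in the pipeline flows from one root seed; each named
#' stage derives its own reproducible substream so that re-running a stage
#' in isolation gives the same draws as running the full pipeline.
#'
#' @param root_seed integer root seed.
#' @param label character label naming the substream.
#' @return An integer seed in \[0, 2^31).
#' @export
derive_seed <- function(root_seed, label) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(label))
  h <- 0
  for (cc in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 131 + cc) %% 2147483647
  }
  as.integer((abs(root_seed) * 48271 + h) %% 2147483647)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# Softmax within consecutive integer groups 1..G. x numeric vector,
# group integer vector of the same length. Inputs are tanh-bounded in all
# callers, so a single global shift is enough for stability.
segment_softmax <- function(x, group) {
  a <- exp(x - max(x))
  s <- rowsum(a, group)
  as.numeric(a / s[group, 1L])
}

# Sum rows of matrix m within groups; returns G x ncol(m) matrix in group
# order 1..G (all groups assumed present).
segment_rowsum <- function(m, group) {
  rowsum(m, group, reorder = TRUE)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- lapply(params, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
  })
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L, m = zeros, v = zeros)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (k in names(params)) {
    g <- grads[[k]]
    opt$m[[k]] <- b1 * opt$m[[k]] + (1 - b1) * g
    opt$v[[k]] <- b2 * opt$v[[k]] + (1 - b2) * g * g
    params[[k]] <- params[[k]] -
      opt$lr * (opt$m[[k]] / corr1) / (sqrt(opt$v[[k]] / corr2) + opt$eps)
  }
  list(opt = opt, params = params)
}

# Flatten a named list of arrays to one numeric vector and back (used by
# the finite-difference gradient checks in the test suite).
flatten_params <- function(params) {
  unlist(lapply(params, as.numeric), use.names = FALSE)
}

unflatten_params <- function(vec, template) {
  out <- template
  i <- 1L
  for (k in names(template)) {
    n <- length(template[[k]])
    piece <- vec[i:(i + n - 1L)]
    out[[k]] <- if (is.null(dim(template[[k]]))) piece else array(piece, dim = dim(template[[k]]))
    i <- i + n
  }
  out
}
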
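#' @keywords internal
"_PACKAGE"

# Numerical helpers shared across encoders and trainers.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise softmax of a matrix, numerically stabilised.
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

clip01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Derive a stage sub-seed from a master seed
#'
#' One master seed drives the whole pipeline; each stochastic stage draws its
#' own stream from `sub_seed(seed, offset)` with a documented fixed offset, so
#' stages are reproducible independently of each other. The result always
#' stays inside R's 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer stage offset.
#' @return an integer seed.
#' @export
sub_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  as.integer((abs(seed) * 1009 + offset * 9973) %% 2147483647)
}

# Fixed stage offsets for the pipeline (documented part of the seed scheme).
STAGE_OFFSETS <- c(
  molecules = 1L, associations = 2L, kg = 3L, pairs = 4L,
  attr_pretrain = 5L, local_pretrain = 6L, kg_train = 7L,
  fusion_train = 8L, split = 9L
)

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ---- Adam optimiser over an arbitrarily nested list of numeric arrays ----

adam_init <- function(params) {
  state <- rapply(params, function(p) list(m = p * 0, v = p * 0),
                  how = "replace")
  list(s = state, t = 0L)
}

# params, grads: identically shaped nested lists. Returns list(params, opt).
adam_step <- function(params, grads, opt, lr = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  t <- opt$t
  step_one <- function(p, g, st) {
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
  }
  walk <- function(p, g, s) {
    if (is.list(p) && !is.null(names(s)) && identical(names(s), c("m", "v"))) {
      stop("internal: malformed optimiser state")
    }
    if (is.list(p)) {
      out_p <- p
      out_s <- s
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], s[[k]])
        out_p[[k]] <- r$p
        out_s[[k]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      r <- step_one(p, g, s)
      list(p = r$p, s = r$st)
    }
  }
  r <- walk(params, grads, opt$s)
  list(params = r$p, opt = list(s = r$s, t = t))
}

# Gaussian init matrix, fan-in scaled.
init_mat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / nc)
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

zeros_like <- function(params) rapply(params, function(p) p * 0, how = "replace")
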
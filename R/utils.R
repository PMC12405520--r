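#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif rbeta rexp median pnorm quantile sd var
#' @importFrom utils head read.csv
NULL

# Classed conditions: every user-facing failure mode carries a class so callers
# (and tests) can distinguish schema vs validation vs dimension errors etc.
stop_pcm <- function(message, class, ...) {
  abort(message, class = c(paste0("pcm_", class), "pcm_error"), ...)
}

warn_pcm <- function(message, class) {
  warn(message, class = c(paste0("pcm_", class), "pcm_warning"))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop_pcm(sprintf("`%s` contains non-finite values", what), "validation_error")
  }
  invisible(x)
}

# Snap a numeric matrix/vector to the nearest float32-representable values so
# that binary round trips through 4-byte storage are bit-identical.
snap_float32 <- function(x) {
  raw <- writeBin(as.numeric(x), raw(), size = 4L)
  out <- readBin(raw, "numeric", n = length(x), size = 4L)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

# d/dx silu(x) = sigmoid(x) * (1 + x * (1 - sigmoid(x)))
silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Row-wise softmax of a matrix.
softmax_rows <- function(x) {
  z <- exp(x - apply(x, 1L, max))
  z / rowSums(z)
}

# Backward through y = softmax(x) given dy (same shape, row-wise for matrices).
softmax_rows_backward <- function(p, dp) {
  p * (dp - rowSums(p * dp))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Derive a child seed from a base seed; kept below 2^31 for 32-bit R integers.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1000003 + offset) %% 2147483647)
}
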
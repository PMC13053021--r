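#' @importFrom stats plogis rnorm runif rbinom quantile sd coef glm binomial
#'   model.matrix optim setNames median
#' @importFrom utils write.csv head modifyList
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_invalid <- function(...) stop(..., call. = FALSE)

# Derive a reproducible child seed from a parent seed and a stream label.
# Kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Stable hash of a configuration list for run manifests (text-based FNV-1a).
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
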
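# Internal helpers: classed conditions and small formatting utilities.

# Signal a classed error so callers/tests can match on condition class.
abort_ncd <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ncdtrend_error", "error"),
                      call = call))
}

warn_ncd <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "ncdtrend_warning", "warning")))
}

# Format a rate or percent at 1 decimal, as in published tables.
fmt1 <- function(x) sprintf("%.1f", x)

# Signed 1-decimal percent, "+19.6" / "-32.1".
fmt_pct <- function(x) sprintf("%+.1f", x)

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds below 2^31 from one master seed.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# 32-bit FNV-1a hash of an R object's serialized bytes, as 8 hex digits.
# Used to stamp figure files with a reproducible configuration fingerprint.
config_hash <- function(object) {
  bytes <- as.integer(serialize(object, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # xor touches only the low byte
    h <- (h - low) + bitwXor(as.integer(low), b)
    # multiply by the FNV prime mod 2^32 without exceeding 2^53
    a <- h %/% 65536; c <- h %% 65536
    h <- (((a * 16777619) %% 65536) * 65536 + c * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

# Symmetric matrix square root (robust to rank deficiency / zero matrices).
mat_sqrt <- function(V) {
  if (length(V) == 1L) return(matrix(sqrt(max(V, 0)), 1L, 1L))
  e <- eigen(V, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}
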
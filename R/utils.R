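# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation calls never perturb the session stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_min && x <= min) {
    stop_domain(sprintf("`%s` must be > %s", name, format(min)))
  }
  if (!strict_min && x < min) {
    stop_domain(sprintf("`%s` must be >= %s", name, format(min)))
  }
  invisible(x)
}

# Sensor index (1..256, row-major from top-left) <-> grid coordinates.
sensor_to_rc <- function(index) {
  index <- as.integer(index)
  if (any(index < 1L | index > MAT_NSENSOR)) {
    stop_domain("sensor index must lie in 1..256")
  }
  cbind(row = (index - 1L) %/% MAT_NCOL + 1L,
        col = (index - 1L) %% MAT_NCOL + 1L)
}

rc_to_sensor <- function(row, col) {
  (as.integer(row) - 1L) * MAT_NCOL + as.integer(col)
}

# Reshape a length-256 sensor vector (row-major order) into the 16x16 grid.
sensor_vector_to_grid <- function(x) {
  matrix(x, nrow = MAT_NROW, ncol = MAT_NCOL, byrow = TRUE)
}

grid_to_sensor_vector <- function(g) {
  as.vector(t(g))
}

# FNV-1a 32-bit hash of a character scalar; used to stamp config hashes into
# artifact file headers without a digest dependency.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # multiply mod 2^32 without losing double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Simple local-maximum counter used by the simulator's own sanity checks.
count_peaks <- function(x, min_height = NULL) {
  n <- length(x)
  if (n < 3L) return(0L)
  core <- x[2:(n - 1L)]
  is_peak <- core > x[1:(n - 2L)] & core >= x[3:n]
  if (!is.null(min_height)) is_peak <- is_peak & core >= min_height
  sum(is_peak)
}
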
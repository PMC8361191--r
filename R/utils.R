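# internal helpers shared across modules

#' @noRd
stop_scfc <- function(..., class = "scfc_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# run `expr` under a temporary RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so generators are pure functions of (args, seed)
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_scfc("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# polynomial rolling hash of a serialized R object, as 8 hex digits;
# stamps pipeline outputs with the configuration that produced them.
# modulus below 2^26 keeps every product exact in double precision
#' @noRd
config_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2L)
  # skip the serialization header (encoding-dependent), hash the payload
  bytes <- as.integer(bytes[-seq_len(14L)])
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 67108859
  sprintf("%08x", h)
}

#' @noRd
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# quantile with midpoint interpolation: value at rank (n-1)*p is the mean of
# the two order statistics bracketing that position
#' @noRd
quantile_midpoint <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp
    (x[floor(h) + 1L] + x[ceiling(h) + 1L]) / 2
  }, numeric(1))
}
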
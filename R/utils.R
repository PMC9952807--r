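# Small shared helpers.

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Fold an axial angle into [0, 90] degrees
#'
#' Axial orientations are defined modulo 180 degrees; angles are reported
#' relative to the stretch axis, so 100 degrees and 80 degrees describe the
#' same inclination. This reduces any angle to the equivalent value in
#' \code{[0, 90]}.
#'
#' @param theta angle(s) in degrees.
#' @return angle(s) in \code{[0, 90]} degrees.
#' @export
fold_angle <- function(theta) {
  th <- theta %% 180
  ifelse(th > 90, 180 - th, th)
}

# FNV-1a hash of a character scalar, returned as hex string. Used for
# provenance stamps in reports; not cryptographic.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits (kept in doubles)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply by 16777619, split to stay within double
    # precision
    hi <- h %/% 65536; lo2 <- h %% 65536
    h <- (lo2 * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
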
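# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that library functions needing
#' randomness do not perturb the caller's RNG stream.
#' @noRd
with_local_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

#' Derive a stage- or sample-specific sub-seed from a global seed
#'
#' Deterministic multiplicative-congruential fan-out: a single run seed maps to
#' distinct, reproducible sub-seeds for every pipeline stage and every cohort
#' sample. All arithmetic stays below 2^53 so it is exact in doubles, and the
#' result is always a valid positive 32-bit integer seed.
#' @param seed integer global seed.
#' @param stream integer or character stream label; characters are folded to an
#'   integer via their UTF-8 codes.
#' @return a positive integer < 2^31 - 1.
#' @noRd
derive_seed <- function(seed, stream) {
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m) * 48271 %% m
  s <- (s + as.numeric(stream) * 16807) %% m
  as.integer(s %% (m - 1) + 1)
}

# round() uses banker's rounding; split sizes and bin indices need half-up.
round_half_up <- function(x) floor(x + 0.5)

#' MD5 hash of an arbitrary R object (via its serialized bytes)
#' @noRd
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
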
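# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so seeded package
#' functions never perturb the global RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Uniform random composition of `total` into `parts` non-negative integers
#'
#' Stars-and-bars: every composition is equally likely. Used for deviant
#' placement so spacing is uniform over all feasible arrangements.
#' @noRd
sample_composition <- function(total, parts) {
  stopifnot(total >= 0, parts >= 1)
  if (parts == 1L) return(as.integer(total))
  if (total == 0L) return(integer(parts))
  cuts <- sort(sample.int(total + parts - 1L, parts - 1L))
  as.integer(diff(c(0L, cuts, total + parts)) - 1L)
}

# FNV-1a 32-bit hash of a character scalar; stable fingerprint for
# configuration metadata written into output file headers. Arithmetic is
# done in doubles with an explicit 2^32 split so no step exceeds 2^53.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

sigmoid <- function(x) stats::plogis(x)

stop_oddballr <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "oddballr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
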
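#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive reproducible child seeds from one master seed
#'
#' All stochastic stages of the pipeline draw their seeds from a single master
#' seed through this function, so that one integer pins down the schedule, the
#' noise streams, per-trial jitter, trial selection and cross-validation
#' splits independently of the order in which stages run.
#'
#' @param master integer master seed.
#' @param n number of child seeds to derive.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# ms -> 0-based sample offset at a given rate, half-open convention
ms_to_samples <- function(ms, fs) as.integer(round(ms / 1000 * fs))

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

# FNV-1a 64-bit-ish hash over serialized R objects, for artifact manifests.
# Implemented on 32-bit words to stay inside R's integer arithmetic.
object_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
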
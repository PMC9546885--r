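#' @importFrom rlang abort warn %||%
#' @importFrom stats var sd cor rnorm runif fft pchisq qr.Q
NULL

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# funnel through this so that a single integer seed pins down every output.
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

# Derive a child seed from a master seed; keeps results < 2^31 and spreads
# consecutive indices apart so per-subject streams do not overlap trivially.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483587L) + 1L
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    abort(sprintf("`%s` = %g is outside the allowed range [%g, %g].",
                  name, x, lower, upper))
  }
  invisible(x)
}

#' Hash of a configuration object
#'
#' Stable content hash used to stamp every pipeline output so that results
#' can be matched to the exact configuration that produced them.
#'
#' @param x Any R object (typically a run configuration list).
#' @return A character scalar.
#' @export
config_hash <- function(x) rlang::hash(x)
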
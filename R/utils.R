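#' @keywords internal
"_PACKAGE"

# Effect classes used throughout the dependency machinery.  Order matters only
# for display; classification assigns exactly one label per ordered node pair.
EFFECT_CLASSES <- c("NO_EFFECT", "AMBIVALENT",
                    "WEAK_ACTIVATOR", "WEAK_INHIBITOR",
                    "STRONG_ACTIVATOR", "STRONG_INHIBITOR")

NODE_ROLES <- c("input", "internal", "output")

`%||%` <- function(a, b) if (is.null(a)) b else a

# set.seed() only when the caller supplied one, leaving the global RNG
# untouched otherwise so library code stays composable.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("'seed' must be a single integer", call. = FALSE)
    set.seed(as.integer(seed))
  }
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
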
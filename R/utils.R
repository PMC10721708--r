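# Shared internal helpers: seeded evaluation, validation, tree-structured
# parameter arithmetic used by the optimizer.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Derive a child seed from a base seed and an index, staying inside the
# 32-bit integer range.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7907 * as.numeric(index)) %% 2147483647L)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (strict_min) {
    if (x <= min) stop(sprintf("'%s' must be > %s", name, min), call. = FALSE)
  } else if (x < min) {
    stop(sprintf("'%s' must be >= %s", name, min), call. = FALSE)
  }
  invisible(x)
}

# Apply `f(a, b)` elementwise over two identically shaped nested lists of
# numeric arrays (parameter trees and their gradients).
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (is.null(a[[nm]])) next
      out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
    }
    return(out)
  }
  f(a, b)
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (is.null(a[[nm]])) next
      out[[nm]] <- tree_map(a[[nm]], f)
    }
    return(out)
  }
  f(a)
}

# Sum of f over all leaves (numeric arrays) of a nested list.
tree_reduce_sum <- function(a, f) {
  if (is.list(a)) {
    return(sum(vapply(a, function(el) {
      if (is.null(el)) 0 else tree_reduce_sum(el, f)
    }, numeric(1))))
  }
  f(a)
}
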
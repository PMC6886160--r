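# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Numerically stable row-wise softmax of a matrix.
row_softmax <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# uniform(+-scale) initial values, drawn from the current RNG stream
runif_mat <- function(nr, nc, scale) {
  matrix(stats::runif(nr * nc, -scale, scale), nrow = nr, ncol = nc)
}

# Recursively keep only numeric (double) leaves and drop attributes, so a
# parameter tree can be flattened, perturbed and updated uniformly.
strip_to_numeric <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    keep <- vapply(x, function(e) is.list(e) || is.double(e), logical(1))
    lapply(x[keep], strip_to_numeric)
  } else {
    x
  }
}

# elementwise map over two parallel nested lists of numeric arrays
map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map2_params(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

# elementwise map over one nested list of numeric arrays
map_params <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map_params(a[[i]], f)
    out
  } else {
    f(a)
  }
}

# flatten a nested parameter list into one numeric vector (for gradient checks)
flatten_params <- function(a) {
  if (is.list(a)) {
    unlist(lapply(a, flatten_params), use.names = FALSE)
  } else {
    as.numeric(a)
  }
}

# write `values` (numeric vector) back into the shapes of nested list `a`
unflatten_params <- function(a, values) {
  pos <- 0L
  rebuild <- function(x) {
    if (is.list(x)) {
      for (i in seq_along(x)) x[[i]] <- rebuild(x[[i]])
      x
    } else {
      n <- length(x)
      v <- values[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (is.null(dim(x))) v else array(v, dim = dim(x))
    }
  }
  out <- rebuild(a)
  stopifnot(pos == length(values))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
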
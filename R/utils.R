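#' @importFrom stats plogis rnorm runif rbinom setNames
#' @importFrom utils head
NULL

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package operations never perturb user scripts.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Leaky rectified linear unit
#'
#' @param x numeric vector or matrix.
#' @param slope negative-side slope (default 0.2).
#' @return elementwise `max(x, 0) + slope * min(x, 0)`.
#' @export
leaky_relu <- function(x, slope = 0.2) {
  pmax(x, 0) + slope * pmin(x, 0)
}

# derivative of leaky_relu at the pre-activation (subgradient 1 at 0)
leaky_relu_grad <- function(x, slope = 0.2) {
  slope + (1 - slope) * (x >= 0)
}

sigmoid <- function(x) plogis(x)

# numerically safe log(1 + exp(x))
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# map f over the leaves (numeric arrays) of a nested list
tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) tree_map(f, x)))
  f(a)
}

# map f over matched leaves of two nested lists with identical structure
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    return(out)
  }
  f(a, b)
}

# sum of squares over every leaf of a nested list
tree_sumsq <- function(a) {
  if (is.list(a)) return(sum(vapply(a, tree_sumsq, numeric(1))))
  sum(a * a)
}

grn_log <- function(..., verbose = getOption("grnlink.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
}
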
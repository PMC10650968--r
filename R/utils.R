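`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
  invisible()
}

#' @noRd
as_binary_mask <- function(x, arg = "mask") {
  if (is.logical(x)) {
    m <- x
  } else {
    abort_if(!is.numeric(x), paste0(arg, " must be a logical or 0/1 matrix"))
    vals <- unique(as.vector(x))
    abort_if(!all(vals %in% c(0, 1)), paste0(arg, " must be strictly binary"))
    m <- x > 0
  }
  abort_if(!is.matrix(m), paste0(arg, " must be a matrix"))
  m
}

check_same_shape <- function(...) {
  ms <- list(...)
  dims <- vapply(ms, function(m) paste(dim(m), collapse = "x"), character(1))
  abort_if(length(unique(dims)) != 1L, "masks/images must share one shape")
  invisible()
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
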
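#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Residualise columns of `m` (or a vector) on covariate matrix `C` (with
# intercept added); returns object of the same shape.
residualise <- function(m, C = NULL) {
  v <- is.null(dim(m))
  x <- if (v) matrix(m, ncol = 1L) else m
  C <- if (is.null(C) || ncol(as.matrix(C)) == 0L) {
    matrix(1, nrow(x), 1L)
  } else {
    cbind(1, as.matrix(C))
  }
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("covariate matrix is rank deficient", call. = FALSE)
  r <- x - C %*% qr.coef(qrC, x)
  if (v) drop(r) else r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
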
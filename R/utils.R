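# Internal numerical helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the caller's
#' `.Random.seed` afterwards so package functions never perturb user RNG
#' state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit({
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Pad a matrix by half-sample symmetric reflection (edge row/column
# duplicated), h rows/cols on each side.  h may exceed the image size; the
# reflection is applied repeatedly in that case.
padMirror <- function(x, h) {
  if (h == 0L) return(x)
  reflectIdx <- function(n, h) {
    # indices for c(reflected head, 1:n, reflected tail), period 2n
    idx <- seq.int(1L - h, n + h)
    m <- ((idx - 1L) %% (2L * n))
    m <- ifelse(m >= n, 2L * n - 1L - m, m)
    m + 1L
  }
  ri <- reflectIdx(nrow(x), h)
  ci <- reflectIdx(ncol(x), h)
  x[ri, ci, drop = FALSE]
}

# FFT cross-correlation of an image with a (2h+1)x(2h+1) kernel under
# mirror-reflected boundary handling:
#   out[i, j] = sum_{a,b in -h..h} kernel[a+h+1, b+h+1] * xpad[i+a, j+b].
# All kernels used in this package are centrally symmetric, so this equals
# plain convolution for them.
convolveMirror <- function(x, kernel) {
  kh <- dim(kernel)
  stopifnot(kh[1] == kh[2], kh[1] %% 2L == 1L)
  h <- (kh[1] - 1L) %/% 2L
  xp <- padMirror(x, h)
  P <- dim(xp)
  # embed the flipped kernel with its centre wrapped to (1,1): correlation
  # via product of forward transforms
  kw <- matrix(0, P[1], P[2])
  ii <- ((seq_len(kh[1]) - h - 1L) %% P[1]) + 1L
  jj <- ((seq_len(kh[2]) - h - 1L) %% P[2]) + 1L
  kw[ii, jj] <- kernel
  out <- Re(stats::fft(stats::fft(xp) * Conj(stats::fft(kw)), inverse = TRUE)) /
    prod(P)
  out[(h + 1L):(h + nrow(x)), (h + 1L):(h + ncol(x)), drop = FALSE]
}

# Sampled isotropic Gaussian kernel, unit sum, support half-width ceil(3*sigma).
gaussianKernel <- function(sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Gaussian blur with mirror boundary; sigma = 0 is the identity.
gaussianBlur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  convolveMirror(x, gaussianKernel(sigma))
}

# Forward-difference gradients with replicated (Neumann) boundary:
# zero gradient across the last column (x) / last row (y).
# x = column index increasing rightwards, y = row index increasing downwards.
forwardDiffX <- function(b) {
  g <- matrix(0, nrow(b), ncol(b))
  if (ncol(b) > 1L)
    g[, -ncol(b)] <- b[, -1L, drop = FALSE] - b[, -ncol(b), drop = FALSE]
  g
}

forwardDiffY <- function(b) {
  g <- matrix(0, nrow(b), ncol(b))
  if (nrow(b) > 1L)
    g[-nrow(b), ] <- b[-1L, , drop = FALSE] - b[-nrow(b), , drop = FALSE]
  g
}

# Centred-difference gradients (replicated boundary), used for the
# structure-tensor direction field where an unbiased stencil matters.
centralDiffX <- function(b) {
  n <- ncol(b)
  left <- b[, c(1L, seq_len(n - 1L)), drop = FALSE]
  right <- b[, c(seq_len(n)[-1L], n), drop = FALSE]
  (right - left) / 2
}

centralDiffY <- function(b) {
  n <- nrow(b)
  up <- b[c(1L, seq_len(n - 1L)), , drop = FALSE]
  down <- b[c(seq_len(n)[-1L], n), , drop = FALSE]
  (down - up) / 2
}

assertMatrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

assertSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}
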
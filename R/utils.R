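`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package operations
#' do not disturb the caller's random stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# DFT sample frequencies in cycles per unit, matching fft() bin order.
fftfreq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

# Whole-sample symmetric extension along both dimensions: [x; rev(x)].
# The doubled signal is invariant under the circular reflection that any
# real, even Fourier filter commutes with, so filter -> crop -> re-extend
# is lossless. This is what makes propagation and phase retrieval an exact
# inverse pair.
sym_pad2 <- function(m) {
  m2 <- rbind(m, m[rev(seq_len(nrow(m))), , drop = FALSE])
  cbind(m2, m2[, rev(seq_len(ncol(m2))), drop = FALSE])
}

sym_crop2 <- function(m, nr, nc) m[seq_len(nr), seq_len(nc), drop = FALSE]

next_pow2 <- function(n) 2^ceiling(log2(n))

as_dim3 <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop("expected a 3D array")
  d
}
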
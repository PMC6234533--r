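# Natural cubic spline with precomputed second derivatives. Used for the
# knee prescribed-motion knot table so the R and compiled evaluators share
# one set of coefficients.

nat_spline_prep <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n, !is.unsorted(x, strictly = TRUE))
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1
  A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  list(x = x, y = y, ypp = as.vector(solve(A, b)))
}

nat_spline_eval <- function(sp, xout) {
  x <- sp$x; y <- sp$y; ypp <- sp$ypp
  if (any(xout < x[1] - 1e-9) || any(xout > x[length(x)] + 1e-9))
    stop(sprintf("value outside knot range [%g, %g]: extrapolation not allowed",
                 x[1], x[length(x)]))
  xout <- pmin(pmax(xout, x[1]), x[length(x)])
  i <- findInterval(xout, x, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(x) - 1L)
  h <- x[i + 1] - x[i]
  A <- (x[i + 1] - xout) / h
  B <- 1 - A
  A * y[i] + B * y[i + 1] + ((A^3 - A) * ypp[i] + (B^3 - B) * ypp[i + 1]) * h^2 / 6
}
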
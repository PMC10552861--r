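# Algebraic circle fitting (Pratt).

#' Fit a circle to points by the Pratt algebraic method
#'
#' Minimises the algebraic distance `A(x^2 + y^2) + Bx + Cy + D` under
#' Pratt's normalisation `B^2 + C^2 - 4AD = 1`, solved as a generalized
#' eigenproblem on the moment matrix. The method is stable for partial
#' arcs and needs no iteration or initial guess. Data are centred and
#' scaled before fitting for conditioning.
#'
#' @param x,y Point coordinates (at least 3 points).
#' @return A list with `cx`, `cy` (centre), `r` (radius) and
#'   `rms` (root-mean-square orthogonal residual).
#' @examples
#' a <- seq(0, pi, length.out = 7)
#' fit_circle_pratt(2 + 5 * cos(a), -1 + 5 * sin(a)) # centre (2,-1), r = 5
#' @export
fit_circle_pratt <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("circle fitting needs at least 3 points", call. = FALSE)

  mx <- mean(x)
  my <- mean(y)
  xs <- x - mx
  ys <- y - my
  s <- sqrt(mean(xs^2 + ys^2))
  if (s == 0) stop("degenerate-fit: all points coincide", call. = FALSE)
  xs <- xs / s
  ys <- ys / s

  z <- xs^2 + ys^2
  A <- cbind(z, xs, ys, 1)
  M <- crossprod(A) / n
  # Pratt constraint matrix for B^2 + C^2 - 4AD = 1
  Cmat <- matrix(c(
    0, 0, 0, -2,
    0, 1, 0, 0,
    0, 0, 1, 0,
    -2, 0, 0, 0
  ), 4, 4, byrow = TRUE)
  E <- eigen(solve(Cmat, M))
  ev <- E$values
  ok <- abs(Im(ev)) < 1e-8
  evr <- Re(ev)
  # smallest eigenvalue that is not materially negative (exact fits sit
  # at ~0, possibly a hair below through rounding)
  cand <- which(ok & evr > -1e-8)
  if (length(cand) == 0) stop("degenerate-fit: no admissible circle solution",
                              call. = FALSE)
  i <- cand[which.min(evr[cand])]
  p <- Re(E$vectors[, i])
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]
  if (abs(a) < 1e-12 * sqrt(b^2 + cc^2)) {
    stop("degenerate-fit: points are collinear", call. = FALSE)
  }
  cx <- -b / (2 * a)
  cy <- -cc / (2 * a)
  disc <- b^2 + cc^2 - 4 * a * d
  if (disc <= 0) stop("degenerate-fit: imaginary radius", call. = FALSE)
  r <- sqrt(disc) / (2 * abs(a))

  # undo normalisation
  cx <- cx * s + mx
  cy <- cy * s + my
  r <- r * s
  res <- sqrt((x - cx)^2 + (y - cy)^2) - r
  list(cx = cx, cy = cy, r = r, rms = sqrt(mean(res^2)))
}
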
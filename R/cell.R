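#' Unit cell
#'
#' Construct a crystallographic unit cell from edge lengths (Angstrom) and
#' angles (degrees). The reciprocal metric tensor is precomputed and used for
#' all resolution calculations.
#'
#' @param a,b,c Cell edges in Angstrom, all positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' cl <- unit_cell(103.7, 110.9, 110.4)
#' d_spacing(cl, c(1, 0, 0))
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  edges <- c(a = a, b = b, c = c)
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(edges)) || any(edges <= 0))
    stop("cell edges must be positive and finite")
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(angs * pi / 180)
  # direct metric tensor G
  G <- matrix(c(
    a * a,           a * b * ca[3],  a * c * ca[2],
    a * b * ca[3],   b * b,          b * c * ca[1],
    a * c * ca[2],   b * c * ca[1],  c * c
  ), 3, 3, byrow = TRUE)
  det_g <- det(G)
  if (det_g <= 0) stop("degenerate unit cell: metric tensor not positive-definite")
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         metric = G, recip_metric = solve(G), volume = sqrt(det_g)),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

is_unit_cell <- function(x) inherits(x, "unit_cell")

#' Resolution of a reflection
#'
#' d-spacing of Miller indices under a unit cell, via the reciprocal metric
#' tensor: 1/d^2 = h' G* h. Vectorised over rows of an n x 3 index matrix.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer triple, or an n x 3 matrix of triples.
#' @return Numeric vector of d in Angstrom.
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(is_unit_cell(cell))
  H <- as_hkl_matrix(hkl)
  if (any(rowSums(H != 0) == 0)) stop("hkl (0,0,0) has no resolution")
  inv_d2 <- rowSums((H %*% cell$recip_metric) * H)
  1 / sqrt(inv_d2)
}

# s = sin(theta)/lambda = 1/(2d); B factors act as exp(-2 B s^2) on intensity
s_squared <- function(cell, hkl) 1 / (4 * d_spacing(cell, hkl)^2)

as_hkl_matrix <- function(hkl) {
  if (is.matrix(hkl)) {
    if (ncol(hkl) != 3) stop("hkl matrix must have 3 columns")
    storage.mode(hkl) <- "double"
    return(hkl)
  }
  if (length(hkl) != 3) stop("hkl must be a triple or an n x 3 matrix")
  matrix(as.numeric(hkl), 1, 3)
}
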
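#' A single crystal's unmerged reflection dataset
#'
#' One microcrystal's integrated partial dataset: unmerged observations
#' (Miller indices, intensity, sigma) plus cell, point-group symmetry and
#' wedge metadata. Intensities may be non-positive (weak reflections); sigmas
#' must be positive.
#'
#' @param id Dataset identifier (text).
#' @param cell A [unit_cell()].
#' @param ops A [point_group()].
#' @param obs data.frame with columns `h, k, l, i, sigi`.
#' @param wedge_deg Rotation range covered by this crystal, degrees in
#'   \[0, 360\].
#' @param truth_label Optional "isomorphous" or "contaminant"; set only by the
#'   simulator.
#' @return Object of class `xtal_dataset`.
#' @export
xtal_dataset <- function(id, cell, ops, obs, wedge_deg = NA_real_,
                         truth_label = NULL) {
  stopifnot(is_unit_cell(cell), is_point_group(ops), is.data.frame(obs))
  need <- c("h", "k", "l", "i", "sigi")
  if (!all(need %in% names(obs))) stop("obs needs columns h,k,l,i,sigi")
  obs <- obs[need]
  obs$h <- as.integer(obs$h); obs$k <- as.integer(obs$k); obs$l <- as.integer(obs$l)
  if (nrow(obs) == 0) stop("dataset '", id, "' has no observations")
  if (any(obs$h == 0 & obs$k == 0 & obs$l == 0)) stop("observation with hkl (0,0,0)")
  if (any(!is.finite(obs$sigi)) || any(obs$sigi <= 0))
    stop("all sigmas must be positive and finite")
  if (!is.na(wedge_deg) && (wedge_deg < 0 || wedge_deg > 360))
    stop("wedge_deg must be in [0, 360]")
  if (!is.null(truth_label))
    truth_label <- match.arg(truth_label, c("isomorphous", "contaminant"))
  structure(list(id = as.character(id), cell = cell, ops = ops, obs = obs,
                 wedge_deg = wedge_deg, truth_label = truth_label),
            class = "xtal_dataset")
}

is_xtal_dataset <- function(x) inherits(x, "xtal_dataset")

#' @export
print.xtal_dataset <- function(x, ...) {
  d <- d_spacing(x$cell, as.matrix(x$obs[c("h", "k", "l")]))
  cat(sprintf("Dataset '%s': %d observations, %.2f-%.2f A, point group %s%s\n",
              x$id, nrow(x$obs), max(d), min(d), x$ops$name,
              if (!is.null(x$truth_label)) paste0(" [", x$truth_label, "]") else ""))
  invisible(x)
}

# resolution of every observation
dataset_d <- function(ds) d_spacing(ds$cell, as.matrix(ds$obs[c("h", "k", "l")]))

# cells equal within tol (fractional, per edge/angle)
cells_compatible <- function(a, b, tol = 0.01) {
  ea <- c(a$a, a$b, a$c); eb <- c(b$a, b$b, b$c)
  aa <- c(a$alpha, a$beta, a$gamma); ab <- c(b$alpha, b$beta, b$gamma)
  all(abs(ea - eb) / ea <= tol) && all(abs(aa - ab) / aa <= tol)
}
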
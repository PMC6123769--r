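#' Resolution shells
#'
#' Partition a resolution range (d_max, d_min] into shells, numbered from low
#' resolution (shell 1, largest d) to high. `equal_volume` places edges
#' uniformly in 1/d^3, so each shell spans an equal reciprocal-space volume;
#' `equal_count` places edges at quantiles of an observed d distribution so
#' shell occupancies differ by at most one.
#'
#' @param d_max,d_min Low- and high-resolution limits in Angstrom
#'   (`d_max > d_min > 0`).
#' @param n_shells Number of shells (>= 1).
#' @param scheme "equal_volume" or "equal_count".
#' @param d_obs Observed d values; required for `equal_count`.
#' @return An object of class `shell_scheme` with `edges` (strictly decreasing
#'   d values of length `n_shells + 1`), `n_shells` and `scheme`.
#' @examples
#' sh <- make_shells(10, 2, n_shells = 5)
#' sh$edges
#' @export
make_shells <- function(d_max, d_min, n_shells = 10,
                        scheme = c("equal_volume", "equal_count"),
                        d_obs = NULL) {
  scheme <- match.arg(scheme)
  if (!(d_max > d_min && d_min > 0)) stop("need d_max > d_min > 0")
  n_shells <- as.integer(n_shells)
  if (n_shells < 1) stop("n_shells must be >= 1")
  if (scheme == "equal_volume") {
    v <- seq(1 / d_max^3, 1 / d_min^3, length.out = n_shells + 1)
    edges <- v^(-1 / 3)
  } else {
    if (is.null(d_obs)) stop("equal_count scheme needs d_obs")
    d_obs <- d_obs[d_obs <= d_max & d_obs >= d_min]
    if (length(d_obs) < n_shells) stop("too few observations for equal_count shells")
    qs <- stats::quantile(d_obs, probs = seq(1, 0, length.out = n_shells + 1),
                          type = 1, names = FALSE)
    edges <- c(d_max, qs[-c(1, n_shells + 1)], d_min)
    if (any(diff(edges) >= 0)) stop("degenerate equal_count edges (ties in d)")
  }
  edges[1] <- d_max
  edges[n_shells + 1] <- d_min
  structure(list(n_shells = n_shells, edges = edges, scheme = scheme),
            class = "shell_scheme")
}

#' @export
print.shell_scheme <- function(x, ...) {
  cat(sprintf("%d %s resolution shells: %.2f - %.2f A\n",
              x$n_shells, x$scheme, x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}

is_shell_scheme <- function(x) inherits(x, "shell_scheme")

#' Assign reflections to shells
#'
#' @param shells A [make_shells()] scheme.
#' @param d Numeric vector of resolutions in Angstrom.
#' @return Integer shell indices in `1..n_shells`; values outside the range
#'   are clamped into the first/last shell.
#' @export
shell_index <- function(shells, d) {
  stopifnot(is_shell_scheme(shells))
  v <- 1 / d^3
  vedges <- 1 / shells$edges^3  # increasing
  idx <- findInterval(v, vedges, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(idx)
}

shell_labels <- function(shells) {
  e <- shells$edges
  sprintf("%.3f-%.3f", e[-length(e)], e[-1])
}
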
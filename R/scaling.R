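#' Per-dataset scale model
#'
#' Linear scale `k` and relative B factor `B` (Angstrom^2) relating one
#' dataset's intensities to the reference frame:
#' `I_dataset(h) ~ k * exp(-2 B s^2) * I_ref(h)` with `s = 1/(2d)`. Merging
#' divides observations by `k * exp(-2 B s^2)`.
#'
#' @param k Positive linear scale. @param B Relative B factor, Angstrom^2.
#' @return Object of class `scale_model`.
#' @export
scale_model <- function(k = 1, B = 0) {
  k <- unname(k); B <- unname(B)
  if (!is.finite(k) || k <= 0) stop("scale k must be positive")
  if (!is.finite(B)) stop("B must be finite")
  structure(list(k = k, B = B), class = "scale_model")
}

#' @export
print.scale_model <- function(x, ...) {
  cat(sprintf("Scale model: k = %.4g, B = %.3g A^2\n", x$k, x$B))
  invisible(x)
}

#' Fit a dataset's scale against a merged reference
#'
#' Least squares of `ln(I_d / I_ref) = ln k - 2 B s^2` over reflections strong
#' in both (I > 3 sigma), after merging the dataset's own observations per
#' unique key. With fewer than 10 strong common pairs B is fixed at 0 and
#' `k = sum(I_ref * I_d) / sum(I_ref^2)`.
#'
#' @param dataset An [xtal_dataset()].
#' @param reference A [merged_set()].
#' @return A [scale_model()].
#' @export
fit_scale <- function(dataset, reference) {
  stopifnot(is_xtal_dataset(dataset), is_merged_set(reference))
  own <- merge_datasets(list(dataset), anomalous = reference$anomalous)
  a <- own$entries; b <- reference$entries
  m <- match(encode_key(a), encode_key(b))
  ok <- !is.na(m)
  if (!any(ok)) stop("no reflections in common with reference: dataset '",
                     dataset$id, "'")
  a <- a[ok, ]; b <- b[m[ok], ]
  strong <- a$i > 3 * a$sigma & b$i > 3 * b$sigma
  if (sum(strong) < 3) stop("fewer than 3 strong common reflections: dataset '",
                            dataset$id, "'")
  Id <- a$i[strong]; Ir <- b$i[strong]
  if (sum(strong) < 10) {
    k <- sum(Ir * Id) / sum(Ir^2)
    if (!is.finite(k) || k <= 0) stop("scale fit failed: dataset '", dataset$id, "'")
    return(scale_model(k, 0))
  }
  s2 <- s_squared(dataset$cell, as.matrix(a[strong, c("h", "k", "l")]))
  fit <- stats::lm.fit(cbind(1, -2 * s2), log(Id / Ir))
  k <- exp(fit$coefficients[1]); B <- fit$coefficients[2]
  if (!is.finite(k) || k <= 0 || !is.finite(B))
    stop("scale fit failed: dataset '", dataset$id, "'")
  scale_model(k, B)
}

#' Sequentially scale and merge an ensemble
#'
#' The first dataset seeds the reference frame with unit scale; each
#' subsequent dataset is scaled against the running merged reference and
#' folded in. Unscalable datasets (no common reflections / degenerate fit) are
#' dropped and reported.
#'
#' @param datasets List of [xtal_dataset()], in merge order (e.g. presorted by
#'   low-resolution R_meas).
#' @param anomalous Friedel-separated merge?
#' @return List with `merged` ([merged_set()]), `scales` (named by dataset id;
#'   `NULL` for unscalable ones) and `unscalable` (character ids).
#' @export
scale_and_merge <- function(datasets, anomalous = FALSE) {
  stopifnot(length(datasets) >= 1)
  ids <- vapply(datasets, function(d) d$id, "")
  cell <- datasets[[1]]$cell; ops <- datasets[[1]]$ops
  scales <- stats::setNames(vector("list", length(datasets)), ids)
  scales[[1]] <- scale_model(1, 0)
  sums <- merge_sums(pool_observations(datasets[1], scales[1], anomalous))
  as_ref <- function(s) new_merged_set(sums_to_entries(s, cell), cell, ops, anomalous)
  for (j in seq_along(datasets)[-1]) {
    sc <- tryCatch(fit_scale(datasets[[j]], as_ref(sums)), error = function(e) NULL)
    scales[j] <- list(sc)   # keep NULL placeholders for unscalable datasets
    if (is.null(sc)) next
    add <- merge_sums(pool_observations(datasets[j], scales[j], anomalous))
    sums <- combine_sums(sums, add)
  }
  unscalable <- ids[vapply(scales, is.null, TRUE)]
  list(merged = as_ref(sums), scales = scales, unscalable = unscalable)
}

combine_sums <- function(a, b) {
  m <- match(b$key, a$key)
  hit <- !is.na(m)
  if (any(hit)) {
    idx <- m[hit]
    a$sw[idx] <- a$sw[idx] + b$sw[hit]
    a$swi[idx] <- a$swi[idx] + b$swi[hit]
    a$n[idx] <- a$n[idx] + b$n[hit]
  }
  out <- rbind(a, b[!hit, , drop = FALSE])
  out[order(out$key), , drop = FALSE]
}
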
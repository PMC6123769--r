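# ---- unique-key encoding -----------------------------------------------
# one exact double per (asu hkl, friedel sign); friedel "-" flips the low bit
encode_key <- function(asu) {
  code <- encode_hkl(as.matrix(asu[c("h", "k", "l")]))
  code * 2 + (asu$friedel == "-")
}
decode_key <- function(key) {
  minus <- key %% 2 == 1
  H <- decode_hkl((key - (key %% 2)) / 2)
  data.frame(h = H[, 1], k = H[, 2], l = H[, 3],
             friedel = ifelse(minus, "-", "+"), stringsAsFactors = FALSE)
}

#' Merged unique-reflection set
#'
#' Container for inverse-variance merged intensities: one row per unique key
#' (canonical ASU triple plus Friedel sign when `anomalous`), with merged
#' intensity `i`, propagated `sigma` and multiplicity `n_obs`.
#'
#' @param entries data.frame with columns `h, k, l, friedel, i, sigma, n_obs`.
#' @param cell A [unit_cell()]. @param ops A [point_group()].
#' @param anomalous Friedel-separated?
#' @return Object of class `merged_set`.
#' @export
merged_set <- function(entries, cell, ops, anomalous) {
  new_merged_set(entries, cell, ops, anomalous)
}

new_merged_set <- function(entries, cell, ops, anomalous) {
  stopifnot(is.data.frame(entries), is_unit_cell(cell), is_point_group(ops))
  need <- c("h", "k", "l", "friedel", "i", "sigma", "n_obs")
  if (!all(need %in% names(entries))) stop("entries needs columns ", paste(need, collapse = ","))
  if (any(entries$sigma <= 0)) stop("merged sigma must be positive")
  if (any(entries$n_obs < 1)) stop("n_obs must be >= 1")
  structure(list(entries = entries[need], cell = cell, ops = ops,
                 anomalous = isTRUE(anomalous)),
            class = "merged_set")
}

is_merged_set <- function(x) inherits(x, "merged_set")

#' @export
print.merged_set <- function(x, ...) {
  e <- x$entries
  d <- d_spacing(x$cell, as.matrix(e[c("h", "k", "l")]))
  cat(sprintf("Merged set: %d unique reflections (%s), %.2f-%.2f A, mean multiplicity %.1f\n",
              nrow(e), if (x$anomalous) "Friedel-separated" else "Friedel-merged",
              max(d), min(d), mean(e$n_obs)))
  invisible(x)
}

merged_d <- function(ms) d_spacing(ms$cell, as.matrix(ms$entries[c("h", "k", "l")]))

# ---- scaled-observation pool -------------------------------------------
# One long table of all observations, rescaled to the reference frame
# (I / (k exp(-2 B s^2))), with unique keys and resolutions attached.
pool_observations <- function(datasets, scales, anomalous) {
  stopifnot(length(datasets) == length(scales))
  cell <- datasets[[1]]$cell
  for (j in seq_along(datasets)) {
    if (!cells_compatible(cell, datasets[[j]]$cell))
      stop("incompatible cells: dataset '", datasets[[j]]$id, "'")
  }
  parts <- vector("list", length(datasets))
  for (j in seq_along(datasets)) {
    ds <- datasets[[j]]; sc <- scales[[j]]
    H <- as.matrix(ds$obs[c("h", "k", "l")])
    s2 <- s_squared(ds$cell, H)
    g <- sc$k * exp(-2 * sc$B * s2)
    asu <- map_to_asu(H, ds$ops, anomalous = anomalous)
    parts[[j]] <- data.frame(
      ds = j, key = encode_key(asu),
      i = ds$obs$i / g, sigi = ds$obs$sigi / g,
      d = 1 / (2 * sqrt(s2)), stringsAsFactors = FALSE)
  }
  do.call(rbind, parts)
}

# per-key accumulators of the inverse-variance merge
merge_sums <- function(pool) {
  w <- 1 / pool$sigi^2
  grp <- factor(pool$key)
  out <- data.frame(
    key = as.numeric(levels(grp)),
    sw = as.vector(rowsum(w, grp)),
    swi = as.vector(rowsum(w * pool$i, grp)),
    n = as.vector(rowsum(rep(1, length(w)), grp)))
  out
}

sums_to_entries <- function(sums, cell) {
  asu <- decode_key(sums$key)
  data.frame(asu, i = sums$swi / sums$sw, sigma = 1 / sqrt(sums$sw),
             n_obs = as.integer(sums$n), stringsAsFactors = FALSE)
}

#' Merge scaled datasets into unique reflections
#'
#' Rescales every observation by its dataset's [scale_model()], groups by
#' unique key and combines by the inverse-variance weighted mean
#' (`sigma = (sum 1/sigma_i^2)^(-1/2)`).
#'
#' @param datasets List of [xtal_dataset()] with compatible cells (within 1%
#'   per edge).
#' @param scales List of [scale_model()], one per dataset; `NULL` means unit
#'   scales.
#' @param anomalous Keep Friedel mates separate?
#' @return A [merged_set()].
#' @export
merge_datasets <- function(datasets, scales = NULL, anomalous = FALSE) {
  if (is.null(scales)) scales <- rep(list(scale_model(1, 0)), length(datasets))
  pool <- pool_observations(datasets, scales, anomalous)
  entries <- sums_to_entries(merge_sums(pool), datasets[[1]]$cell)
  if (!anomalous) entries$friedel <- rep("merged", nrow(entries))
  new_merged_set(entries, datasets[[1]]$cell, datasets[[1]]$ops, anomalous)
}
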
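# run code under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Theoretical unique-reflection count
#'
#' Enumerates every integer Miller triple in the resolution sphere, maps to
#' the asymmetric unit and counts distinct keys — exact, no formula
#' approximation. With `anomalous = TRUE` acentric Friedel mates count as two
#' keys.
#'
#' @param cell A [unit_cell()]. @param ops A [point_group()].
#' @param d_max,d_min Resolution range in Angstrom.
#' @param anomalous Count Friedel mates separately?
#' @return data.frame of unique keys with columns `h, k, l, friedel, d`.
#' @export
unique_reflections <- function(cell, ops, d_max, d_min, anomalous = FALSE) {
  stopifnot(d_max > d_min, d_min > 0)
  hm <- ceiling(cell$a / d_min); km <- ceiling(cell$b / d_min)
  lm <- ceiling(cell$c / d_min)
  grid <- expand.grid(h = -hm:hm, k = -km:km, l = -lm:lm)
  grid <- grid[!(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  H <- as.matrix(grid)
  inv_d2 <- rowSums((H %*% cell$recip_metric) * H)
  d <- 1 / sqrt(inv_d2)
  keep <- d >= d_min * (1 - 1e-9) & d <= d_max * (1 + 1e-9)
  asu <- map_to_asu(H[keep, , drop = FALSE], ops, anomalous = anomalous)
  key <- encode_key(asu)
  first <- !duplicated(key)
  out <- asu[first, , drop = FALSE]
  out$d <- d[keep][first]
  rownames(out) <- NULL
  out
}

# internal: per-shell core statistics from a pooled observation table
# pool: columns key, i, sigi, d (reference scale)
shell_stats_core <- function(pool, shells, cell, ops, anomalous,
                             seed = 0, completeness = TRUE) {
  vmin <- 1 / shells$edges[1]^3; vmax <- 1 / shells$edges[length(shells$edges)]^3
  v <- 1 / pool$d^3
  inr <- v >= vmin * (1 - 1e-9) & v <= vmax * (1 + 1e-9)
  pool <- pool[inr, , drop = FALSE]
  if (nrow(pool) == 0) stop("no observations inside the shell range")
  grp <- factor(pool$key)
  n_h <- as.vector(rowsum(rep(1, nrow(pool)), grp))
  sum_i <- as.vector(rowsum(pool$i, grp))
  mean_i <- sum_i / n_h
  absdev <- as.vector(rowsum(abs(pool$i - mean_i[grp]), grp))
  w <- 1 / pool$sigi^2
  sw <- as.vector(rowsum(w, grp)); swi <- as.vector(rowsum(w * pool$i, grp))
  key_num <- as.numeric(levels(grp))
  kd <- d_spacing(cell, as.matrix(decode_key(key_num)[c("h", "k", "l")]))
  ksh <- shell_index(shells, kd)

  # random half-split means for CC1/2 (keys with n >= 2)
  halves <- with_seed(seed, {
    ord <- order(pool$key, stats::runif(nrow(pool)))
    gi <- as.integer(grp)[ord]
    pos <- sequence(rle(gi)$lengths)
    half <- (pos - 1) %% 2 + 1
    cbind(key_i = gi, half = half, i = pool$i[ord])
  })
  h1 <- rowsum(ifelse(halves[, "half"] == 1, halves[, "i"], 0), halves[, "key_i"])
  c1 <- rowsum(as.numeric(halves[, "half"] == 1), halves[, "key_i"])
  h2 <- rowsum(ifelse(halves[, "half"] == 2, halves[, "i"], 0), halves[, "key_i"])
  c2 <- rowsum(as.numeric(halves[, "half"] == 2), halves[, "key_i"])
  both <- c1 > 0 & c2 > 0
  half_mean <- cbind(h1 / pmax(c1, 1), h2 / pmax(c2, 1))

  theo <- NULL
  if (completeness) {
    theo_keys <- unique_reflections(cell, ops, shells$edges[1],
                                    shells$edges[length(shells$edges)],
                                    anomalous = anomalous)
    theo <- tabulate(shell_index(shells, theo_keys$d), nbins = shells$n_shells)
  }

  one <- function(sel) {
    nh <- n_h[sel]
    mult_ok <- nh >= 2
    num_meas <- sum(sqrt(nh[mult_ok] / (nh[mult_ok] - 1)) * absdev[sel][mult_ok])
    num_pim <- sum(sqrt(1 / (nh[mult_ok] - 1)) * absdev[sel][mult_ok])
    den <- sum(sum_i[sel][mult_ok])
    cc_sel <- sel & both
    cc <- if (sum(cc_sel) >= 3)
      suppressWarnings(stats::cor(half_mean[cc_sel, 1], half_mean[cc_sel, 2]))
    else NA_real_
    merged_i <- swi[sel] / sw[sel]
    merged_sig <- 1 / sqrt(sw[sel])
    c(n_unique = sum(sel),
      multiplicity = if (any(sel)) mean(nh) else NA_real_,
      i_over_sig = if (any(sel)) mean(merged_i / merged_sig) else NA_real_,
      r_meas = if (any(mult_ok) && den != 0) num_meas / den else NA_real_,
      r_pim = if (any(mult_ok) && den != 0) num_pim / den else NA_real_,
      cc_half = cc)
  }

  rows <- t(vapply(seq_len(shells$n_shells), function(s) one(ksh == s),
                   numeric(6)))
  overall <- one(rep(TRUE, length(n_h)))
  edges <- shells$edges
  out <- data.frame(
    shell = c(as.character(seq_len(shells$n_shells)), "overall"),
    d_max = c(edges[-length(edges)], edges[1]),
    d_min = c(edges[-1], edges[length(edges)]),
    rbind(rows, overall))
  if (completeness) {
    out$n_theoretical <- c(theo, sum(theo))
    out$completeness <- ifelse(out$n_theoretical > 0,
                               out$n_unique / out$n_theoretical, NA_real_)
  }
  rownames(out) <- NULL
  class(out) <- c("shell_stats", "data.frame")
  out
}

#' Shell-resolved merging statistics
#'
#' Computes the standard multi-crystal data-quality table per resolution
#' shell and overall: R_meas (multiplicity-weighted merging R),
#' R_pim (precision-indicating R), CC1/2 (Pearson correlation between two
#' seeded random half-splits of each reflection's observations), mean merged
#' I/sigma, completeness against the exact theoretical unique-key count,
#' and multiplicity. Statistics that are undefined in a shell (no
#' multiplicity >= 2, too few half-split pairs) are reported as NA, never 0.
#'
#' @param datasets List of [xtal_dataset()].
#' @param scales Per-dataset [scale_model()] list, or NULL for unit scales.
#' @param shells A [make_shells()] scheme.
#' @param anomalous Friedel-separated statistics?
#' @param seed Seed for the CC1/2 half split.
#' @param completeness Compute the (exact, enumerative) completeness column?
#' @return A `shell_stats` data.frame; last row is the overall line.
#' @export
shell_statistics <- function(datasets, scales = NULL, shells,
                             anomalous = FALSE, seed = 0,
                             completeness = TRUE) {
  if (is.null(scales)) scales <- rep(list(scale_model(1, 0)), length(datasets))
  pool <- pool_observations(datasets, scales, anomalous)
  shell_stats_core(pool, shells, datasets[[1]]$cell, datasets[[1]]$ops,
                   anomalous, seed = seed, completeness = completeness)
}

#' @export
print.shell_stats <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Fit the two-term intensity error model and ISa
#'
#' Models the observed variance of replicate observations as
#' `Var(I) = a (sigma0^2 + b I^2)`: `a` inflates the integration-stage
#' sigmas, `b` is the fractional systematic error floor. The asymptotic
#' signal-to-noise of an infinitely strong reflection is
#' `ISa = 1/sqrt(a b)`. Fitted by regressing, across intensity bins of
#' symmetry-replicate groups, the sample variance on the group-mean
#' `sigma0^2` and squared mean intensity.
#'
#' @param datasets List of [xtal_dataset()] (a single dataset gives that
#'   dataset's own ISa from its internal symmetry replicates).
#' @param scales Per-dataset scales or NULL.
#' @param n_bins Number of intensity bins for the variance regression.
#' @return Object of class `error_model_fit`: `a`, `b`, `isa`, `n_groups`,
#'   `ok` (FALSE marks a failed fit, e.g. negative `a` or `b`).
#' @export
fit_error_model <- function(datasets, scales = NULL, n_bins = 10) {
  if (is.null(scales)) scales <- rep(list(scale_model(1, 0)), length(datasets))
  pool <- pool_observations(datasets, scales, anomalous = FALSE)
  grp <- factor(pool$key)
  n <- as.vector(rowsum(rep(1, nrow(pool)), grp))
  si <- as.vector(rowsum(pool$i, grp))
  si2 <- as.vector(rowsum(pool$i^2, grp))
  ss2 <- as.vector(rowsum(pool$sigi^2, grp))
  rep_ok <- n >= 2
  if (sum(rep_ok) < 30)
    stop("need >= 30 unique reflections with multiplicity >= 2")
  mean_i <- (si / n)[rep_ok]
  samp_var <- ((si2 - si^2 / n) / (n - 1))[rep_ok]
  mean_s2 <- (ss2 / n)[rep_ok]
  bins <- cut(rank(mean_i, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  V <- tapply(samp_var, bins, mean)
  S <- tapply(mean_s2, bins, mean)
  Q <- tapply(mean_i^2, bins, mean)
  fit <- stats::lm.fit(cbind(S, Q), as.vector(V))
  a <- unname(fit$coefficients[1]); ab <- unname(fit$coefficients[2])
  ok <- is.finite(a) && is.finite(ab) && a > 0 && ab > 0
  structure(list(a = a, b = if (ok) ab / a else NA_real_,
                 isa = if (ok) 1 / sqrt(ab) else NA_real_,
                 n_groups = sum(rep_ok), ok = ok),
            class = "error_model_fit")
}

#' @export
print.error_model_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("Error model: a = %.4g, b = %.4g, ISa = %.2f (%d replicate groups)\n",
                x$a, x$b, x$isa, x$n_groups))
  else cat("Error model fit failed (non-positive a or b)\n")
  invisible(x)
}

#' Isomorphous difference R factor between two merged sets
#'
#' Compares native and derivative amplitudes (`F = sqrt(max(I, 0))`) over
#' common unique keys after least-squares scaling of the derivative to the
#' native: `R_iso = sum |F_nat - c F_der| / sum F_nat`. The Pearson
#' correlation of the amplitudes is attached as attribute `cc_iso`.
#'
#' @param native,derivative Friedel-merged [merged_set()] objects.
#' @return R_iso as a single number, with attributes `cc_iso` and `n_common`.
#' @export
r_iso <- function(native, derivative) {
  stopifnot(is_merged_set(native), is_merged_set(derivative))
  if (native$anomalous || derivative$anomalous)
    stop("r_iso expects Friedel-merged sets")
  m <- match(encode_key(native$entries), encode_key(derivative$entries))
  ok <- !is.na(m)
  if (sum(ok) < 10) stop("fewer than 10 common reflections")
  fn <- sqrt(pmax(native$entries$i[ok], 0))
  fd <- sqrt(pmax(derivative$entries$i[m[ok]], 0))
  cc <- sum(fn * fd) / sum(fd^2)
  out <- sum(abs(fn - cc * fd)) / sum(fn)
  attr(out, "cc_iso") <- suppressWarnings(stats::cor(fn, fd))
  attr(out, "n_common") <- sum(ok)
  out
}
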
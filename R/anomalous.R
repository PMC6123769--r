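#' Bijvoet difference table
#'
#' Pairs the "+" and "-" Friedel mates of a Friedel-separated merged set and
#' tabulates the anomalous intensity difference `d_anom = I(+) - I(-)` with
#' propagated sigma. Keys with only one mate observed are dropped. The
#' amplitude-scale difference `dF = d_anom / (2 sqrt(max(I_mean, sigma)))` is
#' attached as a derived column.
#'
#' @param merged An anomalous (Friedel-separated) [merged_set()].
#' @return data.frame of class `bijvoet_table` with columns `h, k, l`
#'   (canonical ASU triple), `i_plus, i_minus, d_anom, sigma_danom, d, dF`.
#' @export
bijvoet_table <- function(merged) {
  stopifnot(is_merged_set(merged))
  if (!merged$anomalous) stop("bijvoet_table needs a Friedel-separated merged set")
  e <- merged$entries
  hk <- encode_hkl(as.matrix(e[c("h", "k", "l")]))
  plus <- e$friedel == "+"
  m <- match(hk[plus], hk[!plus])
  ok <- !is.na(m)
  p <- e[plus, ][ok, ]
  q <- e[!plus, ][m[ok], ]
  i_mean <- (p$i + q$i) / 2
  out <- data.frame(
    h = p$h, k = p$k, l = p$l,
    i_plus = p$i, i_minus = q$i,
    d_anom = p$i - q$i,
    sigma_danom = sqrt(p$sigma^2 + q$sigma^2),
    d = d_spacing(merged$cell, as.matrix(p[c("h", "k", "l")])))
  out$dF <- out$d_anom / (2 * sqrt(pmax(i_mean, p$sigma)))
  rownames(out) <- NULL
  class(out) <- c("bijvoet_table", "data.frame")
  out
}

#' Expected Bijvoet ratio from an anomalous-scattering budget
#'
#' Hendrickson-style feasibility estimate of the fractional anomalous
#' amplitude difference:
#' `dF/F = sqrt(N_A / (2 N_T)) * 2 f'' / Z_eff`,
#' with `N_A` anomalous sites, `N_T` non-hydrogen protein atoms, `f''` the
#' imaginary anomalous correction in electrons and `Z_eff` the effective
#' normal scattering per protein atom (6.7 electrons by default).
#'
#' @param n_anom_sites Number of anomalous scatterer sites (N_A > 0).
#' @param n_protein_atoms Number of non-H atoms in the asymmetric unit
#'   (N_T > 0).
#' @param f_dprime f'' in electrons (>= 0).
#' @param z_eff Effective normal scattering per atom, electrons.
#' @return Expected dF/F as a fraction (e.g. 0.014 for 1.4%).
#' @examples
#' bijvoet_ratio_estimate(18, 3448, 0.94)  # sulfur at 6 keV
#' @export
bijvoet_ratio_estimate <- function(n_anom_sites, n_protein_atoms, f_dprime,
                                   z_eff = 6.7) {
  if (n_anom_sites <= 0 || n_protein_atoms <= 0) stop("atom counts must be positive")
  if (f_dprime < 0) stop("f'' must be >= 0")
  if (z_eff <= 0) stop("z_eff must be positive")
  sqrt(n_anom_sites / (2 * n_protein_atoms)) * 2 * f_dprime / z_eff
}

#' Tabulated f'' values
#'
#' Approximate imaginary anomalous-scattering corrections (electrons) for the
#' elements and wavelengths used in the supported phasing experiments:
#' S at 2.0664 A (6 keV), Se at 0.9785 A (K edge), Hg at 1.9 A, W at
#' 1.2137 A (LIII edge). Magnitudes follow the standard Sasaki-type
#' tabulations; near an absorption edge the true value depends on the exact
#' energy and chemical environment, so override numerically for quantitative
#' work.
#'
#' @param element "S", "Se", "Hg" or "W".
#' @param wavelength Wavelength in Angstrom (must match a tabulated entry
#'   within 0.01 A).
#' @return f'' in electrons.
#' @export
f_dprime_lookup <- function(element, wavelength) {
  tab <- data.frame(
    element = c("S", "Se", "Hg", "W"),
    wavelength = c(2.0664, 0.9785, 1.9, 1.2137),
    f_dprime = c(0.94, 3.80, 7.69, 9.87))
  hit <- tab$element == element & abs(tab$wavelength - wavelength) <= 0.01
  if (!any(hit)) stop("no tabulated f'' for ", element, " at ", wavelength, " A")
  tab$f_dprime[hit][1]
}

#' Split-half correlation of the anomalous signal
#'
#' Datasets are split into two random (seeded) halves; each half is merged
#' Friedel-separated and its Bijvoet differences computed; the Pearson
#' correlation between the two halves' `d_anom` over common keys is returned
#' per resolution shell and overall. A genuine anomalous signal correlates
#' between independent halves; pure noise does not.
#'
#' @param datasets List of at least 4 [xtal_dataset()].
#' @param shells A [make_shells()] scheme; NULL derives the default.
#' @param seed Seed for the half assignment.
#' @param fit_scales Scale each half sequentially before merging; set FALSE
#'   for data already on a common scale.
#' @return data.frame with columns `shell`, `n_pairs`, `cc` (last row
#'   "overall").
#' @export
anomalous_cc_split <- function(datasets, shells = NULL, seed = 0,
                               fit_scales = TRUE) {
  if (length(datasets) < 4) stop("need at least 4 datasets to split")
  if (is.null(shells)) shells <- default_shells(datasets)
  idx <- with_seed(seed, sample(rep(1:2, length.out = length(datasets))))
  half_tab <- function(half) {
    merged <- if (fit_scales)
      scale_and_merge(datasets[idx == half], anomalous = TRUE)$merged
    else merge_datasets(datasets[idx == half], anomalous = TRUE)
    bijvoet_table(merged)
  }
  t1 <- half_tab(1); t2 <- half_tab(2)
  m <- match(encode_hkl(as.matrix(t1[c("h", "k", "l")])),
             encode_hkl(as.matrix(t2[c("h", "k", "l")])))
  ok <- !is.na(m)
  cc_by_shell(t1$d_anom[ok], t2$d_anom[m[ok]],
              shell_index(shells, t1$d[ok]), shells$n_shells)
}

#' Refine a global anomalous scale
#'
#' One-parameter analog of anomalous-substructure refinement: weighted least
#' squares through the origin of observed against calculated Bijvoet
#' differences, `s = sum(w d_obs d_calc) / sum(w d_calc^2)` with
#' `w = 1/sigma_danom(obs)^2`. The scale estimates
#' occupancy x (f''_true / f''_assumed) of the substructure used for the
#' calculated differences.
#'
#' @param observed,calculated [bijvoet_table()] objects, matched by ASU key.
#' @return List with `s`, `se` (standard error), `n_common`.
#' @export
refine_anomalous_scale <- function(observed, calculated) {
  m <- match(encode_hkl(as.matrix(observed[c("h", "k", "l")])),
             encode_hkl(as.matrix(calculated[c("h", "k", "l")])))
  ok <- !is.na(m)
  if (sum(ok) < 20) stop("fewer than 20 common Bijvoet pairs")
  do <- observed$d_anom[ok]
  dc <- calculated$d_anom[m[ok]]
  w <- 1 / observed$sigma_danom[ok]^2
  den <- sum(w * dc^2)
  if (den == 0) stop("degenerate calculated table: all d_anom zero")
  s <- sum(w * do * dc) / den
  list(s = s, se = 1 / sqrt(den), n_common = sum(ok))
}

#' Substitution fraction from refined f'' values
#'
#' Ratio of a refined anomalous scattering factor to a full-substitution
#' reference, as a percentage. `substitution_fraction(3.16, 5.38)` gives the
#' incomplete selenomethionine incorporation of a partially labelled protein
#' relative to a fully labelled reference: 58.7, reported as 59.
#'
#' @param f_dprime_refined Refined f'' (electrons).
#' @param f_dprime_reference Reference f'' at 100% substitution (> 0).
#' @return Percentage (numeric); attribute `reported` carries the
#'   nearest-integer percent used for reporting.
#' @export
substitution_fraction <- function(f_dprime_refined, f_dprime_reference) {
  if (f_dprime_reference <= 0) stop("reference f'' must be positive")
  pct <- 100 * f_dprime_refined / f_dprime_reference
  attr(pct, "reported") <- as.integer(round(pct))
  pct
}
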
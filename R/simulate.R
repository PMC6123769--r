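#' Atom specifications for the structure-factor simulator
#'
#' @param frac_xyz n x 3 matrix of fractional coordinates (wrapped into
#'   \[0,1)).
#' @param z Atomic number(s). @param b_iso Isotropic B factor(s), Angstrom^2.
#' @param f_prime,f_dprime Real and imaginary anomalous corrections,
#'   electrons.
#' @param occupancy Site occupancy in \[0, 1\].
#' @return data.frame with one row per atom.
#' @export
atom_spec <- function(frac_xyz, z = 6, b_iso = 20, f_prime = 0, f_dprime = 0,
                      occupancy = 1) {
  m <- as_hkl_matrix(frac_xyz)  # any n x 3 numeric
  m <- m - floor(m)
  out <- data.frame(x = m[, 1], y = m[, 2], z3 = m[, 3],
                    zn = z, b_iso = b_iso, f_prime = f_prime,
                    f_dprime = f_dprime, occ = occupancy)
  if (any(out$zn < 1)) stop("atomic number must be >= 1")
  if (any(out$b_iso < 0)) stop("b_iso must be >= 0")
  if (any(out$occ < 0 | out$occ > 1)) stop("occupancy must lie in [0,1]")
  out
}

#' Random anomalous substructure
#'
#' @param n Number of sites.
#' @param f_dprime f'' per site, electrons. @param f_prime f' per site.
#' @param z Atomic number (default 34, selenium-like).
#' @param b_iso B factor. @param occupancy Site occupancy.
#' @param seed RNG seed.
#' @return An [atom_spec()] data.frame.
#' @export
random_anom_sites <- function(n, f_dprime = 4, f_prime = 0, z = 34,
                              b_iso = 20, occupancy = 1, seed = 1) {
  xyz <- with_seed(seed, matrix(stats::runif(3 * n), ncol = 3))
  atom_spec(xyz, z = z, b_iso = b_iso, f_prime = f_prime,
            f_dprime = f_dprime, occupancy = occupancy)
}

# structure factors at +h and -h for every asu key
# single-Gaussian form factor f(s) = z exp(-b_el s^2), b_el = 2.0 A^2
calc_structure_factors <- function(cell, ops, atoms, d_min, b_el = 2.0) {
  d_max <- max(cell$a, cell$b, cell$c) * 1.01
  keys <- unique_reflections(cell, ops, d_max, d_min, anomalous = FALSE)
  H <- as.matrix(keys[c("h", "k", "l")])
  s2 <- s_squared(cell, H)
  # expand atoms over the point group: coordinate operator for rotation R
  # acting on hkl is t(R) (keeps |F| invariant over each orbit)
  expanded <- do.call(rbind, lapply(ops$rotations, function(R) {
    a <- atoms
    xyz <- as.matrix(atoms[c("x", "y", "z3")]) %*% R  # x' = t(R) x, rows
    xyz <- xyz - floor(xyz)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z3 <- xyz[, 3]
    a
  }))
  n <- nrow(H)
  f_plus <- complex(real = numeric(n), imaginary = numeric(n))
  f_minus <- f_plus
  chunk <- 200L
  for (start in seq(1, nrow(expanded), by = chunk)) {
    ai <- expanded[start:min(start + chunk - 1L, nrow(expanded)), ]
    phases <- exp(2i * pi * (H %*% t(as.matrix(ai[c("x", "y", "z3")]))))
    # n x m coefficient: occ (z e^{-b_el s2} + f' + i f'') e^{-B s2}
    normal <- outer(exp(-b_el * s2), ai$zn * ai$occ)
    anom <- matrix(ai$occ * (ai$f_prime + 1i * ai$f_dprime),
                   n, nrow(ai), byrow = TRUE)
    dw <- exp(-outer(s2, ai$b_iso))
    coeff <- (normal + anom) * dw
    f_plus <- f_plus + rowSums(coeff * phases)
    f_minus <- f_minus + rowSums(coeff * Conj(phases))
  }
  data.frame(h = keys$h, k = keys$k, l = keys$l, d = keys$d, s2 = s2,
             i_plus = Mod(f_plus)^2, i_minus = Mod(f_minus)^2,
             re_plus = Re(f_plus), im_plus = Im(f_plus),
             re_minus = Re(f_minus), im_minus = Im(f_minus))
}

#' Ground-truth structure factors for a synthetic crystal
#'
#' Places `n_atoms` random light atoms (carbon-like single-Gaussian form
#' factors) plus an optional anomalous substructure in the cell, expands over
#' the point group, and evaluates complex structure factors at +h and -h for
#' every unique reflection to `d_min`. The resulting intensities obey
#' Friedel's law exactly when all f'' are zero and are invariant under the
#' point-group rotations by construction.
#'
#' @param cell A [unit_cell()]. @param ops A [point_group()].
#' @param n_atoms Number of random light atoms (>= 10).
#' @param anom_sites Optional [atom_spec()] of anomalous scatterers.
#' @param d_min High-resolution limit, Angstrom.
#' @param seed RNG seed for the light-atom coordinates.
#' @param b_iso_light B factor given to the light atoms.
#' @return Object of class `ground_truth`: `table` (per-key d, s2, i_plus,
#'   i_minus and complex components), `cell`, `ops`, `atoms`, `d_min`,
#'   `seed`.
#' @export
make_ground_truth <- function(cell, ops, n_atoms = 400, anom_sites = NULL,
                              d_min = 2.5, seed = 1, b_iso_light = 20) {
  stopifnot(is_unit_cell(cell), is_point_group(ops))
  if (n_atoms < 10) stop("need at least 10 atoms")
  if (d_min <= 0) stop("d_min must be positive")
  light <- atom_spec(with_seed(seed, matrix(stats::runif(3 * n_atoms), ncol = 3)),
                     z = 6, b_iso = b_iso_light)
  atoms <- if (is.null(anom_sites)) light else rbind(light, anom_sites)
  structure(list(table = calc_structure_factors(cell, ops, atoms, d_min),
                 cell = cell, ops = ops, atoms = atoms, d_min = d_min,
                 seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d unique reflections to %.2f A, %d atoms (%d anomalous), point group %s\n",
              nrow(x$table), x$d_min, nrow(x$atoms),
              sum(x$atoms$f_dprime != 0), x$ops$name))
  invisible(x)
}

#' Displace a ground truth's atoms (non-isomorphous contaminant)
#'
#' Applies a Gaussian coordinate displacement of total RMS `rms` Angstrom to
#' every atom and recomputes the structure factors. This produces the
#' resolution-dependent intensity decorrelation characteristic of
#' non-isomorphous crystals.
#'
#' @param truth A [make_ground_truth()] object.
#' @param rms Total RMS displacement in Angstrom.
#' @param seed RNG seed for the displacement.
#' @return A new `ground_truth`.
#' @export
perturb_ground_truth <- function(truth, rms = 0.5, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  atoms <- truth$atoms
  shift <- with_seed(seed, matrix(stats::rnorm(3 * nrow(atoms), 0, rms / sqrt(3)),
                                  ncol = 3))
  # Cartesian displacement mapped to fractional via the cell edges
  frac <- sweep(shift, 2, c(truth$cell$a, truth$cell$b, truth$cell$c), "/")
  xyz <- as.matrix(atoms[c("x", "y", "z3")]) + frac
  xyz <- xyz - floor(xyz)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z3 <- xyz[, 3]
  structure(list(table = calc_structure_factors(truth$cell, truth$ops, atoms,
                                                truth$d_min),
                 cell = truth$cell, ops = truth$ops, atoms = atoms,
                 d_min = truth$d_min, seed = seed),
            class = "ground_truth")
}

#' Two-term intensity noise model
#'
#' Observation variance `Var(I) = sigma_floor^2 + alpha I + (gamma I)^2`;
#' the reported sigma carries only the first two terms (the fractional
#' systematic error `gamma` is what the ISa error model must discover).
#'
#' @param sigma_floor Additive SD at zero intensity.
#' @param alpha Counting-noise coefficient.
#' @param gamma Fractional systematic error.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_floor = 0, alpha = 0, gamma = 0) {
  if (sigma_floor < 0 || alpha < 0 || gamma < 0) stop("noise terms must be >= 0")
  if (sigma_floor == 0 && alpha == 0 && gamma == 0)
    stop("noise model cannot be all zero (use a tiny sigma_floor for noiseless data)")
  structure(list(sigma_floor = sigma_floor, alpha = alpha, gamma = gamma),
            class = "noise_model")
}

#' Noise model targeting a per-dataset signal-to-noise
#'
#' Chooses the counting coefficient `alpha` so a single dataset's mean I/sigma
#' is approximately `target_i_over_sig` (using the Wilson-exponential
#' expectation `E sqrt(I/alpha) = 0.886 sqrt(mean I / alpha)`), a sigma floor
#' at 10% of a mean-intensity reflection's sigma, and fractional error
#' `gamma`.
#'
#' @param truth A [make_ground_truth()] object.
#' @param target_i_over_sig Target mean I/sigma per dataset.
#' @param gamma Fractional systematic error (default 0.03, i.e. ISa ~ 33 for
#'   an accurate integration stage).
#' @return A [noise_model()].
#' @export
default_noise_model <- function(truth, target_i_over_sig = 3, gamma = 0.03) {
  mean_i <- mean((truth$table$i_plus + truth$table$i_minus) / 2)
  alpha <- mean_i * (0.886 / target_i_over_sig)^2
  noise_model(sigma_floor = 0.1 * sqrt(alpha * mean_i), alpha = alpha,
              gamma = gamma)
}

#' Microcrystal-ensemble specification
#'
#' Describes the ensemble the simulator emits: counts of isomorphous and
#' contaminant crystals, per-crystal coverage of the unique reflections, and
#' the per-dataset scale/B jitter and noise.
#'
#' @param n_iso,n_contaminant Dataset counts (n_iso + n_contaminant >= 2).
#' @param coverage Fraction of unique keys each crystal records, in (0, 1\].
#' @param wedge_deg Nominal wedge size carried as metadata, degrees.
#' @param scale_jitter SD of log k (lognormal linear scale per dataset).
#' @param b_jitter SD of the per-dataset relative B, Angstrom^2.
#' @param perturb_rms Coordinate RMS displacement defining the contaminant
#'   lattice, Angstrom.
#' @param noise A [noise_model()]; NULL uses [default_noise_model()] at
#'   mean I/sigma 3.
#' @param seed Master seed; all per-dataset seeds derive from it.
#' @return Object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_iso = 40, n_contaminant = 10, coverage = 0.2,
                          wedge_deg = 15, scale_jitter = 0.2, b_jitter = 2,
                          perturb_rms = 0.5, noise = NULL, seed = 1) {
  if (n_iso + n_contaminant < 2) stop("need at least 2 datasets")
  if (!(coverage > 0 && coverage <= 1)) stop("coverage must be in (0, 1]")
  structure(list(n_iso = as.integer(n_iso),
                 n_contaminant = as.integer(n_contaminant),
                 coverage = coverage, wedge_deg = wedge_deg,
                 scale_jitter = scale_jitter, b_jitter = b_jitter,
                 perturb_rms = perturb_rms, noise = noise,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Simulate one microcrystal's partial dataset
#'
#' Draws a per-dataset linear scale `k ~ lognormal(0, scale_jitter)` and
#' relative B `~ Normal(0, b_jitter)`, records a random coverage-fraction
#' subset of the unique reflections (both Friedel mates of every selected
#' key), applies `I = |F(+/-h)|^2 k exp(-2 B s^2)` and the noise model, and
#' scatters the emitted Miller indices over the symmetry orbit. Coverage is
#' index-set coverage only; no diffraction geometry is modelled.
#'
#' @param truth A [make_ground_truth()] (for contaminants, pass the perturbed
#'   truth and set `truth_label`).
#' @param spec An [ensemble_spec()].
#' @param dataset_seed Per-dataset RNG seed.
#' @param id Dataset id.
#' @param truth_label "isomorphous" or "contaminant".
#' @param add_noise Set FALSE to record exact noise-free intensities (sigmas
#'   still follow the noise model) — the basis of the identity oracles.
#' @return An [xtal_dataset()]; the drawn `k` and `B` are attached as
#'   attribute `sim`.
#' @export
sample_crystal_dataset <- function(truth, spec, dataset_seed, id = "sim",
                                   truth_label = "isomorphous",
                                   add_noise = TRUE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "ensemble_spec"))
  nm <- if (is.null(spec$noise)) default_noise_model(truth) else spec$noise
  tab <- truth$table
  with_seed(dataset_seed, {
    k <- exp(stats::rnorm(1, 0, spec$scale_jitter))
    B <- stats::rnorm(1, 0, spec$b_jitter)
    n_sel <- round(spec$coverage * nrow(tab))
    if (n_sel < 10) stop("coverage too low: fewer than 10 reflections drawn")
    sel <- sort(sample.int(nrow(tab), n_sel))
    t2 <- tab[sel, ]
    g <- k * exp(-2 * B * t2$s2)
    # both Friedel mates of each selected key
    i_true <- c(t2$i_plus * g, t2$i_minus * g)
    H <- rbind(as.matrix(t2[c("h", "k", "l")]), -as.matrix(t2[c("h", "k", "l")]))
    sig0 <- sqrt(nm$sigma_floor^2 + nm$alpha * i_true)
    sd_true <- sqrt(sig0^2 + (nm$gamma * i_true)^2)
    i_obs <- if (add_noise) i_true + stats::rnorm(length(i_true), 0, sd_true)
             else i_true
    # scatter indices over the symmetry orbit (intensity-invariant)
    rot <- sample(seq_along(truth$ops$rotations), length(i_obs), replace = TRUE)
    for (r in unique(rot)) {
      pick <- rot == r
      H[pick, ] <- H[pick, , drop = FALSE] %*% t(truth$ops$rotations[[r]])
    }
    ds <- xtal_dataset(id, truth$cell, truth$ops,
                       data.frame(h = H[, 1], k = H[, 2], l = H[, 3],
                                  i = i_obs, sigi = sig0),
                       wedge_deg = spec$wedge_deg, truth_label = truth_label)
    attr(ds, "sim") <- list(k = k, B = B, seed = dataset_seed)
    ds
  })
}

#' Simulate a labelled microcrystal ensemble
#'
#' Emits `n_iso` isomorphous and `n_contaminant` contaminant datasets with
#' per-dataset seeds derived deterministically from `spec$seed`. All
#' contaminants of one ensemble share a single perturbed lattice (one
#' coordinate displacement of RMS `perturb_rms`).
#'
#' @param truth A [make_ground_truth()] object.
#' @param spec An [ensemble_spec()].
#' @param add_noise Set FALSE for exact noise-free ensembles.
#' @return List with `datasets` (named list of [xtal_dataset()]), `manifest`
#'   (data.frame id, truth_label, k, B, n_obs, seed) and `perturbed_truth`
#'   (NULL when no contaminants).
#' @export
make_ensemble <- function(truth, spec, add_noise = TRUE) {
  n <- spec$n_iso + spec$n_contaminant
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max, n + 1))
  perturbed <- if (spec$n_contaminant > 0)
    perturb_ground_truth(truth, spec$perturb_rms, seed = seeds[n + 1])
  else NULL
  labels <- rep(c("isomorphous", "contaminant"), c(spec$n_iso, spec$n_contaminant))
  ids <- sprintf("run_%04d", seq_len(n))
  datasets <- lapply(seq_len(n), function(j) {
    src <- if (labels[j] == "contaminant") perturbed else truth
    sample_crystal_dataset(src, spec, seeds[j], id = ids[j],
                           truth_label = labels[j], add_noise = add_noise)
  })
  names(datasets) <- ids
  manifest <- data.frame(
    id = ids, truth_label = labels,
    k = vapply(datasets, function(d) attr(d, "sim")$k, 0),
    B = vapply(datasets, function(d) attr(d, "sim")$B, 0),
    n_obs = vapply(datasets, function(d) nrow(d$obs), 0L),
    seed = seeds[seq_len(n)])
  list(datasets = datasets, manifest = manifest, perturbed_truth = perturbed)
}
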
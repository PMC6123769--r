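# Shared fixtures and independent brute-force oracles.
# Expensive objects are memoised per test run.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fx, inherits = FALSE)) assign(name, expr, .fx)
  get(name, .fx, inherits = FALSE)
}

toy_cell <- function() unit_cell(30, 35, 40)
toy_pg <- function() point_group("222")

# small ground truth with anomalous substructure (~1000 unique keys)
small_truth <- function() memo("small_truth",
  make_ground_truth(toy_cell(), toy_pg(), n_atoms = 60,
                    anom_sites = random_anom_sites(4, f_dprime = 4, seed = 202),
                    d_min = 3, seed = 101))

# same lattice, no anomalous signal
small_truth_noanom <- function() memo("small_truth_noanom",
  make_ground_truth(toy_cell(), toy_pg(), n_atoms = 60, d_min = 3, seed = 101))

small_shells <- function(n = 5) {
  tr <- small_truth()
  make_shells(max(tr$table$d) * 1.0001, min(tr$table$d) * 0.9999, n)
}

# default-scale truth used by the recovery experiments
default_truth <- function() memo("default_truth",
  make_ground_truth(unit_cell(60, 70, 80), point_group("222"), n_atoms = 400,
                    anom_sites = random_anom_sites(8, f_dprime = 4, seed = 99),
                    d_min = 2.5, seed = 42))

# small contaminated ensemble shared by the selection tests
sel_ensemble <- function() memo("sel_ensemble", {
  make_ensemble(small_truth(),
                ensemble_spec(n_iso = 12, n_contaminant = 4, coverage = 0.6,
                              seed = 91))
})

# hand-rolled dataset from explicit observation rows
manual_dataset <- function(rows, id = "toy", cell = toy_cell(), ops = toy_pg()) {
  xtal_dataset(id, cell, ops,
               data.frame(h = rows[, 1], k = rows[, 2], l = rows[, 3],
                          i = rows[, 4], sigi = rows[, 5]))
}

# ---- independent oracles ------------------------------------------------

# merging statistics computed reflection-by-reflection with plain loops;
# intensities grouped by an externally supplied group id
brute_merge_stats <- function(i, sig, group) {
  groups <- split(seq_along(i), group)
  num_meas <- 0; num_pim <- 0; den <- 0
  wmean <- numeric(0); wsig <- numeric(0); mult <- integer(0)
  for (g in groups) {
    n <- length(g)
    mult <- c(mult, n)
    w <- 1 / sig[g]^2
    wmean <- c(wmean, sum(w * i[g]) / sum(w))
    wsig <- c(wsig, sqrt(1 / sum(w)))
    if (n >= 2) {
      dev <- sum(abs(i[g] - mean(i[g])))
      num_meas <- num_meas + sqrt(n / (n - 1)) * dev
      num_pim <- num_pim + sqrt(1 / (n - 1)) * dev
      den <- den + sum(i[g])
    }
  }
  list(r_meas = num_meas / den, r_pim = num_pim / den,
       multiplicity = mean(mult), i_merged = wmean, sigma_merged = wsig)
}

# general triclinic 1/d^2 quadratic form, coded independently of the
# package's metric-tensor route
brute_d_spacing <- function(a, b, c, al, be, ga, h, k, l) {
  al <- al * pi / 180; be <- be * pi / 180; ga <- ga * pi / 180
  ca <- cos(al); cb <- cos(be); cg <- cos(ga)
  V <- a * b * c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  inv_d2 <- (h^2 * b^2 * c^2 * sin(al)^2 +
             k^2 * a^2 * c^2 * sin(be)^2 +
             l^2 * a^2 * b^2 * sin(ga)^2 +
             2 * h * k * a * b * c^2 * (ca * cb - cg) +
             2 * k * l * a^2 * b * c * (cb * cg - ca) +
             2 * h * l * a * b^2 * c * (ca * cg - cb)) / V^2
  1 / sqrt(inv_d2)
}

# sensitivity/specificity of a selection result against the manifest labels
selection_confusion <- function(result, manifest) {
  iso <- manifest$id[manifest$truth_label == "isomorphous"]
  cont <- manifest$id[manifest$truth_label == "contaminant"]
  c(sensitivity = mean(iso %in% result$kept),
    specificity = mean(!(cont %in% result$kept)))
}

# noise-free single dataset covering the full truth (exact intensities)
exact_full_dataset <- function(truth, id = "exact", seed = 1) {
  spec <- ensemble_spec(n_iso = 2, n_contaminant = 0, coverage = 1,
                        scale_jitter = 0, b_jitter = 0,
                        noise = noise_model(sigma_floor = 1), seed = seed)
  sample_crystal_dataset(truth, spec, dataset_seed = seed, id = id,
                         add_noise = FALSE)
}
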
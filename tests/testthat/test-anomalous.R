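test_that("bijvoet_table pairs mates and propagates sigma", {
  e <- data.frame(h = c(1, 1, 2), k = c(2, 2, 0), l = c(3, 3, 1),
                  friedel = c("+", "-", "+"),
                  i = c(110, 90, 50), sigma = c(5, 5, 2), n_obs = 2L)
  ms <- merged_set(e, toy_cell(), toy_pg(), anomalous = TRUE)
  bt <- bijvoet_table(ms)
  expect_equal(nrow(bt), 1)        # the lone "+" of (2,0,1) is dropped
  expect_equal(bt$d_anom, 20)
  expect_equal(bt$sigma_danom, 7.0711, tolerance = 1e-4)

  only_plus <- merged_set(e[c(1, 3), ], toy_cell(), toy_pg(), anomalous = TRUE)
  expect_equal(nrow(bijvoet_table(only_plus)), 0)
  merged <- merge_datasets(list(exact_full_dataset(small_truth())))
  expect_error(bijvoet_table(merged), "Friedel-separated")
})

test_that("without anomalous scatterers Bijvoet differences are pure noise", {
  tr <- small_truth_noanom()
  spec <- ensemble_spec(n_iso = 6, n_contaminant = 0, coverage = 1,
                        scale_jitter = 0, b_jitter = 0, seed = 81,
                        noise = default_noise_model(tr, 10, gamma = 0))
  ens <- make_ensemble(tr, spec)
  bt <- bijvoet_table(merge_datasets(unname(ens$datasets), anomalous = TRUE))
  expect_gt(nrow(bt), 500)
  pull <- bt$d_anom / bt$sigma_danom
  expect_lt(abs(mean(pull)), 0.1)
  expect_lt(abs(sd(pull) - 1), 0.15)
})

test_that("bijvoet_ratio_estimate reproduces the closed-form arithmetic", {
  expect_equal(bijvoet_ratio_estimate(18, 3448, 0.94), 0.01434,
               tolerance = 1e-3)
  expect_equal(bijvoet_ratio_estimate(18, 3448, 0), 0)
  r <- bijvoet_ratio_estimate(18, 3448, 0.93) /
       bijvoet_ratio_estimate(18, 3448, 3.8)
  expect_equal(r, 0.2447, tolerance = 1e-3)
  expect_error(bijvoet_ratio_estimate(0, 100, 1), "positive")
})

test_that("ratio estimate scales as sqrt(N_A) and linearly in f''", {
  base <- bijvoet_ratio_estimate(4, 1000, 1)
  for (m in c(4, 9, 16))
    expect_equal(bijvoet_ratio_estimate(4 * m, 1000, 1) / base, sqrt(m),
                 tolerance = 1e-12)
  for (f in c(0.5, 2, 7))
    expect_equal(bijvoet_ratio_estimate(4, 1000, f) / base, f,
                 tolerance = 1e-12)
})

test_that("f'' lookup covers the shipped elements and rejects others", {
  expect_equal(f_dprime_lookup("S", 2.0664), 0.94)
  expect_equal(f_dprime_lookup("Se", 0.9785), 3.80)
  expect_error(f_dprime_lookup("Fe", 1.74), "no tabulated")
})

test_that("refine_anomalous_scale solves the trivial cases exactly", {
  tr <- small_truth()
  bt <- bijvoet_table(merge_datasets(list(exact_full_dataset(tr)),
                                     anomalous = TRUE))
  expect_gt(nrow(bt), 20)
  fit <- refine_anomalous_scale(bt, bt)
  expect_equal(fit$s, 1)
  bt2 <- bt
  bt2$d_anom <- 2 * bt2$d_anom
  expect_equal(refine_anomalous_scale(bt2, bt)$s, 2)
  flat <- bt
  flat$d_anom <- 0
  expect_error(refine_anomalous_scale(bt, flat), "degenerate")
})

test_that("the refined anomalous scale is unbiased under noise", {
  tr <- small_truth()
  calc <- bijvoet_table(merge_datasets(list(exact_full_dataset(tr)),
                                       anomalous = TRUE))
  truth_s <- 0.7
  sig <- 2 * stats::median(abs(calc$d_anom))   # <d/sigma> ~ 0.5 per reflection
  est <- vapply(1:200, function(r) {
    set.seed(1000 + r)
    obs <- calc
    obs$d_anom <- truth_s * calc$d_anom + rnorm(nrow(calc), 0, sig)
    obs$sigma_danom <- rep(sig, nrow(calc))
    refine_anomalous_scale(obs, calc)$s
  }, 0)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth_s), 2 * se + 1e-3)
})

test_that("substitution_fraction reports the integer percent", {
  v <- substitution_fraction(3.16, 5.38)
  expect_equal(as.numeric(v), 58.736, tolerance = 1e-3)
  expect_equal(attr(v, "reported"), 59L)
  expect_equal(attr(substitution_fraction(2, 2), "reported"), 100L)
  expect_equal(as.numeric(substitution_fraction(0, 5.38)), 0)
  expect_error(substitution_fraction(1, 0), "positive")
})

test_that("split-half anomalous CC separates signal from no signal", {
  spec <- ensemble_spec(n_iso = 8, n_contaminant = 0, coverage = 1,
                        scale_jitter = 0, b_jitter = 0, seed = 82,
                        noise = noise_model(sigma_floor = 1))
  # noiseless duplicated anomalous truth: CC_anom = 1
  ens <- make_ensemble(small_truth(), spec, add_noise = FALSE)
  cc <- anomalous_cc_split(unname(ens$datasets), seed = 4)
  expect_equal(cc$cc[cc$shell == "overall"], 1, tolerance = 1e-6)
  # f'' = 0 with realistic noise: per-shell CC_anom consistent with zero
  # (per shell, where the noise variance is homogeneous; across shells the
  # intensity-tracking variance inflates the overall Pearson value)
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    spec0 <- ensemble_spec(n_iso = 8, n_contaminant = 0, coverage = 1,
                           scale_jitter = 0, b_jitter = 0, seed = 82 + s,
                           noise = default_noise_model(small_truth_noanom(), 5,
                                                       gamma = 0))
    ens0 <- make_ensemble(small_truth_noanom(), spec0)
    cc0 <- anomalous_cc_split(unname(ens0$datasets), shells = small_shells(),
                              seed = 4)
    per <- cc0[cc0$shell != "overall" & cc0$n_pairs >= 5, ]
    hits <- hits + sum(abs(per$cc) < 3 / sqrt(per$n_pairs))
    total <- total + nrow(per)
    if (s == 1) expect_identical(
      cc0, anomalous_cc_split(unname(ens0$datasets), shells = small_shells(),
                              seed = 4))
  }
  expect_gte(hits / total, 0.9)
})
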
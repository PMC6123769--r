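test_that("presort ranks clean data first and flags sparse datasets", {
  tr <- small_truth_noanom()
  clean <- exact_full_dataset(tr, id = "clean")
  noisy <- clean
  set.seed(92)
  noisy$obs$i <- noisy$obs$i * (1 + rnorm(nrow(noisy$obs), 0, 0.2))
  noisy$id <- "noisy"
  sparse <- manual_dataset(rbind(c(1, 2, 3, 10, 1), c(2, 1, 4, 12, 1)),
                           id = "sparse", ops = point_group("1"))
  sh <- small_shells()
  tab <- presort_by_lowres_rmeas(list(noisy, sparse, clean), sh)
  expect_equal(tab$id[1], "clean")
  expect_equal(tab$rmeas_lowres[1], 0, tolerance = 1e-10)
  expect_equal(tab$id[3], "sparse")
  expect_true(tab$low_multiplicity[3])
})

test_that("presort orders 2% noise ahead of 10% noise (simulation)", {
  tr <- small_truth_noanom()
  base <- exact_full_dataset(tr)
  sh <- small_shells()
  wins <- 0L
  for (s in 1:100) {
    set.seed(1100 + s)
    mk <- function(lvl, id) {
      d <- base
      d$obs$i <- d$obs$i * (1 + rnorm(nrow(d$obs), 0, lvl))
      d$id <- id
      d
    }
    tab <- presort_by_lowres_rmeas(list(mk(0.10, "ten"), mk(0.02, "two")), sh)
    wins <- wins + (tab$id[1] == "two")
  }
  expect_gte(wins, 95)
})

test_that("cc_dataset is 1 against a leave-one-out reference of copies", {
  ds <- exact_full_dataset(small_truth_noanom())
  ref <- merge_datasets(list(ds, ds))   # two remaining copies
  cc <- cc_dataset(ds, ref, small_shells())
  expect_equal(cc$cc[cc$shell == "overall"], 1, tolerance = 1e-9)
})

test_that("an unrelated simulation shows null per-shell CC", {
  tr <- small_truth_noanom()
  other <- memo("unrelated_truth",
    make_ground_truth(toy_cell(), toy_pg(), n_atoms = 60, d_min = 3,
                      seed = 777))
  ref <- merge_datasets(list(exact_full_dataset(tr)))
  sh <- small_shells()
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    spec <- ensemble_spec(n_iso = 2, n_contaminant = 0, coverage = 1,
                          scale_jitter = 0, b_jitter = 0, seed = s,
                          noise = default_noise_model(other, 5, gamma = 0))
    ds <- sample_crystal_dataset(other, spec, dataset_seed = 1200 + s)
    cc <- cc_dataset(ds, ref, sh)
    per <- cc[cc$shell != "overall" & cc$n_pairs >= 5, ]
    hits <- hits + sum(abs(per$cc) < 3 / sqrt(per$n_pairs))
    total <- total + nrow(per)
  }
  expect_gte(hits / total, 0.9)
})

test_that("contaminants decorrelate from low to high resolution shells", {
  tr <- small_truth_noanom()
  pt <- perturb_ground_truth(tr, 0.5, seed = 94)
  ref <- merge_datasets(list(exact_full_dataset(tr)))
  spec <- ensemble_spec(n_iso = 2, n_contaminant = 0, coverage = 1,
                        scale_jitter = 0, b_jitter = 0, seed = 1,
                        noise = noise_model(sigma_floor = 1))
  cont <- sample_crystal_dataset(pt, spec, dataset_seed = 95,
                                 add_noise = FALSE)
  cc <- cc_dataset(cont, ref, small_shells())
  per <- cc$cc[cc$shell != "overall"]
  expect_lt(cor(seq_along(per), per, method = "spearman"), -0.8)
})

test_that("identical noiseless datasets are all kept in one iteration", {
  ds <- lapply(1:20, function(j)
    exact_full_dataset(small_truth_noanom(), id = paste0("c", j)))
  res <- select_datasets(ds, selection_config(cc_threshold = 0.5))
  expect_equal(length(res$kept), 20)
  expect_equal(res$selection_rate, 1.0)
  expect_equal(res$iterations, 1L)
  expect_true(res$converged)
})

test_that("an unreachable threshold triggers the min_kept guard", {
  ens <- sel_ensemble()
  expect_warning(
    res <- select_datasets(unname(ens$datasets),
                           selection_config(cc_threshold = 0.9995)),
    "min_kept")
  expect_true(res$min_kept_triggered)
  expect_gte(length(res$kept), 2)
})

test_that("selection is idempotent on its own kept set", {
  ens <- sel_ensemble()
  cfg <- selection_config(cc_threshold = "auto")
  res <- select_datasets(unname(ens$datasets), cfg)
  again <- select_datasets(unname(ens$datasets[res$kept]), cfg)
  expect_setequal(again$kept, res$kept)
})

test_that("kept-set size is non-increasing in the CC threshold", {
  ens <- sel_ensemble()
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.93, 0.96, 0.98), function(thr) {
    res <- suppressWarnings(
      select_datasets(unname(ens$datasets), selection_config(cc_threshold = thr)))
    length(res$kept)
  }, 0)
  expect_true(all(diff(sizes) <= 0))
  expect_gt(sizes[1], tail(sizes, 1))   # the sweep actually discriminates
})

test_that("auto selection separates contaminants on the shared ensemble", {
  ens <- sel_ensemble()
  # decision shell 3: on this small ensemble the lowest shells have too few
  # pairs for 0.5-A non-isomorphism to clear the CC sampling noise
  res <- select_datasets(unname(ens$datasets),
                         selection_config(cc_threshold = "auto",
                                          statistic = "cc_norm",
                                          decision_shell = 3))
  conf <- selection_confusion(res, ens$manifest)
  expect_gte(conf["sensitivity"], 0.9)
  expect_gte(conf["specificity"], 0.75)
  expect_setequal(c(res$kept, names(res$rejected)), ens$manifest$id)
})

test_that("weak-but-isomorphous data are kept while contaminants go", {
  tr <- small_truth_noanom()
  pt <- perturb_ground_truth(tr, 0.5, seed = 96)
  nm <- default_noise_model(tr, 6, gamma = 0)
  spec <- ensemble_spec(n_iso = 2, n_contaminant = 0, coverage = 0.8,
                        scale_jitter = 0, b_jitter = 0, noise = nm, seed = 1)
  set.seed(97)
  mk <- function(src, id, int_scale, noise_boost) {
    ds <- sample_crystal_dataset(src, spec, dataset_seed = sample.int(1e8, 1),
                                 id = id, add_noise = FALSE)
    sig0 <- ds$obs$sigi * noise_boost
    ds$obs$i <- (ds$obs$i + rnorm(nrow(ds$obs), 0, sig0)) * int_scale
    ds$obs$sigi <- sig0 * int_scale
    ds
  }
  # weak iso: x0.3 intensity; contaminants: full strength but noise boosted
  # so that both classes sit at the same mean I/sigma
  strong <- lapply(1:10, function(j) mk(tr, paste0("strong", j), 1, 1))
  weak <- lapply(1:10, function(j) mk(tr, paste0("weak", j), 0.3, 1 / 0.3))
  cont <- lapply(1:10, function(j) mk(pt, paste0("cont", j), 1, 1 / 0.3))
  res <- select_datasets(c(strong, weak, cont),
                         selection_config(cc_threshold = "auto",
                                          statistic = "cc_norm"))
  kept_weak <- mean(paste0("weak", 1:10) %in% res$kept)
  rej_cont <- mean(!paste0("cont", 1:10) %in% res$kept)
  expect_gte(kept_weak, 0.8)
  expect_gte(rej_cont, 0.9)
})
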
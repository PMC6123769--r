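one_shell <- function() make_shells(50, 2.5, 1)

test_that("R_meas matches hand arithmetic for a reflection observed twice", {
  rows <- rbind(c(1, 2, 3, 8, 1),
                c(1, 2, 3, 12, 1))
  st <- shell_statistics(list(manual_dataset(rows)), shells = one_shell(),
                         completeness = FALSE)
  ov <- st[st$shell == "overall", ]
  expect_equal(ov$r_meas, sqrt(2) * 4 / 20, tolerance = 1e-12)
  expect_equal(ov$r_pim, 4 / 20, tolerance = 1e-12)
  expect_equal(ov$multiplicity, 2)
})

test_that("duplicated noiseless data give R_meas 0 and CC1/2 exactly 1", {
  # no anomalous signal, so Friedel mates are genuine replicates
  ds <- exact_full_dataset(small_truth_noanom())
  st <- shell_statistics(list(ds, ds), shells = small_shells(),
                         completeness = FALSE)
  expect_equal(st$r_meas, rep(0, nrow(st)))
  expect_equal(st$cc_half, rep(1, nrow(st)))
})

test_that("a 5-reflection toy table matches the brute-force oracle to 1e-12", {
  set.seed(41)
  mult <- c(2, 3, 2, 4, 2)
  keys <- rbind(c(1, 2, 3), c(2, 0, 1), c(0, 3, 2), c(4, 1, 1), c(1, 1, 5))
  rows <- do.call(rbind, lapply(seq_along(mult), function(j) {
    cbind(matrix(keys[j, ], mult[j], 3, byrow = TRUE),
          rnorm(mult[j], 100, 30), runif(mult[j], 1, 5))
  }))
  ds <- manual_dataset(rows, ops = point_group("1"))
  st <- shell_statistics(list(ds), shells = one_shell(), completeness = FALSE)
  ov <- st[st$shell == "overall", ]
  oracle <- brute_merge_stats(rows[, 4], rows[, 5],
                              rep(seq_along(mult), mult))
  expect_equal(ov$r_meas, oracle$r_meas, tolerance = 1e-12)
  expect_equal(ov$r_pim, oracle$r_pim, tolerance = 1e-12)
  expect_equal(ov$multiplicity, oracle$multiplicity, tolerance = 1e-12)
})

test_that("R_meas >= R_pim, equal only when every multiplicity is 2", {
  set.seed(42)
  for (rep in 1:20) {
    n_key <- 30
    keys <- unique(matrix(sample(1:8, 3 * n_key, TRUE), ncol = 3))
    mult <- sample(2:6, nrow(keys), TRUE)
    rows <- do.call(rbind, lapply(seq_len(nrow(keys)), function(j) {
      cbind(matrix(keys[j, ], mult[j], 3, byrow = TRUE),
            rnorm(mult[j], 80, 25), runif(mult[j], 1, 3))
    }))
    st <- shell_statistics(list(manual_dataset(rows, ops = point_group("1"))),
                           shells = one_shell(), completeness = FALSE)
    ov <- st[st$shell == "overall", ]
    expect_gte(ov$r_meas, ov$r_pim)
  }
  # all-pairs case: R_meas = sqrt(2) * R_pim ... equality of the sqrt factors
  rows <- rbind(c(1, 2, 3, 8, 1), c(1, 2, 3, 12, 1),
                c(2, 1, 1, 50, 1), c(2, 1, 1, 60, 1))
  st <- shell_statistics(list(manual_dataset(rows, ops = point_group("1"))),
                         shells = one_shell(), completeness = FALSE)
  ov <- st[st$shell == "overall", ]
  expect_equal(ov$r_meas, sqrt(2) * ov$r_pim, tolerance = 1e-12)
})

test_that("CC1/2 decreases monotonically with injected fractional noise", {
  tr <- small_truth()
  base <- exact_full_dataset(tr)
  levels <- c(0.01, 0.02, 0.05, 0.10, 0.20)
  cc <- vapply(seq_along(levels), function(j) {
    set.seed(50 + j)
    noisy <- lapply(1:2, function(copy) {
      d <- base
      d$obs$i <- d$obs$i * (1 + rnorm(nrow(d$obs), 0, levels[j]))
      d$id <- paste0("n", copy)
      d
    })
    st <- shell_statistics(noisy, shells = one_shell(), completeness = FALSE)
    st$cc_half[st$shell == "overall"]
  }, 0)
  expect_lte(cor(levels, cc, method = "spearman"), -0.9)
})

test_that("empty shells report NA markers, not zeros", {
  rows <- rbind(c(1, 0, 0, 10, 1), c(1, 0, 0, 12, 1),  # d = 30
                c(10, 0, 0, 5, 1), c(10, 0, 0, 6, 1))  # d = 3
  st <- shell_statistics(list(manual_dataset(rows)),
                         shells = make_shells(30.1, 2.9, 4),
                         completeness = FALSE)
  mid <- st[st$shell %in% c("2", "3"), ]
  expect_true(all(is.na(mid$r_meas)))
  expect_true(all(is.na(mid$cc_half)))
  expect_true(all(mid$n_unique == 0))
})

test_that("union completeness of partial datasets follows 1 - (1-f)^N", {
  tr <- small_truth()
  f <- 0.3; N <- 10
  ens <- make_ensemble(tr, ensemble_spec(n_iso = N, n_contaminant = 0,
                                         coverage = f, seed = 61))
  sh <- make_shells(max(tr$table$d) * 1.0001, min(tr$table$d) * 0.9999, 1)
  st <- shell_statistics(unname(ens$datasets), shells = sh)
  got <- st$completeness[st$shell == "overall"]
  expected <- 1 - (1 - f)^N
  # binomial error on ~1000 keys
  expect_lt(abs(got - expected), 3 * sqrt(expected * (1 - expected) / 900) + 0.01)
})

test_that("anomalous completeness counts Friedel mates separately", {
  tr <- small_truth()
  ds <- exact_full_dataset(tr)
  sh <- make_shells(max(tr$table$d) * 1.0001, min(tr$table$d) * 0.9999, 1)
  stm <- shell_statistics(list(ds), shells = sh, anomalous = FALSE)
  sta <- shell_statistics(list(ds), shells = sh, anomalous = TRUE)
  expect_equal(stm$completeness[2], 1, tolerance = 1e-6)
  expect_equal(sta$completeness[2], 1, tolerance = 1e-6)
  # acentric keys double; centric zones (h, k or l = 0 in 222) do not
  expect_gt(sta$n_theoretical[2], 1.4 * stm$n_theoretical[2])
  expect_lt(sta$n_theoretical[2], 2 * stm$n_theoretical[2])
})
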
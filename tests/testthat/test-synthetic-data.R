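test_that("generate_library handles the empty case and is seed-deterministic", {
  expect_equal(nrow(generate_library(0, c(70, 600), 0, seed = 1)), 0L)
  l1 <- generate_library(100, c(70, 600), n_silc = 17, seed = 7)
  l2 <- generate_library(100, c(70, 600), n_silc = 17, seed = 7)
  expect_identical(l1, l2)
  expect_equal(sum(l1$is_silc), 17L)
  expect_error(generate_library(10, c(100, 100), 0, seed = 1), "empty mass range")
  expect_error(generate_library(5, c(70, 600), 6, seed = 1), "n_silc")
})

test_that("generated masses are pairwise separated beyond twice the tolerance", {
  lib <- generate_library(100, c(70, 600), n_silc = 17, seed = 7)
  m <- lib$monoisotopic_mass
  # exhaustive all-pairs check, ppm relative to the smaller mass
  for (i in 1:(length(m) - 1)) {
    for (j in (i + 1):length(m)) {
      sep <- abs(m[i] - m[j]) / min(m[i], m[j]) * 1e6
      expect_gt(sep, 4)
    }
  }
})

test_that("design row counts follow pools x (1 + conditions) x replicates", {
  expect_equal(nrow(generate_design(3, default_condition_grid(), 1)), 69L)
  expect_equal(nrow(generate_design(1, default_condition_grid()[0, ], 1)), 1L)
  expect_equal(nrow(generate_design(3, default_condition_grid(), 3)), 207L)
  d <- generate_design(3, default_condition_grid(), 1)
  expect_equal(sum(d$is_reference), 3L)
  expect_error(generate_design(0, default_condition_grid(), 1), "pool")
  bad <- data.frame(series = "room", level = c(2, 2), unit = "hours")
  expect_error(generate_design(1, bad, 1), "duplicate levels")
})

test_that("zero-noise simulation gives identical sums across samples", {
  lib <- tiny_library(6, 2)
  des <- generate_design(2, ft_grid(3), replicates = 2)
  pk <- simulate_peak_tables(lib, des, effect_spec(noise_sigma = 0, seed = 5))
  am <- annotate_peaks(pk, lib, des)
  for (met in lib$name) {
    row <- am$intensity[met, ]
    expect_equal(max(row) / min(row), 1, tolerance = 1e-12)
  }
})

test_that("an injected noise-free drift propagates exactly to the fold change", {
  lib <- tiny_library(6, 2)
  target <- lib$name[!lib$is_silc][1]
  des <- generate_design(3, ft_grid(7), replicates = 3)
  drifts <- data.frame(metabolite = target, series = "freeze_thaw",
                       level = 7, fc = 2.0)
  pk <- simulate_peak_tables(lib, des, effect_spec(drifts = drifts,
                                                   noise_sigma = 0, seed = 5))
  am <- annotate_peaks(pk, lib, des)
  rec <- stability_records(am, mav = c(freeze_thaw = 0.05))
  hit <- rec[rec$metabolite == target & rec$level == 7, ]
  expect_equal(hit$center, 2.0, tolerance = 1e-12)
  expect_equal(hit$call, "increased")
  # all other levels of the drifted metabolite stay at fold change 1
  other <- rec[rec$metabolite == target & rec$level != 7, ]
  expect_equal(other$center, rep(1, nrow(other)), tolerance = 1e-12)
})

test_that("replicate noise reproduces the lognormal CV closed form", {
  # one metabolite, 1e4 repeated infusions of one reference preparation
  lib <- metabolite_library("X", 200)
  des <- generate_design(1, ft_grid(1)[0, ], replicates = 10000)
  pk <- simulate_peak_tables(lib, des, effect_spec(noise_sigma = 0.15, seed = 2))
  per_rep <- tapply(pk$intensity, pk$replicate, sum)
  cv <- coefficient_of_variation(as.numeric(per_rep))
  expected <- sqrt(exp(0.15^2) - 1) # 0.15085
  # Monte-Carlo tolerance ~3 standard errors of a lognormal CV at n = 1e4
  expect_equal(cv, expected, tolerance = 0.03)
})

test_that("simulation is bit-identical under a fixed seed", {
  lib <- tiny_library()
  des <- generate_design(2, ft_grid(2), replicates = 2)
  eff <- effect_spec(noise_sigma = 0.1, seed = 77)
  expect_identical(simulate_peak_tables(lib, des, eff),
                   simulate_peak_tables(lib, des, eff))
})

test_that("sILC channels carry no condition effect and cannot be drifted", {
  lib <- tiny_library(6, 2)
  silc <- lib$name[lib$is_silc][1]
  des <- generate_design(3, ft_grid(3), replicates = 1)
  pk <- simulate_peak_tables(lib, des, effect_spec(noise_sigma = 0, seed = 1))
  am <- annotate_peaks(pk, lib, des)
  ref <- am$intensity[silc, "P1_reference"]
  cond_cols <- am$samples$sample_id[am$samples$pool == 1 &
                                      !am$samples$is_reference]
  expect_equal(unname(am$intensity[silc, cond_cols]) / ref,
               rep(1, length(cond_cols)), tolerance = 1e-12)
  bad <- effect_spec(drifts = data.frame(metabolite = silc,
                                         series = "freeze_thaw",
                                         level = 1, fc = 2))
  expect_error(simulate_peak_tables(lib, des, bad), "sILC")
  unknown <- effect_spec(drifts = data.frame(metabolite = "nope",
                                             series = "freeze_thaw",
                                             level = 1, fc = 2))
  expect_error(simulate_peak_tables(lib, des, unknown), "unknown metabolite")
})

test_that("rescaling all baselines leaves downstream fold changes unchanged", {
  lib <- tiny_library(5, 1)
  des <- generate_design(3, ft_grid(2), replicates = 2)
  eff1 <- effect_spec(noise_sigma = 0.08, seed = 13,
                      baseline_range = c(1e4, 1e6))
  eff2 <- effect_spec(noise_sigma = 0.08, seed = 13,
                      baseline_range = c(1e4, 1e6) * 100)
  am1 <- annotate_peaks(simulate_peak_tables(lib, des, eff1), lib, des)
  am2 <- annotate_peaks(simulate_peak_tables(lib, des, eff2), lib, des)
  r1 <- stability_records(am1, mav = 0.05)
  r2 <- stability_records(am2, mav = 0.05)
  expect_equal(r1$center, r2$center, tolerance = 1e-9)
  expect_identical(r1$call, r2$call)
})
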
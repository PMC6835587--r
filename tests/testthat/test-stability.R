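test_that("fold change is the plain intensity ratio with guarded reference", {
  expect_equal(fold_change(10, 10), 1)
  expect_equal(fold_change(30, 10), 3)
  expect_true(is.na(fold_change(5, 0)))
  expect_true(is.na(fold_change(5, NA)))
})

test_that("t-based confidence interval matches hand arithmetic", {
  expect_equal(fc_confidence_interval(c(1.3, 1.3, 1.3)),
               c(center = 1.3, low = 1.3, high = 1.3))
  ci <- fc_confidence_interval(c(0.9, 1.0, 1.1))
  hw <- qt(0.975, df = 2) * sd(c(0.9, 1.0, 1.1)) / sqrt(3) # 4.302653 * 0.1/sqrt(3)
  expect_equal(unname(ci["center"]), 1.0)
  expect_equal(unname(ci["high"] - ci["center"]), hw)
  expect_equal(hw, 0.2484, tolerance = 1e-4)
  # the interval always contains the sample mean
  set.seed(9)
  for (i in 1:25) {
    fcs <- runif(3, 0.5, 2)
    ci <- fc_confidence_interval(fcs)
    expect_lte(ci["low"], mean(fcs))
    expect_gte(ci["high"], mean(fcs))
  }
  # minmax alternative brackets the observations themselves
  mm <- fc_confidence_interval(c(0.9, 1.0, 1.4), method = "minmax")
  expect_equal(unname(mm), c(1.1, 0.9, 1.4))
  expect_true(all(is.na(fc_confidence_interval(c(1.2)))))
})

test_that("classification applies strict band comparisons", {
  expect_equal(classify_call(1.10, 1.40, mav = 0.072), "increased")
  expect_equal(classify_call(0.95, 1.05, mav = 0.072), "unaffected")
  expect_equal(classify_call(0.70, 0.80, mav = 0.188), "decreased")
  # boundary equality is NOT outside the band (strict > / <)
  expect_equal(classify_call(1.072, 1.40, mav = 0.072), "unaffected")
  expect_equal(classify_call(0.60, 0.812, mav = 0.188), "unaffected")
  expect_equal(classify_call(NA, NA, mav = 0.1), "undefined")
})

test_that("count_affected equals an exhaustive tally on random calls", {
  expect_equal(nrow(count_affected(data.frame(series = character(0),
                                              level = numeric(0),
                                              call = character(0),
                                              in_neuro_panel = logical(0)))),
               0L)
  set.seed(31)
  records <- data.frame(
    series = sample(c("freeze_thaw", "room"), 300, replace = TRUE),
    level = 7,
    call = sample(c("increased", "decreased", "unaffected", "undefined"),
                  300, replace = TRUE, prob = c(.2, .2, .5, .1)),
    in_neuro_panel = sample(c(TRUE, FALSE), 300, replace = TRUE)
  )
  got <- count_affected(records)
  for (s in unique(records$series)) {
    rec <- records[records$series == s, ]
    row <- got[got$series == s, ]
    expect_equal(row$n_decreased, sum(rec$call == "decreased"))
    expect_equal(row$n_increased, sum(rec$call == "increased"))
    expect_equal(row$n_affected, row$n_decreased + row$n_increased)
    expect_equal(row$n_undefined, sum(rec$call == "undefined"))
  }
  panel <- count_affected(records, subset = "panel")
  rec_p <- records[records$in_neuro_panel, ]
  expect_equal(sum(panel$n_affected),
               sum(rec_p$call %in% c("increased", "decreased")))
})

test_that("widening the variability band never increases the affected count", {
  lib <- generate_library(60, c(70, 600), n_silc = 5, seed = 14)
  des <- generate_design(3, ft_grid(4), replicates = 3)
  drifters <- lib$name[!lib$is_silc][1:10]
  drifts <- data.frame(metabolite = drifters, series = "freeze_thaw",
                       level = 4, fc = rep(c(1.6, 0.6), 5))
  pk <- simulate_peak_tables(lib, des,
                             effect_spec(drifts = drifts, noise_sigma = 0.07,
                                         seed = 14))
  am <- annotate_peaks(pk, lib, des)
  counts <- vapply(c(0, 0.05, 0.15, 0.4, 1.0), function(mav) {
    rec <- stability_records(am, mav = mav)
    sum(count_affected(rec)$n_affected)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("calls are invariant under global intensity rescaling", {
  lib <- tiny_library(6, 2)
  des <- generate_design(3, ft_grid(3), replicates = 2)
  pk <- simulate_peak_tables(lib, des, effect_spec(noise_sigma = 0.1, seed = 20))
  am1 <- annotate_peaks(pk, lib, des)
  pk2 <- pk
  pk2$intensity <- pk2$intensity * 1e3
  am2 <- annotate_peaks(pk2, lib, des)
  r1 <- stability_records(am1, mav = 0.08)
  r2 <- stability_records(am2, mav = 0.08)
  expect_equal(r1$center, r2$center, tolerance = 1e-12)
  expect_identical(r1$call, r2$call)
})

test_that("the reference compared against itself is never flagged", {
  # a condition generated with drift 1 and zero noise is the reference in
  # disguise: every fold change is exactly 1
  lib <- tiny_library(5, 1)
  des <- generate_design(3, ft_grid(1), replicates = 3)
  pk <- simulate_peak_tables(lib, des, effect_spec(noise_sigma = 0, seed = 2))
  am <- annotate_peaks(pk, lib, des)
  rec <- stability_records(am, mav = c(freeze_thaw = 0.01))
  expect_true(all(rec$call == "unaffected"))
  expect_equal(rec$center, rep(1, nrow(rec)), tolerance = 1e-12)
})

test_that("pools with zero reference are dropped and calls become undefined", {
  lib <- metabolite_library(c("A", "B"), c(150, 300))
  des <- generate_design(3, ft_grid(1), replicates = 1)
  pk <- simulate_peak_tables(lib, des, effect_spec(noise_sigma = 0, seed = 3))
  # remove metabolite A's peaks (all adducts sit in 149-189 m/z) from two
  # pools' references, so A is undetected there
  pk <- pk[!(pk$sample_id %in% c("P1_reference", "P2_reference") &
               pk$mz > 100 & pk$mz < 200), ]
  am <- annotate_peaks(pk, lib, des)
  rec <- suppressMessages(stability_records(am, mav = 0.05))
  expect_equal(rec$call[rec$metabolite == "A"], "undefined")
  expect_equal(rec$n_pools[rec$metabolite == "A"], 1)
  expect_equal(rec$call[rec$metabolite == "B"], "unaffected")
  counts <- count_affected(rec)
  expect_equal(counts$n_undefined, 1)
  expect_equal(counts$n_assessed, 1)
})
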
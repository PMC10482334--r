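test_that("compute_auc handles rectangles, trapezoids and replicates", {
  # constant abundance a over days 3..17: rectangle, 14 * a
  tc <- compute_auc(c(3, 5, 7, 10, 12, 14, 17), rep(250, 7))
  expect_equal(tc$auc, 14 * 250)
  # means (2, 4, 6) at days (0, 2, 4)
  expect_equal(compute_auc(c(0, 2, 4), c(2, 4, 6))$auc, 16)
  # replicate matrix with a missing value skipped in the per-day mean
  m <- rbind(c(1, 3, 5), c(3, NA, 7))
  tc2 <- compute_auc(c(0, 2, 4), m)
  expect_equal(tc2$means, c(2, 3, 6))
  expect_equal(tc2$auc, 5 + 9)
  # unsorted day grid is sorted with its values
  expect_equal(compute_auc(c(4, 0, 2), c(6, 2, 4))$auc, 16)
  # replicate-order invariance
  expect_equal(compute_auc(c(0, 2, 4), m[2:1, ])$auc, tc2$auc)
})

test_that("compute_auc rejects bad trajectories", {
  expect_error(compute_auc(c(3), 1), "at least 2 days")
  expect_error(compute_auc(c(3, 3), c(1, 2)), "distinct")
  m <- rbind(c(1, NA, 5), c(3, NA, 7))
  expect_error(compute_auc(c(0, 2, 4), m), "missing at day 2")
})

test_that("trapezoid AUC matches the interpolation oracle on random data", {
  set.seed(123)
  for (i in 1:200) {
    k <- sample(3:9, 1)
    days <- sort(sample(0:20, k))
    means <- runif(k, 0, 1e6)
    expect_equal(compute_auc(days, means)$auc, oracle_auc(days, means),
                 tolerance = 1e-10)
  }
})

test_that("fold_change implements the signed convention with sentinels", {
  expect_equal(fold_change(3, 2, floor = 0.1), 1.5)
  expect_equal(fold_change(2, 3, floor = 0.1), -1.5)
  expect_equal(fold_change(5, 5, floor = 0.1), 1.0)  # no change
  # detected only under test: infinite increase (and symmetrically)
  expect_identical(fold_change(1e6, 100, floor = 5000), Inf)
  expect_identical(fold_change(100, 1e6, floor = 5000), -Inf)
  # both below the floor: undefined, never regulated
  expect_identical(fold_change(10, 20, floor = 5000), NA_real_)
  expect_error(fold_change(-1, 2), "non-negative")
})

test_that("fold_change is antisymmetric under condition swap", {
  set.seed(5)
  a <- runif(200, 0, 1e5); b <- runif(200, 0, 1e5)
  f1 <- fold_change(a, b, floor = 1000)
  f2 <- fold_change(b, a, floor = 1000)
  fin <- is.finite(f1)
  expect_equal(f1[fin], -f2[fin], tolerance = 1e-12)
  expect_identical(is.na(f1), is.na(f2))
  expect_identical(f1[is.infinite(f1)], -f2[is.infinite(f2)])
})

test_that("max_fold_change picks the largest-magnitude day", {
  days <- c(3, 5, 7, 10)
  base <- c(10, 20, 30, 40) * 1000
  expect_equal(max_fold_change(base, base, days)$signed_fc, 1.0)
  spike <- base; spike[4] <- 2 * base[4]
  mx <- max_fold_change(spike, base, days)
  expect_equal(mx$signed_fc, 2.0)
  expect_equal(mx$day, 10)
  # largest magnitude wins, sign kept: ratios (+1.2, -1.3, +1.1)
  test_m <- c(1.2 * 1e4, 1e4 / 1.3, 1.1 * 1e4)
  ctrl_m <- rep(1e4, 3)
  mx2 <- max_fold_change(test_m, ctrl_m, c(1, 2, 3), floor = 100)
  expect_equal(mx2$signed_fc, -1.3, tolerance = 1e-12)
  expect_equal(mx2$day, 2)
  # brute force over random series
  set.seed(42)
  for (i in 1:50) {
    t_m <- runif(5, 0, 1e5); c_m <- runif(5, 0, 1e5)
    fc <- fold_change(t_m, c_m, floor = 1000)
    got <- max_fold_change(t_m, c_m, 1:5, floor = 1000)
    if (all(is.na(fc))) {
      expect_true(is.na(got$signed_fc))
    } else {
      expect_equal(abs(got$signed_fc), max(abs(fc), na.rm = TRUE))
    }
  }
  # no day with both conditions above the floor: undefined
  expect_true(is.na(max_fold_change(c(1, 2), c(1, 2), c(0, 3),
                                    floor = 10)$signed_fc))
})

test_that("call_regulation combines threshold and OPLS significance", {
  calls <- data.frame(
    feature_id = c("a", "b", "c", "d", "e", "f"),
    signed_fc = c(1.5, 1.15, 1.15, 3.0, Inf, NA)
  )
  # metabolite mode (1.5): boundary inclusive
  met <- call_regulation(calls, 1.5, significant_ids = c("a", "b", "e", "f"))
  expect_identical(met$regulated, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(met$direction[1], "up")
  expect_identical(met$direction[5], "up")      # infinite sentinel passes
  expect_identical(met$regulated[4], FALSE)     # |fc| 3.0 but not significant
  # protein mode (1.1): 1.15 passes when significant
  prot <- call_regulation(calls, 1.1, significant_ids = c("b"))
  expect_identical(prot$regulated, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # down direction
  dn <- call_regulation(data.frame(feature_id = "x", signed_fc = -2), 1.5, "x")
  expect_identical(dn$direction, "down")
  expect_error(call_regulation(calls, 0.9, "a"), ">= 1")
})

test_that("differential_analysis works on a toy table end to end", {
  tab <- toy_table()
  calls <- differential_analysis(tab, significant_ids = c("FA", "FB"),
                                 abundance_floor = 5000)
  # FA: test (10,20,30,40)k vs control (12,22,32,44)k -> auc 150k vs 164k
  fa <- calls[calls$feature_id == "FA", ]
  expect_equal(fa$auc_test, 150000)
  expect_equal(fa$auc_control, 164000)
  expect_equal(fa$signed_fc, -164 / 150, tolerance = 1e-12)
  expect_false(fa$regulated)  # below the 1.5 metabolite threshold
  # FB: test (100,80,60,40)k vs control (90,70,50,30)k -> up-regulation
  fb <- calls[calls$feature_id == "FB", ]
  expect_equal(fb$auc_test, (90 + 70 + 50) * 2 * 1000)
  expect_true(fb$signed_fc > 1)
  # FC sits at the 5000 floor in both conditions: AUC = 30000 = floor * span
  fc <- calls[calls$feature_id == "FC", ]
  expect_true(is.na(fc$signed_fc))
  expect_false(fc$regulated)
  expect_identical(fc$direction, "none")
})

test_that("differential_analysis warns and intersects mismatched day grids", {
  tab <- toy_table()
  sm <- tab$sample_meta
  sm$day[sm$sample_id == "s1"] <- 1  # test grid now (1,2,4,6), control (0,2,4,6)
  tab2 <- feature_table(tab$abundance, sm, tab$feature_meta)
  expect_warning(calls <- differential_analysis(tab2, "FA"), "intersection")
  expect_equal(calls$auc_test[1], compute_auc(c(2, 4, 6), c(20, 30, 40) * 1000)$auc)
})

test_that("planted fold changes are recovered from generator output", {
  d <- study_design(n_features = 600, n_discriminative = 40, n_exclusive = 10,
                    noise_cv = 0.2, seed = 17)
  sim <- generate_dataset(d)
  tab <- impute_missing(sim$table)
  calls <- differential_analysis(tab, significant_ids = character(0))
  disc <- sim$truth$discriminative_ids
  planted <- sim$truth$planted_log2fc[disc]
  got <- calls$signed_fc[match(disc, calls$feature_id)]
  # signed convention: planted log2fc of +1 -> ~ +2, of -1 -> ~ -2
  expect_equal(sign(got), unname(sign(planted)))
  expect_true(median(abs(got)) > 1.8 && median(abs(got)) < 2.2)
  # per-feature empirical log2 ratio within +-0.1 of the planted effect, on average
  emp <- sign(got) * log2(abs(got))
  expect_lt(abs(mean(emp - planted)), 0.1)
  # exclusive features: infinite increase
  excl_fc <- calls$signed_fc[match(sim$truth$exclusive_ids, calls$feature_id)]
  expect_true(all(excl_fc == Inf))
})
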
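# Sample construction: binning, trimming, deduplication, filtering,
# residualization and pair assembly.

test_that("age bins are half-open [k-0.5, k+0.5) over the 0.5-19.5 window", {
  expect_identical(bin_age(0.5), 1L)
  expect_identical(bin_age(1.4999), 1L)
  expect_identical(bin_age(1.5), 2L)
  expect_identical(bin_age(19.4999), 19L)
  expect_identical(bin_age(19.5), NA_integer_)
  expect_identical(bin_age(0.49), NA_integer_)
  expect_identical(bin_age(c(0.5, 7.2, 25)), c(1L, 7L, NA_integer_))
  expect_error(bin_age("seven"), "numeric")
})

test_that("a single gross outlier is removed and clean data almost untouched", {
  set.seed(41)
  tab <- data.frame(family_id = 1:201, twin_order = 1, cohort = "c",
                    region = "r", zygosity = "MZ", sex = "M",
                    birth_year = 1990, exact_age = 7,
                    height_cm = c(rnorm(200, 120, 5), 120 + 50))
  out <- trim_outliers(tab, z_max = 4)
  expect_equal(out$report$n_removed, 1L)
  expect_true(all(out$table$height_cm < 165))
  expect_equal(nrow(out$table), 200L)

  # clean simulated cohort: iterated trimming loses well under 1%
  cohort <- simulate_cohort(generator_config(seed = 42, n_pairs = 5000))
  res <- trim_outliers(cohort, z_max = 3.5)
  expect_lt(res$report$fraction_removed, 0.01)

  empty <- trim_outliers(tab[0, ])
  expect_equal(nrow(empty$table), 0L)
  expect_equal(empty$report$n_removed, 0L)
})

test_that("one record per individual per age group, nearest to the center", {
  tab <- data.frame(family_id = c(1, 1, 2), twin_order = c(1, 1, 1),
                    cohort = "c", region = "r", zygosity = "MZ", sex = "M",
                    birth_year = 1990, exact_age = c(6.9, 7.3, 7.0),
                    height_cm = c(119, 121, 118))
  out <- select_one_per_individual_per_age(tab)
  expect_equal(nrow(out), 2L)
  expect_equal(out$exact_age[out$family_id == 1], 6.9)
  # single-record individuals pass through unchanged
  expect_equal(out[out$family_id == 2, "height_cm"], 118)
  # idempotence: processing a duplicated table gives the single-copy result
  dup <- rbind(tab, tab)
  expect_equal(select_one_per_individual_per_age(dup), out)
  # tie on distance: earliest record order wins, deterministically
  tie <- data.frame(family_id = 1, twin_order = 1, cohort = "c",
                    region = "r", zygosity = "MZ", sex = "M",
                    birth_year = 1990, exact_age = c(6.8, 7.2),
                    height_cm = c(1, 2))
  expect_equal(select_one_per_individual_per_age(tie)$height_cm, 1)
})

test_that("cohorts below the minimum measurement count are dropped", {
  mk <- function(n, coh) tiny_measurements(ceiling(n / 2), seed = n,
                                           cohort = coh)[seq_len(n), ]
  tab <- rbind(mk(49, "small"), mk(50, "boundary"), mk(120, "big"))
  out <- filter_min_cohort(tab, min_n = 50)
  expect_setequal(unique(out$cohort), c("boundary", "big"))
  expect_warning(res <- filter_min_cohort(mk(30, "only"), min_n = 50),
                 "fewer")
  expect_equal(nrow(res), 0L)
})

test_that("residualization matches a direct OLS oracle and centers strata", {
  set.seed(43)
  n <- 400
  tab <- data.frame(family_id = rep(1:(n / 2), each = 2),
                    twin_order = rep(1:2, n / 2),
                    cohort = sample(c("a", "b"), n, replace = TRUE),
                    region = "r", zygosity = "MZ", sex = "M",
                    birth_year = rep(sample(1970:2000, n / 2, TRUE), each = 2),
                    exact_age = 9.5 + runif(n))
  noise <- rnorm(n, 0, 2)
  tab$height_cm <- 2 * (tab$birth_year - 2000) + noise +
    3 * (tab$cohort == "b")
  out <- residualize(tab, mode = "univariate")
  oracle <- residuals(lm(height_cm ~ birth_year + exact_age + cohort,
                         data = transform(tab, cohort = factor(cohort))))
  expect_equal(out$height_cm, unname(oracle), tolerance = 1e-10)
  expect_equal(var(out$height_cm), var(noise), tolerance = 0.3)
  expect_equal(sum(out$height_cm), 0, tolerance = 1e-8)

  # intercept-only design: residuals are height minus the stratum fit
  one <- tab; one$cohort <- "a"; one$birth_year <- 1990
  r1 <- residualize(one, mode = "moderation")
  expect_equal(r1$height_cm, one$height_cm - mean(one$height_cm),
               tolerance = 1e-10)
})

test_that("pair assembly joins co-twins, orders OS male-first, flags errors", {
  base <- data.frame(family_id = c(1, 1, 2, 3, 3, 4, 4),
                     twin_order = c(1, 2, 1, 1, 2, 1, 2),
                     cohort = "c", region = "r",
                     zygosity = c("MZ", "MZ", "DZ", "DZ", "DZ", "MZ", "MZ"),
                     sex = c("M", "M", "F", "F", "M", "M", "F"),
                     birth_year = 1990, exact_age = 7.1,
                     height_cm = c(120, 121, 118, 117, 123, 119, 122))
  pairs <- make_pairs(base)
  expect_equal(nrow(pairs), 2L)            # fam 2 incomplete, fam 4 invalid
  expect_setequal(pairs$family_id, c(1, 3))
  os <- pairs[pairs$family_id == 3, ]
  expect_equal(os$group, "OS")
  expect_equal(os$y1, 123)                  # male first
  errs <- attr(pairs, "data_errors")
  expect_equal(errs$family_id, 4)
  expect_match(errs$reason, "discordant")
  # >2 records in a family-age cell is a structural data error
  bad <- rbind(base, data.frame(family_id = 1, twin_order = 2, cohort = "c",
                                region = "r", zygosity = "MZ", sex = "M",
                                birth_year = 1990, exact_age = 7.2,
                                height_cm = 125))
  expect_error(make_pairs(bad), "family-age")
})

test_that("the preprocessing pipeline is deterministic and monotone", {
  cohort <- simulate_cohort(generator_config(seed = 44, n_pairs = 3000))
  a <- preprocess_measurements(cohort)
  b <- preprocess_measurements(cohort)
  expect_identical(a$pairs, b$pairs)
  counts <- unlist(a$log[c("input", "in_age_window", "after_outlier_trim",
                           "after_dedup", "after_cohort_filter")])
  expect_true(all(diff(counts) <= 0))
  # residualization preserves pair structure and group labels
  expect_true(all(a$pairs$group %in% c("MZM", "MZF", "DZM", "DZF", "OS")))
})
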
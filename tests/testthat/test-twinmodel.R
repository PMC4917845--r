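# ACE sex-limitation likelihood, fitting, nested tests and profile CIs.

test_that("model-implied moments follow the twin covariance algebra", {
  p1 <- sexlim_params(a_m = 1, c_m = 0, e_m = 0)
  expect_equal(expected_moments("MZM", p1)$sigma,
               matrix(c(1, 1, 1, 1), 2))
  expect_equal(expected_moments("DZM", p1)$sigma[1, 2], 0.5)
  p2 <- sexlim_params(a_m = 2, c_m = 0, e_m = 0, a_f = 1, c_f = 0, e_f = 0,
                      r_gos = 0.5)
  expect_equal(expected_moments("OS", p2)$sigma[1, 2], 1.0)
  # OS means come from the DZ means of each sex
  p3 <- sexlim_params(1, 1, 1, mu_mzm = 5, mu_dzm = 6, mu_mzf = 7,
                      mu_dzf = 8)
  expect_equal(expected_moments("OS", p3)$mean, c(6, 8))
})

test_that("the likelihood matches a per-pair oracle and is additive", {
  pairs3 <- data.frame(group = c("MZM", "DZF", "OS"),
                       y1 = c(1.2, -0.5, 0.3), y2 = c(0.9, 0.1, -1.1))
  set.seed(61)
  p <- random_sexlim()
  expect_equal(neg2ll(p, pairs3), oracle_neg2ll(p, pairs3),
               tolerance = 1e-8)
  expect_equal(neg2ll(p, pairs3, method = "perpair"),
               oracle_neg2ll(p, pairs3), tolerance = 1e-8)
  # sufficient-statistic and per-pair paths agree on larger data too
  sim <- simulate_pairs_at_age(c(MZM = 200, DZF = 150, OS = 120), p,
                               seed = 62)
  expect_equal(neg2ll(p, sim), neg2ll(p, sim, method = "perpair"),
               tolerance = 1e-8)
  # additivity: doubling every pair doubles the deviance
  expect_equal(neg2ll(p, rbind(pairs3, pairs3)), 2 * neg2ll(p, pairs3),
               tolerance = 1e-10)
  # singular implied covariance yields +Inf, not an error
  sing <- sexlim_params(a_m = 1, c_m = 0, e_m = 0)
  expect_identical(neg2ll(sing, pairs3[1, , drop = FALSE]), Inf)
})

test_that("Falconer closed forms are exact and clipped for starts", {
  f <- falconer(0.9, 0.5)
  expect_equal(unname(c(f$a2, f$c2, f$e2)), c(0.8, 0.1, 0.1))
  expect_equal(falconer(0.6, 0.6)$a2, 0)
  f2 <- falconer(0.4, 0.5)   # raw a2 negative, clipped for starting values
  expect_equal(unname(f2$clipped["a2"]), 0)
})

test_that("ML recovers generating parameters on large samples", {
  truth <- sexlim_params(a_m = sqrt(0.6 * 40), c_m = sqrt(0.25 * 40),
                         e_m = sqrt(0.15 * 40),
                         a_f = sqrt(0.5 * 36), c_f = sqrt(0.3 * 36),
                         e_f = sqrt(0.2 * 36), r_gos = 0.4,
                         mu_mzm = 140, mu_dzm = 141, mu_mzf = 138,
                         mu_dzf = 139)
  p <- simulate_pairs_at_age(
    c(MZM = 50000, MZF = 50000, DZM = 50000, DZF = 50000, OS = 50000),
    truth, seed = 63)
  f <- fit_ace_sexlim(p)
  expect_true(f$converged)
  expect_lt(abs(f$standardized$m["h2"] - 0.6), 0.015)
  expect_lt(abs(f$standardized$m["c2"] - 0.25), 0.015)
  expect_lt(abs(f$standardized$f["h2"] - 0.5), 0.015)
  expect_lt(abs(f$params$r_gos - 0.4), 0.03)
  expect_lt(abs(f$params$mu_mzm - 140), 0.1)
})

test_that("zero additive variance is reported at the boundary", {
  truth <- sexlim_params(a_m = 0, c_m = 2, e_m = 1,
                         a_f = 0, c_f = 2, e_f = 1)
  p <- simulate_pairs_at_age(
    c(MZM = 4000, MZF = 4000, DZM = 4000, DZF = 4000, OS = 4000),
    truth, seed = 64)
  f <- fit_ace_sexlim(p)
  expect_lt(unname(f$standardized$m["h2"]), 0.05)
  ci <- profile_ci(f, "h2_m")
  expect_equal(unname(ci["lower"]), 0)
})

test_that("the saturated model attains the closed-form ML moments", {
  set.seed(65)
  p <- simulate_pairs_at_age(
    c(MZM = 300, MZF = 300, DZM = 300, DZF = 300, OS = 300),
    random_sexlim(), seed = 66)
  sat <- fit_saturated(p)
  ace <- fit_ace_sexlim(p)
  expect_lte(sat$minus2LL, ace$minus2LL)
  expect_equal(sat$n_free_params, 17L)
  # OS block: plain ML moments (n denominator)
  os <- p[p$group == "OS", ]
  y <- cbind(os$y1, os$y2)
  expect_equal(sat$moments$OS$mean, colMeans(y), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sat$moments$OS$sigma, cov(y) * (nrow(y) - 1) / nrow(y),
               tolerance = 1e-10, ignore_attr = TRUE)
  # exchangeable block: compare against a brute-force 3-parameter optimum
  mz <- p[p$group == "MZM", ]
  nm <- nrow(mz)
  obj <- function(th) {
    mu <- th[1]; v <- exp(th[2]); cv <- tanh(th[3]) * v
    S <- matrix(c(v, cv, cv, v), 2)
    val <- tryCatch(
      -2 * sum(apply(cbind(mz$y1, mz$y2), 1, function(y)
        -log(2 * pi) - 0.5 * log(det(S)) -
          0.5 * mahalanobis(matrix(y, 1), c(mu, mu), S))),
      error = function(e) Inf)
    if (is.finite(val)) val else 1e10
  }
  op <- optim(c(mean(c(mz$y1, mz$y2)), log(var(mz$y1)), 0.5), obj,
              method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(sat$moments$MZM$mean[1], op$par[1], tolerance = 1e-3)
  expect_equal(sat$moments$MZM$sigma[1, 1], exp(op$par[2]),
               tolerance = 1e-3)
  # the saturated -2LL contribution matches the numerically optimized one
  expect_equal(
    acegrowth:::neg2ll_group(pair_suffstats(mz)$MZM, sat$moments$MZM),
    op$value, tolerance = 1e-4)

  tiny <- fit_saturated(p[c(1, 301), ])  # one pair per represented group
  expect_true(length(tiny$unidentifiable_groups) > 0)
})

test_that("submodels respect the nesting chain of deviances", {
  set.seed(67)
  p <- simulate_pairs_at_age(
    c(MZM = 800, MZF = 800, DZM = 800, DZF = 800, OS = 800),
    sexlim_params(a_m = 2.5, c_m = 1.5, e_m = 1, a_f = 2.2, c_f = 1.6,
                  e_f = 1.1, r_gos = 0.45), seed = 68)
  sat <- fit_saturated(p)
  full <- fit_ace_sexlim(p)
  sc <- fit_submodel(p, "scale")
  eq <- fit_submodel(p, "equal_sexes")
  dc <- fit_submodel(p, "drop_C")
  tol <- 1e-6 * abs(full$minus2LL)
  expect_lte(sat$minus2LL, full$minus2LL + tol)
  expect_lte(full$minus2LL, sc$minus2LL + tol)
  expect_lte(sc$minus2LL, eq$minus2LL + tol)
  expect_lte(full$minus2LL, dc$minus2LL + tol)
  expect_equal(c(full$n_free_params, sc$n_free_params, eq$n_free_params,
                 dc$n_free_params), c(11L, 9L, 7L, 9L))
})

test_that("dropping C on C-free data costs little deviance", {
  deltas <- numeric(30)
  for (i in seq_len(30)) {
    truth <- sexlim_params(a_m = 3, c_m = 0, e_m = 2,
                           a_f = 3, c_f = 0, e_f = 2, r_gos = 0.5)
    p <- simulate_pairs_at_age(
      c(MZM = 200, MZF = 200, DZM = 200, DZF = 200, OS = 200),
      truth, seed = 700 + i)
    full <- fit_ace_sexlim(p, n_restarts = 2)
    dc <- fit_submodel(p, "drop_C", n_restarts = 2)
    deltas[i] <- lrt(full, dc)$delta_minus2LL
  }
  expect_true(all(deltas >= 0))
  expect_lt(mean(deltas), 2.5)  # at or below the chi-square(2) mean
})

test_that("equating truly equal sexes yields well-behaved p-values", {
  pvals <- numeric(40)
  truth <- sexlim_params(a_m = 2.5, c_m = 1.5, e_m = 1.2, r_gos = 0.5)
  for (i in seq_len(40)) {
    p <- simulate_pairs_at_age(
      c(MZM = 250, MZF = 250, DZM = 250, DZF = 250, OS = 250),
      truth, seed = 800 + i)
    full <- fit_ace_sexlim(p, n_restarts = 1)
    eq <- fit_submodel(p, "equal_sexes", n_restarts = 1)
    pvals[i] <- lrt(full, eq)$p_value
  }
  # under the null the p-values are uniform: mean near 0.5, few rejections
  expect_gt(mean(pvals), 0.33)
  expect_lt(mean(pvals), 0.67)
  expect_lte(mean(pvals <= 0.05), 0.2)
})

test_that("likelihood-ratio tests compute the chi-square tail correctly", {
  fake <- function(ll, k) structure(list(minus2LL = ll, n_free_params = k),
                                    class = "acefit")
  same <- lrt(fake(100, 11), fake(100, 9))
  expect_equal(same$delta_minus2LL, 0)
  expect_equal(same$p_value, 1)
  crit <- lrt(fake(100, 11), fake(103.84, 10))
  expect_equal(crit$delta_df, 1L)
  expect_equal(crit$p_value, 0.05, tolerance = 1e-3)
  expect_error(lrt(fake(100, 9), fake(99, 11)), "nested")
})

test_that("Bonferroni correction thresholds at alpha/m", {
  d <- bonferroni(c(0.003, 0.002), m = 19, alpha = 0.05)
  expect_equal(d$reject, c(FALSE, TRUE))   # threshold 0.05/19 = 0.00263
  expect_true(bonferroni(0.04, m = 1)$reject)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
})

test_that("profile intervals bracket the estimate and respect bounds", {
  truth <- sexlim_params(a_m = sqrt(0.5 * 30), c_m = sqrt(0.3 * 30),
                         e_m = sqrt(0.2 * 30),
                         a_f = sqrt(0.5 * 30), c_f = sqrt(0.3 * 30),
                         e_f = sqrt(0.2 * 30), r_gos = 0.5)
  p <- simulate_pairs_at_age(
    c(MZM = 2000, MZF = 2000, DZM = 2000, DZF = 2000, OS = 2000),
    truth, seed = 69)
  f <- fit_ace_sexlim(p)
  for (q in c("h2_m", "c2_f", "r_gos")) {
    ci <- profile_ci(f, q)
    est <- attr(ci, "estimate")
    expect_lt(ci["lower"], est)
    expect_gt(ci["upper"], est)
  }
  ci <- profile_ci(f, "h2_m")
  expect_gte(ci["lower"], 0)
  expect_lte(ci["upper"], 1)
})
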
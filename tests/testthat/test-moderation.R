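# Gene-by-age moderation: moments, free-parameter arithmetic, fitting,
# variance curves, and null calibration of group comparisons.

test_that("moderated moments reduce correctly and match hand arithmetic", {
  flat <- moderation_params(a0 = 2, c0 = 1.5, e0 = 1, m_MZ0 = 100,
                            m_DZ0 = 101)
  m5 <- moderated_moments(5, "MZ", flat)
  m15 <- moderated_moments(15, "MZ", flat)
  expect_equal(m5, m15)                      # no age terms: homogeneous
  # hand-computed at one age: x = 12 - 10 = 2
  p <- moderation_params(a0 = 2, a1 = 0.3, a2 = -0.05,
                         c0 = 1, c1 = 0.1, e0 = 0.8,
                         m_MZ0 = 110, m_MZ1 = 5, m_MZ2 = -0.1,
                         m_DZ0 = 111, m_DZ1 = 5, m_DZ2 = -0.1)
  a <- 2 + 0.3 * 2 - 0.05 * 4; cc <- 1 + 0.1 * 2; e <- 0.8
  mz <- moderated_moments(12, "MZ", p)
  expect_equal(mz$var, a^2 + cc^2 + e^2, tolerance = 1e-12)
  expect_equal(mz$cov, a^2 + cc^2, tolerance = 1e-12)
  expect_equal(mz$mean, 110 + 5 * 2 - 0.1 * 4, tolerance = 1e-12)
  dz <- moderated_moments(12, "DZ", p)
  expect_equal(dz$cov, 0.5 * a^2 + cc^2, tolerance = 1e-12)
  # x = 0 gives the intercept-only moments
  expect_equal(moderated_moments(10, "MZ", p)$var, 2^2 + 1 + 0.8^2,
               tolerance = 1e-12)
  expect_error(moderated_moments(8, "OS", p), "same-sex")
})

test_that("free-parameter counts give the published df arithmetic", {
  free_sexes <- count_free_params(list(n_groups = 2))
  equal_sexes <- count_free_params(list(n_groups = 2, equate_groups = TRUE))
  expect_equal(free_sexes - equal_sexes, 15L)
  free_regions <- count_free_params(list(n_groups = 3))
  equal_regions <- count_free_params(list(n_groups = 3,
                                          equate_groups = TRUE))
  expect_equal(free_regions - equal_regions, 30L)
  quad <- count_free_params(list(n_groups = 1, path_degree = 2))
  lin <- count_free_params(list(n_groups = 1, path_degree = 1))
  expect_equal(quad - lin, 3L)
  expect_equal(quad, 15L)
})

test_that("moderation ML recovers an age-increasing genetic variance", {
  truth <- moderation_params(a0 = 5, a1 = 0.35, c0 = 3, c1 = -0.08,
                             e0 = 1.8, m_MZ0 = 140, m_MZ1 = 6,
                             m_MZ2 = -0.2, m_DZ0 = 140.5, m_DZ1 = 6,
                             m_DZ2 = -0.2)
  d <- sim_moderation_pairs(30000, truth, seed = 71)
  f <- fit_moderation(d, grouping = "pooled")
  est <- f$params[[1]]
  expect_true(f$converged)
  expect_equal(unname(est["a0"]), 5, tolerance = 0.15)
  expect_equal(unname(est["a1"]), 0.35, tolerance = 0.05)
  expect_equal(unname(est["c0"]), 3, tolerance = 0.15)
  expect_equal(unname(est["e0"]), 1.8, tolerance = 0.05)
  vc <- variance_curves(est)
  expect_true(all(diff(vc$A_var) > 0))     # increasing A variance
  # constrained fit can never beat the free fit
  f_lin <- fit_moderation(d, grouping = "pooled", path_degree = 1)
  expect_gte(f_lin$minus2LL, f$minus2LL - 1e-4 * abs(f$minus2LL))
  expect_equal(f$n_free_params - f_lin$n_free_params, 3L)
})

test_that("with all age slopes fixed at zero the fit equals the pooled
           homogeneous model", {
  truth <- moderation_params(a0 = 4, c0 = 2.5, e0 = 1.5, m_MZ0 = 120,
                             m_DZ0 = 121)
  d <- sim_moderation_pairs(4000, truth, seed = 72)
  f0 <- fit_moderation(d, grouping = "pooled", path_degree = 0,
                       mean_degree = 0)
  expect_equal(f0$n_free_params, 5L)
  # independent oracle: direct 5-parameter age-pooled ACE optimum
  zyg <- substr(d$group, 1, 2)
  obj <- function(th) {
    a <- th[1]; cc <- th[2]; e <- th[3]
    v <- a^2 + cc^2 + e^2
    cv <- ifelse(zyg == "MZ", a^2 + cc^2, 0.5 * a^2 + cc^2)
    mu <- ifelse(zyg == "MZ", th[4], th[5])
    det <- v^2 - cv^2
    if (any(det <= 0)) return(1e12)
    d1 <- d$y1 - mu; d2 <- d$y2 - mu
    sum(2 * log(2 * pi) + log(det) +
          (v * (d1^2 + d2^2) - 2 * cv * d1 * d2) / det)
  }
  op <- optim(c(3, 3, 2, 120, 120), obj, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(f0$minus2LL, op$value, tolerance = 1e-5 * abs(op$value))
})

test_that("variance curves are non-negative and the A peak is located", {
  p <- moderation_params(a0 = 1, a1 = 0.1, a2 = -0.02, c0 = 1, e0 = 1,
                         m_MZ0 = 0, m_DZ0 = 0)
  vc <- variance_curves(p)
  expect_true(all(vc$A_var >= 0 & vc$C_var >= 0 & vc$E_var >= 0))
  # grid-search oracle for the A-variance peak age
  grid <- seq(1, 19, by = 0.01)
  av <- (1 + 0.1 * (grid - 10) - 0.02 * (grid - 10)^2)^2
  expect_equal(attr(vc, "a_peak_age"), grid[which.max(av)],
               tolerance = 0.01)
  flat <- variance_curves(moderation_params(a0 = 2, c0 = 1, e0 = 1))
  expect_true(all(flat$A_var == flat$A_var[1]))
})

test_that("equating identically distributed groups costs chi-square(15)
           deviance on average", {
  truth <- moderation_params(a0 = 4, a1 = 0.2, c0 = 2.5, e0 = 1.5,
                             m_MZ0 = 120, m_MZ1 = 4, m_DZ0 = 120.5,
                             m_DZ1 = 4)
  nrep <- 40
  deltas <- numeric(nrep)
  for (i in seq_len(nrep)) {
    d1 <- sim_moderation_pairs(700, truth, sex = "M", seed = 9000 + 2 * i)
    d2 <- sim_moderation_pairs(700, truth, sex = "F", seed = 9001 + 2 * i)
    d <- rbind(d1, d2)
    free <- fit_moderation(d, grouping = "sex")
    eq <- fit_moderation(d, grouping = "sex", equate_groups = TRUE)
    deltas[i] <- max(eq$minus2LL - free$minus2LL, 0)
  }
  ddf <- 15
  se <- sqrt(2 * ddf / nrep)
  expect_lt(abs(mean(deltas) - ddf), 3 * se + 0.5)
})
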
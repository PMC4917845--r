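# Independent oracles and small fixture builders used across tests.

# Direct per-pair bivariate-normal -2 log-likelihood, written independently
# of the package's likelihood code: covariance assembled from the paths by
# its own arithmetic, density evaluated with base linear algebra.
oracle_neg2ll <- function(p, pairs) {
  sigma_of <- function(group) {
    vm <- p$a_m^2 + p$c_m^2 + p$e_m^2
    vf <- p$a_f^2 + p$c_f^2 + p$e_f^2
    switch(group,
      MZM = matrix(c(vm, p$a_m^2 + p$c_m^2, p$a_m^2 + p$c_m^2, vm), 2),
      MZF = matrix(c(vf, p$a_f^2 + p$c_f^2, p$a_f^2 + p$c_f^2, vf), 2),
      DZM = matrix(c(vm, 0.5 * p$a_m^2 + p$c_m^2,
                     0.5 * p$a_m^2 + p$c_m^2, vm), 2),
      DZF = matrix(c(vf, 0.5 * p$a_f^2 + p$c_f^2,
                     0.5 * p$a_f^2 + p$c_f^2, vf), 2),
      OS = matrix(c(vm, p$r_gos * p$a_m * p$a_f + p$c_m * p$c_f,
                    p$r_gos * p$a_m * p$a_f + p$c_m * p$c_f, vf), 2))
  }
  mean_of <- function(group) switch(group,
    MZM = c(p$mu_mzm, p$mu_mzm), MZF = c(p$mu_mzf, p$mu_mzf),
    DZM = c(p$mu_dzm, p$mu_dzm), DZF = c(p$mu_dzf, p$mu_dzf),
    OS = c(p$mu_dzm, p$mu_dzf))
  tot <- 0
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$group[i]
    S <- sigma_of(g)
    y <- c(pairs$y1[i], pairs$y2[i])
    md <- stats::mahalanobis(matrix(y, 1), mean_of(g), S)
    ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    tot <- tot + (2 * log(2 * pi) + ld + md)
  }
  tot
}

# Random valid sex-limitation parameter sets for fuzzing the likelihood.
random_sexlim <- function() {
  sexlim_params(
    a_m = runif(1, 0.2, 3), c_m = runif(1, 0.2, 3), e_m = runif(1, 0.3, 2),
    a_f = runif(1, 0.2, 3), c_f = runif(1, 0.2, 3), e_f = runif(1, 0.3, 2),
    r_gos = runif(1, -0.4, 0.9),
    mu_mzm = rnorm(1, 0, 3), mu_dzm = rnorm(1, 0, 3),
    mu_mzf = rnorm(1, 0, 3), mu_dzf = rnorm(1, 0, 3))
}

# Same-sex pairs drawn from the age-moderation model, with moments computed
# by the test's own polynomial arithmetic.
sim_moderation_pairs <- function(n, p, sex = "M", seed = 1,
                                 age_range = c(0.5, 19.5)) {
  set.seed(seed)
  zyg <- sample(c("MZ", "DZ"), n, replace = TRUE)
  age <- runif(n, age_range[1], age_range[2])
  x <- age - 10
  a <- p["a0"] + p["a1"] * x + p["a2"] * x^2
  cc <- p["c0"] + p["c1"] * x + p["c2"] * x^2
  e <- p["e0"] + p["e1"] * x + p["e2"] * x^2
  v <- a^2 + cc^2 + e^2
  cv <- ifelse(zyg == "MZ", a^2 + cc^2, 0.5 * a^2 + cc^2)
  mu <- ifelse(zyg == "MZ",
               p["m_MZ0"] + p["m_MZ1"] * x + p["m_MZ2"] * x^2,
               p["m_DZ0"] + p["m_DZ1"] * x + p["m_DZ2"] * x^2)
  rho <- cv / v
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  data.frame(family_id = seq_len(n), group = paste0(zyg, sex),
             y1 = mu + sqrt(v) * z1, y2 = mu + sqrt(v) * z2,
             exact_age = age, stringsAsFactors = FALSE)
}

# A minimal raw measurement table (one age group unless stated).
tiny_measurements <- function(n_fam = 30, seed = 1, age_group = 7,
                              cohort = "coh1", zygosity = "MZ",
                              sex = "M") {
  set.seed(seed)
  data.frame(
    family_id = rep(seq_len(n_fam), each = 2),
    twin_order = rep(1:2, n_fam),
    cohort = cohort, region = "Europe", zygosity = zygosity,
    sex = sex,
    birth_year = rep(sample(1960:2000, n_fam, replace = TRUE), each = 2),
    exact_age = age_group - 0.5 + runif(2 * n_fam),
    height_cm = rnorm(2 * n_fam, 120, 6),
    stringsAsFactors = FALSE)
}
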
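# Univariate ACE sex-limitation model for paired twin observations.
#
# Five zygosity-sex groups: MZM, MZF, DZM, DZF, OS (opposite-sex DZ,
# male listed first). 11 free parameters: sex-specific paths a, c, e,
# the OS additive-genetic correlation r_gOS, and zygosity-by-sex means.

TWIN_GROUPS <- c("MZM", "MZF", "DZM", "DZF", "OS")

#' Construct the parameter set of the ACE sex-limitation model
#'
#' Paths are on the phenotype (cm) scale; variance components are their
#' squares. \code{r_gos} is the additive-genetic correlation between
#' opposite-sex co-twins (0.5 when genetic effects are not sex-specific).
#' Opposite-sex pairs use the DZ means of their respective sexes.
#'
#' @param a_m,c_m,e_m,a_f,c_f,e_f path coefficients (cm), by sex.
#' @param r_gos opposite-sex additive-genetic correlation, in [-1, 1].
#' @param mu_mzm,mu_dzm,mu_mzf,mu_dzf zygosity-by-sex means (cm).
#' @return An object of class \code{sexlim_params} (a named list).
#' @export
sexlim_params <- function(a_m, c_m, e_m, a_f = a_m, c_f = c_m, e_f = e_m,
                          r_gos = 0.5, mu_mzm = 0, mu_dzm = mu_mzm,
                          mu_mzf = mu_mzm, mu_dzf = mu_mzf) {
  for (nm in c("a_m", "c_m", "e_m", "a_f", "c_f", "e_f")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("invalid path coefficient '", nm, "': must be a single number >= 0",
           call. = FALSE)
  }
  if (!is.numeric(r_gos) || length(r_gos) != 1L || is.na(r_gos) ||
      r_gos < -1 || r_gos > 1)
    stop("invalid correlation 'r_gos': must lie in [-1, 1]", call. = FALSE)
  structure(list(a_m = a_m, c_m = c_m, e_m = e_m,
                 a_f = a_f, c_f = c_f, e_f = e_f, r_gos = r_gos,
                 mu_mzm = mu_mzm, mu_dzm = mu_dzm,
                 mu_mzf = mu_mzf, mu_dzf = mu_dzf),
            class = "sexlim_params")
}

#' Model-implied mean vector and covariance matrix for one twin group
#'
#' The additive genetic deviation correlates 1.0 within MZ pairs, 0.5 within
#' same-sex DZ pairs and \code{r_gos} within opposite-sex pairs; the shared
#' environment correlates 1.0 and the unique environment 0 in all groups.
#'
#' @param group one of "MZM", "MZF", "DZM", "DZF", "OS".
#' @param params a \code{\link{sexlim_params}} object.
#' @return list with \code{mean} (length 2) and \code{sigma} (2 x 2 matrix).
#' @export
expected_moments <- function(group, params) {
  group <- match.arg(group, TWIN_GROUPS)
  p <- params
  vm <- p$a_m^2 + p$c_m^2 + p$e_m^2
  vf <- p$a_f^2 + p$c_f^2 + p$e_f^2
  switch(group,
    MZM = list(mean = c(p$mu_mzm, p$mu_mzm),
               sigma = matrix(c(vm, p$a_m^2 + p$c_m^2,
                                p$a_m^2 + p$c_m^2, vm), 2, 2)),
    MZF = list(mean = c(p$mu_mzf, p$mu_mzf),
               sigma = matrix(c(vf, p$a_f^2 + p$c_f^2,
                                p$a_f^2 + p$c_f^2, vf), 2, 2)),
    DZM = list(mean = c(p$mu_dzm, p$mu_dzm),
               sigma = matrix(c(vm, 0.5 * p$a_m^2 + p$c_m^2,
                                0.5 * p$a_m^2 + p$c_m^2, vm), 2, 2)),
    DZF = list(mean = c(p$mu_dzf, p$mu_dzf),
               sigma = matrix(c(vf, 0.5 * p$a_f^2 + p$c_f^2,
                                0.5 * p$a_f^2 + p$c_f^2, vf), 2, 2)),
    OS  = list(mean = c(p$mu_dzm, p$mu_dzf),
               sigma = matrix(c(vm, p$r_gos * p$a_m * p$a_f + p$c_m * p$c_f,
                                p$r_gos * p$a_m * p$a_f + p$c_m * p$c_f, vf),
                              2, 2)))
}

#' Per-group sufficient statistics of a paired-observation table
#'
#' With complete pairs and a constant group mean/covariance, the bivariate
#' normal likelihood depends on the data only through the per-group count,
#' sample mean vector, and scatter matrix about the sample mean.
#'
#' @param pairs data.frame with columns \code{group}, \code{y1}, \code{y2}.
#' @return named list, one element per group present: \code{n}, \code{mean},
#'   \code{scatter}.
#' @export
pair_suffstats <- function(pairs) {
  stopifnot(all(c("group", "y1", "y2") %in% names(pairs)))
  out <- list()
  for (g in intersect(TWIN_GROUPS, unique(pairs$group))) {
    y <- as.matrix(pairs[pairs$group == g, c("y1", "y2")])
    storage.mode(y) <- "double"
    dimnames(y) <- NULL
    n <- nrow(y)
    m <- colMeans(y)
    d <- sweep(y, 2, m)
    out[[g]] <- list(n = n, mean = m, scatter = crossprod(d))
  }
  out
}

# -2 log-likelihood contribution of one group from its sufficient statistics.
neg2ll_group <- function(st, mom) {
  v1 <- mom$sigma[1, 1]; v2 <- mom$sigma[2, 2]; cv <- mom$sigma[1, 2]
  det <- v1 * v2 - cv * cv
  if (!is.finite(det) || det <= 0 || v1 <= 0 || v2 <= 0) return(Inf)
  S <- st$scatter
  d <- st$mean - mom$mean
  tr <- (v2 * S[1, 1] - 2 * cv * S[1, 2] + v1 * S[2, 2]) / det
  qf <- st$n * (v2 * d[1]^2 - 2 * cv * d[1] * d[2] + v1 * d[2]^2) / det
  st$n * (2 * log(2 * pi) + log(det)) + tr + qf
}

neg2ll_from_stats <- function(stats, moments_by_group) {
  tot <- 0
  for (g in names(stats)) {
    tot <- tot + neg2ll_group(stats[[g]], moments_by_group[[g]])
  }
  tot
}

#' Minus twice the log-likelihood of paired data under the sex-limitation model
#'
#' Sums -2 log of the bivariate-normal density of every pair under its
#' group's model-implied moments. The default path evaluates the exact
#' closed form from per-group sufficient statistics; \code{method =
#' "perpair"} retains the direct per-pair summation for verification. A
#' singular implied covariance yields \code{+Inf} rather than an error.
#'
#' @param params \code{\link{sexlim_params}}.
#' @param pairs paired-observation table (columns \code{group,y1,y2}).
#' @param method "suffstat" (default) or "perpair".
#' @return scalar -2 log-likelihood.
#' @export
neg2ll <- function(params, pairs, method = c("suffstat", "perpair")) {
  method <- match.arg(method)
  moms <- setNames(lapply(TWIN_GROUPS, expected_moments, params = params),
                   TWIN_GROUPS)
  if (method == "suffstat")
    return(neg2ll_from_stats(pair_suffstats(pairs), moms))
  tot <- 0
  for (g in intersect(TWIN_GROUPS, unique(pairs$group))) {
    mom <- moms[[g]]
    v1 <- mom$sigma[1, 1]; v2 <- mom$sigma[2, 2]; cv <- mom$sigma[1, 2]
    det <- v1 * v2 - cv * cv
    if (det <= 0 || v1 <= 0 || v2 <= 0) return(Inf)
    sub <- pairs[pairs$group == g, ]
    d1 <- sub$y1 - mom$mean[1]; d2 <- sub$y2 - mom$mean[2]
    qf <- (v2 * d1^2 - 2 * cv * d1 * d2 + v1 * d2^2) / det
    tot <- tot + sum(2 * log(2 * pi) + log(det) + qf)
  }
  tot
}

#' Closed-form variance-component estimates from twin correlations
#'
#' The classical closed form: a2 = 2(rMZ - rDZ), c2 = 2 rDZ - rMZ,
#' e2 = 1 - rMZ. Raw values are returned alongside versions clipped to
#' [0, 1] (used as optimizer starting values).
#'
#' @param r_mz,r_dz MZ and same-sex DZ intraclass correlations.
#' @return list with \code{a2}, \code{c2}, \code{e2} and \code{clipped}.
#' @export
falconer <- function(r_mz, r_dz) {
  a2 <- 2 * (r_mz - r_dz)
  c2 <- 2 * r_dz - r_mz
  e2 <- 1 - r_mz
  cl <- pmax(pmin(c(a2 = a2, c2 = c2, e2 = e2), 1), 0)
  list(a2 = a2, c2 = c2, e2 = e2, clipped = cl)
}

# ---- generic ML machinery -------------------------------------------------

num_grad <- function(fn, par, eps = 1e-5) {
  g <- numeric(length(par))
  for (i in seq_along(par)) {
    h <- eps * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    g[i] <- (fn(up) - fn(dn)) / (2 * h)
  }
  g
}

# Minimize fn over theta with multiple starts; returns best point with
# convergence diagnostics. parscale stabilizes BFGS across cm-scale means
# and unit-scale transforms.
ml_optim <- function(starts, fn, parscale = NULL, maxit = 1000L) {
  # BFGS aborts on non-finite trial values; cap them so the line search
  # backs off instead
  fn_raw <- fn
  fn <- function(p) {
    v <- tryCatch(fn_raw(p), error = function(e) Inf)
    if (is.finite(v)) v else 1e12
  }
  best <- NULL
  for (s in starts) {
    s <- unname(s)
    ps <- if (is.null(parscale)) pmax(abs(s), 0.1) else unname(parscale)
    opt <- tryCatch(
      stats::optim(s, fn, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-12,
                                  parscale = ps)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    return(list(par = unname(starts[[1]]), value = Inf, converged = FALSE,
                grad_norm = NA_real_))
  ps <- if (is.null(parscale)) pmax(abs(best$par), 0.1) else unname(parscale)
  # polish from the best point until the improvement is negligible
  repeat {
    re <- tryCatch(
      stats::optim(best$par, fn, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-12,
                                  parscale = ps)),
      error = function(e) NULL)
    if (is.null(re) || !is.finite(re$value) ||
        best$value - re$value < 1e-8) break
    best <- re
  }
  g <- num_grad(fn, best$par)
  gn <- sqrt(sum((g * ps)^2))
  # gradient tolerance is relative to the -2LL magnitude: the attainable
  # finite-difference accuracy scales with the objective value
  value <- if (best$value >= 1e12) Inf else best$value
  list(par = best$par, value = value,
       converged = best$convergence == 0 && is.finite(value) &&
         gn <= 1e-5 * max(1, abs(value)),
       grad_norm = gn)
}

# Standardized components per sex from a sexlim_params object.
standardize_params <- function(p) {
  vm <- p$a_m^2 + p$c_m^2 + p$e_m^2
  vf <- p$a_f^2 + p$c_f^2 + p$e_f^2
  list(m = c(h2 = p$a_m^2 / vm, c2 = p$c_m^2 / vm, e2 = p$e_m^2 / vm),
       f = c(h2 = p$a_f^2 / vf, c2 = p$c_f^2 / vf, e2 = p$e_f^2 / vf))
}

# Falconer-based starting parameters from the data.
sexlim_starts <- function(stats) {
  grp_r <- function(g) {
    st <- stats[[g]]
    if (is.null(st) || st$n < 3) return(NA_real_)
    S <- st$scatter / st$n
    cv <- S[1, 2]; v <- sqrt(S[1, 1] * S[2, 2])
    if (v <= 0) return(NA_real_)
    max(min(cv / v, 0.99), -0.99)
  }
  grp_stat <- function(g, fun) {
    st <- stats[[g]]
    if (is.null(st)) return(NA_real_)
    fun(st)
  }
  v_m <- mean(c(grp_stat("MZM", function(s) mean(diag(s$scatter)) / s$n),
                grp_stat("DZM", function(s) mean(diag(s$scatter)) / s$n),
                grp_stat("OS", function(s) s$scatter[1, 1] / s$n)), na.rm = TRUE)
  v_f <- mean(c(grp_stat("MZF", function(s) mean(diag(s$scatter)) / s$n),
                grp_stat("DZF", function(s) mean(diag(s$scatter)) / s$n),
                grp_stat("OS", function(s) s$scatter[2, 2] / s$n)), na.rm = TRUE)
  if (!is.finite(v_m) || v_m <= 0) v_m <- 1
  if (!is.finite(v_f) || v_f <= 0) v_f <- 1
  comp <- function(rmz, rdz) {
    if (is.na(rmz)) rmz <- 0.8
    if (is.na(rdz)) rdz <- 0.5
    cl <- falconer(rmz, rdz)$clipped
    pmin(pmax(cl, 0.05), 0.9)
  }
  cm <- comp(grp_r("MZM"), grp_r("DZM"))
  cf <- comp(grp_r("MZF"), grp_r("DZF"))
  mu <- function(g, idx = NULL) {
    st <- stats[[g]]
    if (is.null(st)) return(0)
    if (is.null(idx)) mean(st$mean) else st$mean[idx]
  }
  list(paths_m = sqrt(cm * v_m), paths_f = sqrt(cf * v_f),
       mu = c(mzm = mu("MZM"),
              dzm = mean(c(mu("DZM"), mu("OS", 1)), na.rm = TRUE),
              mzf = mu("MZF"),
              dzf = mean(c(mu("DZF"), mu("OS", 2)), na.rm = TRUE)))
}

unpack_full <- function(theta) {
  sexlim_params(a_m = abs(theta[1]), c_m = abs(theta[2]), e_m = abs(theta[3]),
                a_f = abs(theta[4]), c_f = abs(theta[5]), e_f = abs(theta[6]),
                r_gos = tanh(theta[7]),
                mu_mzm = theta[8], mu_dzm = theta[9],
                mu_mzf = theta[10], mu_dzf = theta[11])
}

make_fit_result <- function(opt, params, n_free, stats, model,
                            constraint = NULL) {
  std <- standardize_params(params)
  structure(list(model = model, constraint = constraint, params = params,
                 minus2LL = opt$value, n_free_params = n_free,
                 n_pairs = vapply(stats, function(s) s$n, numeric(1)),
                 converged = opt$converged, grad_norm = opt$grad_norm,
                 standardized = std, suffstats = stats),
            class = "acefit")
}

#' @export
print.acefit <- function(x, ...) {
  cat("ACE twin-model fit [", x$model,
      if (!is.null(x$constraint)) paste0(" / ", x$constraint), "]\n", sep = "")
  cat("  -2logL =", format(x$minus2LL, digits = 10),
      " free parameters =", x$n_free_params,
      " converged =", x$converged, "\n")
  if (!is.null(x$standardized)) {
    cat("  males  : h2 =", round(x$standardized$m["h2"], 3),
        " c2 =", round(x$standardized$m["c2"], 3),
        " e2 =", round(x$standardized$m["e2"], 3), "\n")
    cat("  females: h2 =", round(x$standardized$f["h2"], 3),
        " c2 =", round(x$standardized$f["c2"], 3),
        " e2 =", round(x$standardized$f["e2"], 3), "\n")
    if (!is.null(x$params$r_gos))
      cat("  r_gOS  =", round(x$params$r_gos, 3), "\n")
  }
  invisible(x)
}

#' Fit the 11-parameter ACE sex-limitation model by maximum likelihood
#'
#' Minimizes \code{\link{neg2ll}} over sex-specific a/c/e paths, the
#' opposite-sex genetic correlation (bounded in [-1, 1] through a tanh
#' transform) and zygosity-by-sex means, by quasi-Newton iteration from a
#' Falconer-based start plus jittered restarts. Paths are optimized
#' unbounded and reported as absolute values, so variance components need
#' no boundary constraints.
#'
#' @param pairs paired-observation table (\code{group}, \code{y1}, \code{y2}).
#' @param n_restarts additional jittered starts beyond the Falconer start.
#' @param restart_seed seed for the restart jitter (fixed for reproducibility).
#' @return A \code{FitResult} (class \code{acefit}): parameter estimates,
#'   -2 log-likelihood, free-parameter count, per-group pair counts,
#'   convergence flag and standardized components.
#' @export
fit_ace_sexlim <- function(pairs, n_restarts = 4L, restart_seed = 11L) {
  stats <- pair_suffstats(pairs)
  if (length(stats) == 0L) stop("no complete pairs to fit", call. = FALSE)
  st <- sexlim_starts(stats)
  base <- c(st$paths_m, st$paths_f, atanh(0.5),
            st$mu["mzm"], st$mu["dzm"], st$mu["mzf"], st$mu["dzf"])
  starts <- list(base)
  if (n_restarts > 0) {
    jit <- withr_seed(restart_seed, {
      lapply(seq_len(n_restarts), function(i)
        base * c(exp(stats::rnorm(6, 0, 0.25)), 1, rep(1, 4)) +
          c(rep(0, 7), stats::rnorm(4, 0, 0.5)))
    })
    starts <- c(starts, jit)
  }
  fn <- function(theta) neg2ll_from_stats(
    stats, setNames(lapply(TWIN_GROUPS, expected_moments,
                           params = unpack_full(theta)), TWIN_GROUPS))
  ps <- pmax(abs(base), c(rep(0.05, 7), rep(0.5, 4)))
  opt <- ml_optim(starts, fn, parscale = ps)
  make_fit_result(opt, unpack_full(opt$par), 11L, stats, "ACE sex-limitation")
}

# Evaluate a block with a local seed without disturbing the global RNG.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit the saturated model (free means, variances and covariances per group)
#'
#' Means and variances are equated across co-twins within same-sex groups
#' (the within-pair ordering is arbitrary) and sex-specific in the
#' opposite-sex group; every group has a free within-pair covariance:
#' 6 means + 6 variances + 5 covariances = 17 free parameters. Estimates
#' are the closed-form maximum-likelihood moments (n denominator;
#' symmetrized within same-sex groups).
#'
#' @param pairs paired-observation table.
#' @return A \code{FitResult} with element \code{moments} (per-group ML mean
#'   vector and covariance matrix). Groups with fewer than 2 pairs are
#'   flagged unidentifiable.
#' @export
fit_saturated <- function(pairs) {
  stats <- pair_suffstats(pairs)
  if (length(stats) == 0L) stop("no complete pairs to fit", call. = FALSE)
  moments <- list()
  unident <- character(0)
  val <- 0
  for (g in names(stats)) {
    st <- stats[[g]]
    if (st$n < 2) unident <- c(unident, g)
    if (g == "OS") {
      mu <- st$mean
      sig <- st$scatter / st$n
    } else {
      m <- mean(st$mean)
      # scatter about the common mean, symmetrized (exchangeable pair)
      d <- st$mean - m
      S <- st$scatter / st$n + outer(d, d)
      v <- mean(diag(S))
      sig <- matrix(c(v, S[1, 2], S[1, 2], v), 2, 2)
      mu <- c(m, m)
    }
    moments[[g]] <- list(mean = mu, sigma = sig)
    val <- val + neg2ll_group(st, moments[[g]])
  }
  opt <- list(value = val, converged = length(unident) == 0L,
              grad_norm = 0)
  res <- make_fit_result(opt, NULL, 17L, stats, "saturated")
  res$standardized <- NULL
  res$moments <- moments
  res$unidentifiable_groups <- unident
  res
}

#' Fit a constrained submodel of the ACE sex-limitation model
#'
#' \describe{
#'   \item{equal_sexes}{a, c, e equated across sexes and r_gOS fixed at 0.5
#'     (7 free parameters).}
#'   \item{scale}{standardized proportions equated across sexes with a free
#'     female/male total-variance ratio; r_gOS free (9 parameters).}
#'   \item{drop_C}{c_m = c_f = 0 (9 parameters).}
#'   \item{drop_A}{a_m = a_f = 0; r_gOS has no effect and is fixed
#'     (8 parameters).}
#' }
#'
#' @param pairs paired-observation table.
#' @param constraint one of "equal_sexes", "scale", "drop_C", "drop_A".
#' @param n_restarts,restart_seed as in \code{\link{fit_ace_sexlim}}.
#' @return A \code{FitResult}.
#' @export
fit_submodel <- function(pairs,
                         constraint = c("equal_sexes", "scale",
                                        "drop_C", "drop_A"),
                         n_restarts = 4L, restart_seed = 11L) {
  constraint <- match.arg(constraint)
  stats <- pair_suffstats(pairs)
  if (length(stats) == 0L) stop("no complete pairs to fit", call. = FALSE)
  st <- sexlim_starts(stats)
  mus <- unname(c(st$mu["mzm"], st$mu["dzm"], st$mu["mzf"], st$mu["dzf"]))
  spec <- switch(constraint,
    equal_sexes = list(
      base = c((st$paths_m + st$paths_f) / 2, mus),
      n_free = 7L,
      unpack = function(th) sexlim_params(
        a_m = abs(th[1]), c_m = abs(th[2]), e_m = abs(th[3]),
        a_f = abs(th[1]), c_f = abs(th[2]), e_f = abs(th[3]), r_gos = 0.5,
        mu_mzm = th[4], mu_dzm = th[5], mu_mzf = th[6], mu_dzf = th[7])),
    scale = list(
      base = c(st$paths_m,
               log(sum(st$paths_f^2) / sum(st$paths_m^2)) / 2,
               atanh(0.5), mus),
      n_free = 9L,
      unpack = function(th) {
        k <- exp(th[4])  # female/male SD ratio
        sexlim_params(
          a_m = abs(th[1]), c_m = abs(th[2]), e_m = abs(th[3]),
          a_f = abs(th[1]) * k, c_f = abs(th[2]) * k, e_f = abs(th[3]) * k,
          r_gos = tanh(th[5]),
          mu_mzm = th[6], mu_dzm = th[7], mu_mzf = th[8], mu_dzf = th[9])
      }),
    drop_C = list(
      base = c(sqrt(st$paths_m[1]^2 + st$paths_m[2]^2), st$paths_m[3],
               sqrt(st$paths_f[1]^2 + st$paths_f[2]^2), st$paths_f[3],
               atanh(0.5), mus),
      n_free = 9L,
      unpack = function(th) sexlim_params(
        a_m = abs(th[1]), c_m = 0, e_m = abs(th[2]),
        a_f = abs(th[3]), c_f = 0, e_f = abs(th[4]), r_gos = tanh(th[5]),
        mu_mzm = th[6], mu_dzm = th[7], mu_mzf = th[8], mu_dzf = th[9])),
    drop_A = list(
      base = c(sqrt(st$paths_m[1]^2 + st$paths_m[2]^2), st$paths_m[3],
               sqrt(st$paths_f[1]^2 + st$paths_f[2]^2), st$paths_f[3], mus),
      n_free = 8L,
      unpack = function(th) sexlim_params(
        a_m = 0, c_m = abs(th[1]), e_m = abs(th[2]),
        a_f = 0, c_f = abs(th[3]), e_f = abs(th[4]), r_gos = 0.5,
        mu_mzm = th[5], mu_dzm = th[6], mu_mzf = th[7], mu_dzf = th[8])))
  fn <- function(theta) neg2ll_from_stats(
    stats, setNames(lapply(TWIN_GROUPS, expected_moments,
                           params = spec$unpack(theta)), TWIN_GROUPS))
  starts <- list(spec$base)
  if (n_restarts > 0) {
    jit <- withr_seed(restart_seed + 1L, {
      lapply(seq_len(n_restarts), function(i)
        spec$base * exp(stats::rnorm(length(spec$base), 0, 0.15)))
    })
    starts <- c(starts, jit)
  }
  opt <- ml_optim(starts, fn, parscale = pmax(abs(spec$base), 0.05))
  make_fit_result(opt, spec$unpack(opt$par), spec$n_free, stats,
                  "ACE submodel", constraint = constraint)
}

#' Likelihood-ratio test between nested maximum-likelihood fits
#'
#' @param full,nested \code{FitResult}s; \code{nested} must have fewer free
#'   parameters than \code{full}.
#' @return list with \code{delta_minus2LL}, \code{delta_df}, \code{p_value}.
#'   A negative difference beyond numerical tolerance is clamped to 0 with a
#'   warning (it indicates an optimizer artefact).
#' @export
lrt <- function(full, nested) {
  if (!inherits(full, "acefit") || !inherits(nested, "acefit"))
    stop("lrt() expects two fit results", call. = FALSE)
  ddf <- full$n_free_params - nested$n_free_params
  if (ddf < 1) stop("models are not nested: 'nested' must have fewer free ",
                    "parameters than 'full'", call. = FALSE)
  delta <- nested$minus2LL - full$minus2LL
  if (delta < 0) {
    if (delta < -1e-4)
      warning("nested model fit better than full (delta = ",
              format(delta), "); clamping to 0")
    delta <- 0
  }
  list(delta_minus2LL = delta, delta_df = ddf,
       p_value = stats::pchisq(delta, df = ddf, lower.tail = FALSE))
}

#' Bonferroni-corrected decisions for a family of tests
#'
#' @param p_values numeric vector of p-values.
#' @param m number of tests corrected for (>= \code{length(p_values)}).
#' @param alpha family-wise error rate.
#' @return data.frame with \code{p}, \code{threshold} (= alpha/m) and
#'   \code{reject} (p <= alpha/m).
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  if (m < length(p_values))
    stop("m must be at least the number of p-values", call. = FALSE)
  thr <- alpha / m
  data.frame(p = p_values, threshold = thr,
             reject = ifelse(is.na(p_values), NA, p_values <= thr))
}

# ---- profile-likelihood confidence intervals ------------------------------

# Constrained -2LL with one standardized quantity fixed at value q.
# quantity: h2_m, c2_m, e2_m, h2_f, c2_f, e2_f, r_gos.
profile_neg2ll <- function(q, quantity, stats, warm_env) {
  comp_idx <- c(h2 = 1L, c2 = 2L, e2 = 3L)
  if (quantity == "r_gos") {
    unpack <- function(th) sexlim_params(
      a_m = abs(th[1]), c_m = abs(th[2]), e_m = abs(th[3]),
      a_f = abs(th[4]), c_f = abs(th[5]), e_f = abs(th[6]),
      r_gos = q,
      mu_mzm = th[7], mu_dzm = th[8], mu_mzf = th[9], mu_dzf = th[10])
    p0 <- warm_env$params
    base <- c(p0$a_m, p0$c_m, p0$e_m, p0$a_f, p0$c_f, p0$e_f,
              p0$mu_mzm, p0$mu_dzm, p0$mu_mzf, p0$mu_dzf)
  } else {
    sex <- sub("^.*_", "", quantity)
    comp <- comp_idx[[sub("_.*$", "", quantity)]]
    others <- setdiff(1:3, comp)
    # free block: log total variance, logit split of (1-q) over the other
    # two components; the profiled sex's paths are fully determined by them.
    unpack <- function(th) {
      V <- exp(th[1])
      s <- stats::plogis(th[2])
      comps <- numeric(3)
      comps[comp] <- q
      comps[others[1]] <- (1 - q) * s
      comps[others[2]] <- (1 - q) * (1 - s)
      pa <- sqrt(pmax(comps, 0) * V)
      if (sex == "m")
        sexlim_params(a_m = pa[1], c_m = pa[2], e_m = pa[3],
                      a_f = abs(th[3]), c_f = abs(th[4]), e_f = abs(th[5]),
                      r_gos = tanh(th[6]), mu_mzm = th[7], mu_dzm = th[8],
                      mu_mzf = th[9], mu_dzf = th[10])
      else
        sexlim_params(a_m = abs(th[3]), c_m = abs(th[4]), e_m = abs(th[5]),
                      a_f = pa[1], c_f = pa[2], e_f = pa[3],
                      r_gos = tanh(th[6]), mu_mzm = th[7], mu_dzm = th[8],
                      mu_mzf = th[9], mu_dzf = th[10])
    }
    p0 <- warm_env$params
    if (sex == "m") {
      V0 <- p0$a_m^2 + p0$c_m^2 + p0$e_m^2
      comps0 <- c(p0$a_m^2, p0$c_m^2, p0$e_m^2) / V0
      free_paths <- c(p0$a_f, p0$c_f, p0$e_f)
    } else {
      V0 <- p0$a_f^2 + p0$c_f^2 + p0$e_f^2
      comps0 <- c(p0$a_f^2, p0$c_f^2, p0$e_f^2) / V0
      free_paths <- c(p0$a_m, p0$c_m, p0$e_m)
    }
    rest <- comps0[others]
    s0 <- if (sum(rest) > 0) rest[1] / sum(rest) else 0.5
    s0 <- min(max(s0, 1e-4), 1 - 1e-4)
    base <- c(log(V0), stats::qlogis(s0), free_paths,
              atanh(min(max(p0$r_gos, -0.999), 0.999)),
              p0$mu_mzm, p0$mu_dzm, p0$mu_mzf, p0$mu_dzf)
  }
  if (!is.null(warm_env$theta) &&
      length(warm_env$theta) == length(base) &&
      identical(warm_env$quantity, quantity)) {
    starts <- list(warm_env$theta, base)
  } else starts <- list(base)
  fn <- function(theta) neg2ll_from_stats(
    stats, setNames(lapply(TWIN_GROUPS, expected_moments,
                           params = unpack(theta)), TWIN_GROUPS))
  opt <- ml_optim(starts, fn, parscale = pmax(abs(base), 0.05), maxit = 500L)
  warm_env$theta <- opt$par
  warm_env$quantity <- quantity
  opt$value
}

#' Profile-likelihood confidence interval for a standardized quantity
#'
#' The boundary is located where the profiled -2 log-likelihood (nuisance
#' parameters re-optimized at each point) rises above the optimum by the
#' chi-square(1) quantile of the requested level (3.841 at 95%). Intervals
#' for proportions are truncated to [0, 1] and for \code{r_gos} to [-1, 1];
#' if the profile never crosses the threshold before the boundary of the
#' parameter space, the interval is closed at that boundary.
#'
#' @param fit a converged \code{FitResult} from \code{\link{fit_ace_sexlim}}.
#' @param quantity one of "h2_m", "c2_m", "e2_m", "h2_f", "c2_f", "e2_f",
#'   "r_gos".
#' @param level confidence level.
#' @return numeric vector \code{c(lower, upper)} with attribute
#'   \code{estimate}.
#' @export
profile_ci <- function(fit, quantity = c("h2_m", "c2_m", "e2_m",
                                         "h2_f", "c2_f", "e2_f", "r_gos"),
                       level = 0.95) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(fit, "acefit"), !is.null(fit$suffstats))
  stats <- fit$suffstats
  if (quantity == "r_gos") {
    est <- fit$params$r_gos
    lo_bound <- -1; hi_bound <- 1
  } else {
    sex <- sub("^.*_", "", quantity)
    comp <- sub("_.*$", "", quantity)
    est <- unname(fit$standardized[[sex]][comp])
    lo_bound <- 0; hi_bound <- 1
  }
  target <- fit$minus2LL + stats::qchisq(level, df = 1)
  warm <- new.env(parent = emptyenv())
  warm$params <- fit$params
  g <- function(q) profile_neg2ll(q, quantity, stats, warm) - target
  find_limit <- function(dir) {
    step <- 0.02
    q_in <- est
    repeat {
      q_out <- q_in + dir * step
      if (dir < 0 && q_out <= lo_bound) q_out <- lo_bound
      if (dir > 0 && q_out >= hi_bound) q_out <- hi_bound
      gv <- g(q_out)
      if (is.finite(gv) && gv > 0) {
        root <- stats::uniroot(g, lower = min(q_in, q_out),
                               upper = max(q_in, q_out), tol = 1e-4)
        return(root$root)
      }
      if (q_out <= lo_bound && dir < 0) return(lo_bound)
      if (q_out >= hi_bound && dir > 0) return(hi_bound)
      q_in <- q_out
      step <- step * 1.7
    }
  }
  lower <- if (est <= lo_bound + 1e-10) lo_bound else find_limit(-1)
  upper <- if (est >= hi_bound - 1e-10) hi_bound else find_limit(+1)
  structure(c(lower = lower, upper = upper), estimate = est, level = level)
}
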
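# Gene-by-age interaction model: a/c/e path coefficients and zygosity-
# specific means are polynomials (up to quadratic) in age, fitted to
# same-sex pairs by per-pair maximum likelihood (ages vary continuously, so
# no sufficient-statistic shortcut exists).

MOD_AGE_CENTER <- 10  # years; centering for numerical conditioning

MOD_PAR_NAMES <- c("a0", "a1", "a2", "c0", "c1", "c2", "e0", "e1", "e2",
                   "m_MZ0", "m_MZ1", "m_MZ2", "m_DZ0", "m_DZ1", "m_DZ2")

#' Construct one group's moderation parameter block
#'
#' 15 parameters: path coefficients a0..a2, c0..c2, e0..e2 (cm, cm/yr,
#' cm/yr^2 on age centered at 10 years) and zygosity-specific quadratic
#' mean coefficients m_MZ0..2, m_DZ0..2 (cm scale).
#'
#' @param ... named values for any of the 15 coefficients (others 0).
#' @return named numeric vector of class \code{moderation_params}.
#' @export
moderation_params <- function(...) {
  vals <- list(...)
  p <- setNames(numeric(15), MOD_PAR_NAMES)
  if (length(vals)) {
    bad <- setdiff(names(vals), MOD_PAR_NAMES)
    if (length(bad)) stop("unknown moderation parameter(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    p[names(vals)] <- unlist(vals)
  }
  structure(p, class = "moderation_params")
}

poly_eval <- function(x, p0, p1, p2) p0 + p1 * x + p2 * x^2

#' Model-implied moments of a same-sex pair at a given age
#'
#' Path value p(x) = p0 + p1 x + p2 x^2 at x = age - 10; the pair variance
#' is a(x)^2 + c(x)^2 + e(x)^2 and the within-pair covariance
#' a(x)^2 + c(x)^2 (MZ) or 0.5 a(x)^2 + c(x)^2 (DZ). Means are the
#' zygosity-specific quadratic. Opposite-sex pairs are not part of the
#' moderation analysis and are rejected.
#'
#' @param age exact age in years (vectorized).
#' @param zygosity "MZ" or "DZ".
#' @param params a \code{\link{moderation_params}} block.
#' @return list with \code{mean} (per age), \code{var}, \code{cov}.
#' @export
moderated_moments <- function(age, zygosity, params) {
  if (!all(zygosity %in% c("MZ", "DZ")))
    stop("moderation model covers same-sex MZ/DZ pairs only ",
         "(opposite-sex pairs are excluded)", call. = FALSE)
  p <- params
  x <- age - MOD_AGE_CENTER
  a <- poly_eval(x, p["a0"], p["a1"], p["a2"])
  c_ <- poly_eval(x, p["c0"], p["c1"], p["c2"])
  e <- poly_eval(x, p["e0"], p["e1"], p["e2"])
  v <- a^2 + c_^2 + e^2
  cv <- ifelse(zygosity == "MZ", a^2 + c_^2, 0.5 * a^2 + c_^2)
  mu <- ifelse(zygosity == "MZ",
               poly_eval(x, p["m_MZ0"], p["m_MZ1"], p["m_MZ2"]),
               poly_eval(x, p["m_DZ0"], p["m_DZ1"], p["m_DZ2"]))
  list(mean = unname(mu), var = unname(v), cov = unname(cv))
}

# Vectorized per-pair -2 log-likelihood of one group under one block.
mod_neg2ll_block <- function(p, dat) {
  mom <- moderated_moments(dat$exact_age, dat$zyg, p)
  det <- mom$var^2 - mom$cov^2
  if (any(!is.finite(det)) || any(det <= 0) || any(mom$var <= 0)) return(Inf)
  d1 <- dat$y1 - mom$mean
  d2 <- dat$y2 - mom$mean
  qf <- (mom$var * (d1^2 + d2^2) - 2 * mom$cov * d1 * d2) / det
  sum(2 * log(2 * pi) + log(det) + qf)
}

#' Free-parameter count of a moderation model specification
#'
#' A block has 3 path polynomials of degree \code{path_degree} and 2 mean
#' polynomials of degree \code{mean_degree}; groups either share one block
#' (\code{equate_groups = TRUE}) or have one block each. Differences of
#' these counts between nested specifications give the degrees of freedom
#' of their likelihood-ratio tests: e.g. equating two sexes with the full
#' quadratic block costs 15 df, equating three regions costs 30, and
#' dropping the quadratic path terms within one group costs 3.
#'
#' @param model_spec list with \code{n_groups}, \code{equate_groups}
#'   (default FALSE), \code{path_degree} (default 2), \code{mean_degree}
#'   (default 2).
#' @return integer free-parameter count.
#' @export
count_free_params <- function(model_spec) {
  n_groups <- model_spec$n_groups
  equate <- isTRUE(model_spec$equate_groups)
  pd <- if (is.null(model_spec$path_degree)) 2L else model_spec$path_degree
  md <- if (is.null(model_spec$mean_degree)) 2L else model_spec$mean_degree
  stopifnot(n_groups >= 1, pd %in% 0:2, md %in% 0:2)
  blocks <- if (equate) 1L else as.integer(n_groups)
  blocks * (3L * (pd + 1L) + 2L * (md + 1L))
}

# Mask of free coefficients for given polynomial degrees.
mod_free_mask <- function(path_degree, mean_degree) {
  keep_poly <- function(deg) c(TRUE, deg >= 1, deg >= 2)
  c(rep(keep_poly(path_degree), 3), rep(keep_poly(mean_degree), 2))
}

# Starting block from one group's data.
mod_start_block <- function(dat, path_degree, mean_degree) {
  x <- dat$exact_age - MOD_AGE_CENTER
  ymean <- (dat$y1 + dat$y2) / 2
  p <- setNames(numeric(15), MOD_PAR_NAMES)
  for (z in c("MZ", "DZ")) {
    ii <- dat$zyg == z
    pref <- paste0("m_", z)
    if (sum(ii) >= 6) {
      cf <- stats::coef(stats::lm(c(dat$y1[ii], dat$y2[ii]) ~
                                    poly(rep(x[ii], 2), 2, raw = TRUE)))
      cf[is.na(cf)] <- 0
      p[paste0(pref, 0:2)] <- cf
    } else if (any(ii)) {
      p[paste0(pref, 0)] <- mean(ymean[ii])
    }
  }
  ctr <- function(y, mu) y - mu
  mu_hat <- ifelse(dat$zyg == "MZ",
                   poly_eval(x, p["m_MZ0"], p["m_MZ1"], p["m_MZ2"]),
                   poly_eval(x, p["m_DZ0"], p["m_DZ1"], p["m_DZ2"]))
  r1 <- dat$y1 - mu_hat; r2 <- dat$y2 - mu_hat
  V <- stats::var(c(r1, r2))
  rz <- function(z) {
    ii <- dat$zyg == z
    if (sum(ii) < 3) return(NA_real_)
    stats::cor(c(r1[ii], r2[ii]), c(r2[ii], r1[ii]))
  }
  fc <- falconer(if (is.na(rz("MZ"))) 0.8 else rz("MZ"),
                 if (is.na(rz("DZ"))) 0.5 else rz("DZ"))$clipped
  fc <- pmin(pmax(fc, 0.05), 0.9)
  p[c("a0", "c0", "e0")] <- sqrt(fc * V)
  p
}

#' Fit the gene-by-age moderation model by maximum likelihood
#'
#' Joint per-pair ML over one or more groups of same-sex pairs (e.g. the
#' two sexes, or sex-by-region cells). Each group has a 15-parameter block
#' (9 path + 6 mean coefficients); blocks can be equated across groups and
#' polynomial degrees reduced, giving the nested model family whose
#' likelihood-ratio tests compare sexes, regions and the need for quadratic
#' terms.
#'
#' @param pairs paired-observation table (same-sex groups; opposite-sex
#'   pairs are dropped). Must carry \code{exact_age}.
#' @param grouping "sex" (default), "pooled", or "sex_region".
#' @param equate_groups fit one shared block for all groups.
#' @param path_degree,mean_degree polynomial degrees (0--2) of the path and
#'   mean coefficients.
#' @param maxit BFGS iteration cap.
#' @return A \code{FitResult} (class \code{acefit}) whose \code{params} is a
#'   named list of \code{moderation_params} blocks, one per group (shared
#'   blocks are repeated under each group name).
#' @export
fit_moderation <- function(pairs, grouping = c("sex", "pooled", "sex_region"),
                           equate_groups = FALSE, path_degree = 2L,
                           mean_degree = 2L, maxit = 2000L) {
  grouping <- match.arg(grouping)
  ss <- pairs[pairs$group %in% c("MZM", "MZF", "DZM", "DZF"), ]
  if (nrow(ss) == 0L) stop("no same-sex pairs to fit", call. = FALSE)
  if (is.null(ss$exact_age) || any(is.na(ss$exact_age)))
    stop("moderation fit requires an 'exact_age' column", call. = FALSE)
  ss$zyg <- substr(ss$group, 1, 2)
  ss$sex <- substr(ss$group, 3, 3)
  gkey <- switch(grouping,
                 pooled = rep("all", nrow(ss)),
                 sex = ss$sex,
                 sex_region = paste(ss$sex, ss$region, sep = ":"))
  datasets <- split(ss[c("y1", "y2", "exact_age", "zyg")], gkey)
  n_groups <- length(datasets)
  mask <- mod_free_mask(path_degree, mean_degree)
  blocks <- if (equate_groups) 1L else n_groups
  start_blocks <- lapply(datasets, mod_start_block,
                         path_degree = path_degree,
                         mean_degree = mean_degree)
  base_full <- if (equate_groups) {
    list(Reduce(`+`, start_blocks) / n_groups)
  } else start_blocks
  theta0 <- unlist(lapply(base_full, function(b) b[mask]))
  nb <- sum(mask)
  unpack <- function(theta) {
    lapply(seq_len(blocks), function(i) {
      p <- setNames(numeric(15), MOD_PAR_NAMES)
      p[mask] <- theta[((i - 1) * nb + 1):(i * nb)]
      p
    })
  }
  fn <- function(theta) {
    bl <- unpack(theta)
    tot <- 0
    for (i in seq_len(n_groups)) {
      b <- if (equate_groups) bl[[1]] else bl[[i]]
      tot <- tot + mod_neg2ll_block(b, datasets[[i]])
      if (!is.finite(tot)) return(Inf)
    }
    tot
  }
  parscale <- unlist(lapply(base_full, function(b) {
    anchors <- pmax(abs(b[c("a0", "a0", "a0", "c0", "c0", "c0",
                            "e0", "e0", "e0", "m_MZ0", "m_MZ0", "m_MZ0",
                            "m_DZ0", "m_DZ0", "m_DZ0")]), 1)
    (rep(c(1, 0.15, 0.03), 5) * anchors)[mask]
  }))
  parscale <- pmax(parscale, 0.02)
  opt <- ml_optim(list(theta0), fn, parscale = parscale, maxit = maxit)
  bl <- unpack(opt$par)
  params <- if (equate_groups)
    setNames(rep(list(structure(bl[[1]], class = "moderation_params")),
                 n_groups), names(datasets))
  else setNames(lapply(bl, structure, class = "moderation_params"),
                names(datasets))
  n_free <- count_free_params(list(n_groups = n_groups,
                                   equate_groups = equate_groups,
                                   path_degree = path_degree,
                                   mean_degree = mean_degree))
  res <- make_fit_result(
    list(value = opt$value, converged = opt$converged,
         grad_norm = opt$grad_norm),
    NULL, n_free,
    lapply(datasets, function(d) list(n = nrow(d))), "moderation")
  res$standardized <- NULL
  res$params <- params
  res$grouping <- grouping
  res$spec <- list(n_groups = n_groups, equate_groups = equate_groups,
                   path_degree = path_degree, mean_degree = mean_degree)
  res
}

#' Raw variance curves implied by a moderation parameter block
#'
#' Tabulates A, C and E variances (squared path polynomials) over the
#' requested ages and locates the age at which the additive genetic
#' variance peaks (numerically, fine grid plus local refinement, within the
#' age range).
#'
#' @param params a \code{\link{moderation_params}} block.
#' @param ages ages at which to tabulate (default 1..19).
#' @return data.frame (age, A_var, C_var, E_var) with attribute
#'   \code{a_peak_age}.
#' @export
variance_curves <- function(params, ages = 1:19) {
  p <- params
  x <- ages - MOD_AGE_CENTER
  out <- data.frame(
    age = ages,
    A_var = poly_eval(x, p["a0"], p["a1"], p["a2"])^2,
    C_var = poly_eval(x, p["c0"], p["c1"], p["c2"])^2,
    E_var = poly_eval(x, p["e0"], p["e1"], p["e2"])^2)
  rownames(out) <- NULL
  grid <- seq(min(ages), max(ages), by = 0.01)
  av <- poly_eval(grid - MOD_AGE_CENTER, p["a0"], p["a1"], p["a2"])^2
  peak <- grid[which.max(av)]
  lo <- max(min(ages), peak - 0.01); hi <- min(max(ages), peak + 0.01)
  if (hi > lo) {
    op <- stats::optimize(function(g)
      -poly_eval(g - MOD_AGE_CENTER, p["a0"], p["a1"], p["a2"])^2,
      interval = c(lo, hi))
    peak <- op$minimum
  }
  attr(out, "a_peak_age") <- peak
  out
}
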
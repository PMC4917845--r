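# Synthetic twin-cohort height data with known ACE structure.

#' Configuration of the synthetic twin-cohort generator
#'
#' Defaults emulate the structure of large pooled twin-cohort height data:
#' three geographic-cultural regions weighted by their observed share of
#' paired measurements, 1--19 one-year age groups with region-specific mean
#' growth curves and total variances (\code{\link{growth_reference}}),
#' zygosity mix 39\% MZ / 34\% same-sex DZ / 27\% opposite-sex DZ, and
#' age- and sex-specific standardized ACE components
#' (\code{\link{default_components}}).
#'
#' @param seed integer RNG seed.
#' @param n_pairs number of twin pairs (families) to simulate.
#' @param regions character vector of region names (subset of the reference
#'   table's regions).
#' @param region_weights sampling weights for the regions (default: observed
#'   paired-measurement shares 131856 / 29856 / 17924).
#' @param cohorts_per_region integer vector, cohorts per region (default
#'   20, 15, 6). Cohort sizes are heavy-tailed (weights proportional to 1/i).
#' @param zygosity_probs probabilities c(MZ, SSDZ, OSDZ); must be
#'   non-negative and sum to 1.
#' @param sex_ratio probability that an MZ or same-sex-DZ pair is male.
#' @param mean_curve data.frame (region, sex, age, mean_cm, sd_cm) giving the
#'   growth-curve means and total SDs; defaults to the reference table.
#'   Means are interpolated linearly in exact age between integer ages.
#' @param components data.frame (sex, age, h2, c2, e2) of generating
#'   standardized components; path coefficients are
#'   \code{sqrt(component * sd_cm^2)}.
#' @param r_gos additive-genetic correlation within opposite-sex pairs
#'   (0.5 when genetic effects are not sex-specific).
#' @param dz_mean_shift cm added to DZ (and OS) means.
#' @param cohort_effect_sd SD (cm) of cohort-level mean shifts.
#' @param birth_year_range integer range of birth years.
#' @param birth_year_slope secular trend, cm per birth year (applied around
#'   the mid-range year).
#' @param repeat_prob probability that a pair is measured in more than one
#'   age group (extra age groups are geometric, giving a mean close to the
#'   observed ~2.1 measurements per pair at the default 0.5).
#' @param repeat_e_corr correlation of the unique-environment deviation of
#'   the same individual across age groups (unknown in real data; exposed as
#'   a parameter, default 0).
#' @param missing_cotwin_prob probability that one co-twin's measurement is
#'   missing.
#' @param measurement_error_sd SD (cm) of additive measurement noise;
#'   0 (default) folds measurement error into e.
#' @param assortative_r spousal phenotype correlation; when positive, the
#'   shared parental midpoint raises the DZ/OS genetic correlation by
#'   (approximately) r/2 * h2 on the standardized A scale. Off by default;
#'   intended for robustness experiments only.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(seed = 1L,
                             n_pairs = 20000L,
                             regions = c("Europe",
                                         "North-America and Australia",
                                         "East-Asia"),
                             region_weights = NULL,
                             cohorts_per_region = NULL,
                             zygosity_probs = c(MZ = 0.39, SSDZ = 0.34,
                                                OSDZ = 0.27),
                             sex_ratio = 0.5,
                             mean_curve = growth_reference(),
                             components = default_components(),
                             r_gos = 0.5,
                             dz_mean_shift = 0,
                             cohort_effect_sd = 0.5,
                             birth_year_range = c(1950L, 2005L),
                             birth_year_slope = 0.02,
                             repeat_prob = 0.5,
                             repeat_e_corr = 0,
                             missing_cotwin_prob = 0,
                             measurement_error_sd = 0,
                             assortative_r = 0) {
  if (length(regions) < 1L)
    stop("invalid 'regions': at least one region is required", call. = FALSE)
  if (is.null(region_weights)) {
    default_w <- c("Europe" = 131856, "North-America and Australia" = 29856,
                   "East-Asia" = 17924)
    region_weights <- if (all(regions %in% names(default_w)))
      unname(default_w[regions]) else rep(1, length(regions))
  }
  if (is.null(cohorts_per_region)) {
    default_k <- c("Europe" = 20L, "North-America and Australia" = 15L,
                   "East-Asia" = 6L)
    cohorts_per_region <- if (all(regions %in% names(default_k)))
      unname(default_k[regions]) else rep(5L, length(regions))
  }
  if (any(zygosity_probs < 0) || abs(sum(zygosity_probs) - 1) > 1e-8)
    stop("invalid 'zygosity_probs': must be non-negative and sum to 1",
         call. = FALSE)
  if (r_gos < -1 || r_gos > 1)
    stop("invalid 'r_gos': must lie in [-1, 1]", call. = FALSE)
  for (nm in c("cohort_effect_sd", "measurement_error_sd"))
    if (get(nm) < 0) stop("invalid '", nm, "': must be >= 0", call. = FALSE)
  for (nm in c("repeat_prob", "missing_cotwin_prob", "sex_ratio"))
    if (get(nm) < 0 || get(nm) > 1)
      stop("invalid '", nm, "': must be a probability", call. = FALSE)
  need <- expand.grid(region = regions, sex = c("M", "F"), age = 1:19,
                      stringsAsFactors = FALSE)
  key <- paste(mean_curve$region, mean_curve$sex, mean_curve$age)
  if (!all(paste(need$region, need$sex, need$age) %in% key))
    stop("invalid 'mean_curve': must cover every (age 1-19, sex, region) ",
         "requested", call. = FALSE)
  if (any(c(components$h2, components$c2, components$e2) < 0))
    stop("invalid 'components': proportions must be >= 0", call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_pairs = as.integer(n_pairs),
    regions = regions, region_weights = region_weights,
    cohorts_per_region = as.integer(cohorts_per_region),
    zygosity_probs = zygosity_probs, sex_ratio = sex_ratio,
    mean_curve = mean_curve, components = components, r_gos = r_gos,
    dz_mean_shift = dz_mean_shift, cohort_effect_sd = cohort_effect_sd,
    birth_year_range = as.integer(birth_year_range),
    birth_year_slope = birth_year_slope, repeat_prob = repeat_prob,
    repeat_e_corr = repeat_e_corr,
    missing_cotwin_prob = missing_cotwin_prob,
    measurement_error_sd = measurement_error_sd,
    assortative_r = assortative_r), class = "generator_config")
}

# Correlated standard-normal pair: z2 = rho*z1 + sqrt(1-rho^2)*eps.
corr_pair <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(pmax(1 - rho^2, 0)) * stats::rnorm(n)
  cbind(z1, z2)
}

#' Simulate twin pairs of one age group directly from model parameters
#'
#' Latent-variable simulation: standard-normal A, C, E deviations are drawn
#' with within-pair correlations (A: 1.0 MZ, 0.5 same-sex DZ, \code{r_gos}
#' OS; C: 1.0; E: 0), and each phenotype is
#' mean + a*A + c*C + e*E with sex-specific paths.
#'
#' @param n_per_group named counts for MZM, MZF, DZM, DZF, OS (missing
#'   groups default to 0).
#' @param truth a \code{\link{sexlim_params}} object (generating values).
#' @param seed RNG seed.
#' @return data.frame with columns \code{family_id}, \code{group},
#'   \code{zygosity}, \code{sex1}, \code{sex2}, \code{y1}, \code{y2}.
#' @export
simulate_pairs_at_age <- function(n_per_group, truth, seed = 1L) {
  if (!inherits(truth, "sexlim_params"))
    truth <- do.call(sexlim_params, as.list(truth))
  n <- setNames(rep(0L, 5L), TWIN_GROUPS)
  n[names(n_per_group)] <- as.integer(n_per_group)
  if (any(n < 0)) stop("invalid 'n_per_group': counts must be >= 0",
                       call. = FALSE)
  set.seed(seed)
  sex_of <- list(MZM = c("M", "M"), MZF = c("F", "F"), DZM = c("M", "M"),
                 DZF = c("F", "F"), OS = c("M", "F"))
  rho_a <- c(MZM = 1, MZF = 1, DZM = 0.5, DZF = 0.5, OS = truth$r_gos)
  paths <- list(M = c(truth$a_m, truth$c_m, truth$e_m),
                F = c(truth$a_f, truth$c_f, truth$e_f))
  mu <- list(MZM = c(truth$mu_mzm, truth$mu_mzm),
             MZF = c(truth$mu_mzf, truth$mu_mzf),
             DZM = c(truth$mu_dzm, truth$mu_dzm),
             DZF = c(truth$mu_dzf, truth$mu_dzf),
             OS = c(truth$mu_dzm, truth$mu_dzf))
  out <- list()
  fid0 <- 0L
  for (g in TWIN_GROUPS) {
    ng <- n[[g]]
    if (ng == 0L) next
    A <- corr_pair(ng, rho_a[[g]])
    C <- stats::rnorm(ng)
    E <- matrix(stats::rnorm(2L * ng), ncol = 2)
    sx <- sex_of[[g]]
    p1 <- paths[[sx[1]]]; p2 <- paths[[sx[2]]]
    y1 <- mu[[g]][1] + p1[1] * A[, 1] + p1[2] * C + p1[3] * E[, 1]
    y2 <- mu[[g]][2] + p2[1] * A[, 2] + p2[2] * C + p2[3] * E[, 2]
    out[[g]] <- data.frame(
      family_id = fid0 + seq_len(ng), group = g,
      zygosity = if (g %in% c("MZM", "MZF")) "MZ" else "DZ",
      sex1 = sx[1], sex2 = sx[2], y1 = y1, y2 = y2,
      stringsAsFactors = FALSE)
    fid0 <- fid0 + ng
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Linear interpolation of the region/sex growth curve at exact ages.
interp_curve <- function(curve, region, sex, exact_age, col) {
  sub <- curve[curve$region == region & curve$sex == sex, ]
  sub <- sub[order(sub$age), ]
  stats::approx(sub$age, sub[[col]], xout = exact_age, rule = 2)$y
}

#' Simulate a full multi-region twin-cohort measurement table
#'
#' One row per measurement of one twin. Families are assigned a region,
#' cohort, zygosity and sexes; each pair is measured in one or more age
#' groups (geometric number of extra groups with success probability
#' \code{repeat_prob}), at an exact age uniform within the one-year bin.
#' Heights combine the interpolated growth-curve mean, a DZ mean shift, a
#' cohort effect, a secular birth-year trend, and the latent A/C/E
#' deviations scaled by the age- and sex-specific paths. A and C latents
#' persist across a pair's repeated measurements; E is redrawn per age
#' group with correlation \code{repeat_e_corr}. Deterministic given the
#' config (the seed lives in the config).
#'
#' @param config a \code{\link{generator_config}}.
#' @return data.frame with columns \code{family_id}, \code{twin_order},
#'   \code{cohort}, \code{region}, \code{zygosity}, \code{sex},
#'   \code{birth_year}, \code{exact_age}, \code{height_cm}, plus generating
#'   truth columns \code{true_group} and \code{age_group}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cf <- config
  set.seed(cf$seed)
  nfam <- cf$n_pairs
  reg <- sample(cf$regions, nfam, replace = TRUE,
                prob = cf$region_weights / sum(cf$region_weights))
  # cohorts: heavy-tailed sizes within region
  cohort <- character(nfam)
  cohort_levels <- character(0)
  for (i in seq_along(cf$regions)) {
    k <- cf$cohorts_per_region[i]
    idx <- which(reg == cf$regions[i])
    labs <- sprintf("%s_cohort%02d", gsub("[^A-Za-z]", "", cf$regions[i]),
                    seq_len(k))
    cohort[idx] <- sample(labs, length(idx), replace = TRUE,
                          prob = (1 / seq_len(k)))
    cohort_levels <- c(cohort_levels, labs)
  }
  coh_eff <- setNames(stats::rnorm(length(cohort_levels), 0,
                                   cf$cohort_effect_sd), cohort_levels)
  zyg_type <- sample(c("MZ", "SSDZ", "OSDZ"), nfam, replace = TRUE,
                     prob = cf$zygosity_probs)
  pair_sex1 <- ifelse(zyg_type == "OSDZ", "M",
                      ifelse(stats::runif(nfam) < cf$sex_ratio, "M", "F"))
  pair_sex2 <- ifelse(zyg_type == "OSDZ", "F", pair_sex1)
  birth_year <- sample(seq(cf$birth_year_range[1], cf$birth_year_range[2]),
                       nfam, replace = TRUE)
  # effective A correlation; assortative mating raises the DZ/OS correlation
  # through the correlated parental midpoints (approximate, documented)
  dz_bump <- 0.5 * cf$assortative_r * 0.5
  rho_a <- ifelse(zyg_type == "MZ", 1,
                  ifelse(zyg_type == "SSDZ", pmin(0.5 + dz_bump, 1),
                         pmin(cf$r_gos + dz_bump, 1)))
  A <- matrix(0, nfam, 2)
  for (r in unique(rho_a)) {
    ii <- which(rho_a == r)
    A[ii, ] <- corr_pair(length(ii), r)
  }
  Cl <- stats::rnorm(nfam)
  E0 <- matrix(stats::rnorm(2 * nfam), nfam, 2)  # persistent E part
  # ages per family: 1 + geometric extra groups, region-weighted by the
  # reference age composition
  n_extra <- stats::rgeom(nfam, prob = 1 - cf$repeat_prob)
  age_w <- lapply(cf$regions, function(r) {
    sub <- cf$mean_curve[cf$mean_curve$region == r, ]
    w <- tapply(if ("n" %in% names(sub)) sub$n else rep(1, nrow(sub)),
                sub$age, sum)
    w / sum(w)
  })
  names(age_w) <- cf$regions
  yr_mid <- mean(cf$birth_year_range)
  k_fam <- pmin(1L + n_extra, 19L)
  ages_by_fam <- lapply(seq_len(nfam), function(f) {
    w <- age_w[[reg[f]]]
    sort(sample(as.integer(names(w)), k_fam[f], prob = w))
  })
  # pair-measurement level (one row per family x age group)
  fam <- rep(seq_len(nfam), times = k_fam)
  age <- unlist(ages_by_fam)
  npm <- length(fam)
  exact <- age - 0.5 + stats::runif(npm)
  grp <- ifelse(zyg_type == "MZ", paste0("MZ", pair_sex1),
                ifelse(zyg_type == "SSDZ", paste0("DZ", pair_sex1), "OS"))
  rho_e <- cf$repeat_e_corr
  comp_key <- paste(cf$components$sex, cf$components$age)
  base_mean <- (zyg_type[fam] != "MZ") * cf$dz_mean_shift +
    coh_eff[cohort[fam]] + cf$birth_year_slope * (birth_year[fam] - yr_mid)
  height <- matrix(0, npm, 2)
  for (tw in 1:2) {
    sx <- if (tw == 1) pair_sex1[fam] else pair_sex2[fam]
    mu <- numeric(npm); sdv <- numeric(npm)
    for (r in cf$regions) for (s in c("M", "F")) {
      ii <- which(reg[fam] == r & sx == s)
      if (!length(ii)) next
      mu[ii] <- interp_curve(cf$mean_curve, r, s, exact[ii], "mean_cm")
      sdv[ii] <- interp_curve(cf$mean_curve, r, s, exact[ii], "sd_cm")
    }
    comp <- cf$components[match(paste(sx, age), comp_key), ]
    e_dev <- sqrt(rho_e) * E0[fam, tw] +
      sqrt(1 - rho_e) * stats::rnorm(npm)
    height[, tw] <- mu + base_mean +
      sqrt(comp$h2) * sdv * A[fam, tw] +
      sqrt(comp$c2) * sdv * Cl[fam] +
      sqrt(comp$e2) * sdv * e_dev
    if (cf$measurement_error_sd > 0)
      height[, tw] <- height[, tw] +
        stats::rnorm(npm, 0, cf$measurement_error_sd)
  }
  out <- data.frame(
    family_id = c(fam, fam), twin_order = rep(1:2, each = npm),
    cohort = cohort[c(fam, fam)], region = reg[c(fam, fam)],
    zygosity = ifelse(zyg_type[c(fam, fam)] == "MZ", "MZ", "DZ"),
    sex = c(pair_sex1[fam], pair_sex2[fam]),
    birth_year = birth_year[c(fam, fam)],
    exact_age = c(exact, exact), height_cm = c(height[, 1], height[, 2]),
    true_group = grp[c(fam, fam)], age_group = c(age, age),
    stringsAsFactors = FALSE)
  out <- out[order(out$family_id, out$twin_order, out$age_group), ]
  if (cf$missing_cotwin_prob > 0) {
    drop <- stats::runif(nrow(out)) < cf$missing_cotwin_prob / 2
    out <- out[!drop, ]
  }
  rownames(out) <- NULL
  out
}

#' Write a simulated cohort and its configuration to disk
#'
#' @param table measurement table from \code{\link{simulate_cohort}}.
#' @param config the \code{\link{generator_config}} used.
#' @param path output CSV path; a JSON sidecar \code{<path>.json} records
#'   the full configuration including the seed.
#' @return invisibly, the two paths written.
#' @export
write_cohort <- function(table, config, path) {
  utils::write.csv(table, path, row.names = FALSE)
  side <- paste0(path, ".json")
  cfj <- config
  cfj$mean_curve <- NULL
  cfj$components <- NULL
  jsonlite::write_json(
    list(schema = "acegrowth-generator-1", config = unclass(cfj),
         mean_curve = config$mean_curve, components = config$components),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}
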
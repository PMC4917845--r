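# Descriptive statistics and twin correlations that drive model selection.

#' Descriptive height statistics by stratum
#'
#' @param table measurement-level table with \code{height_cm}.
#' @param strata character vector of stratifying columns (default age group,
#'   sex and region).
#' @return data.frame of per-stratum N, mean and SD (denominator n - 1;
#'   SD is NA for single-record strata, empty strata are omitted).
#' @export
describe_heights <- function(table, strata = c("age_group", "sex", "region")) {
  if (is.null(table$age_group) && "age_group" %in% strata)
    table$age_group <- bin_age(table$exact_age)
  strata <- intersect(strata, names(table))
  f <- interaction(table[strata], drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(table)), f)
  rows <- lapply(idx, function(ii) {
    x <- table$height_cm[ii]
    cbind(table[ii[1], strata, drop = FALSE],
          data.frame(n = length(x), mean = mean(x),
                     sd = if (length(x) > 1) stats::sd(x) else NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[strata]), , drop = FALSE]
}

# Fisher-z confidence interval for a correlation.
fisher_ci <- function(r, n, level = 0.95) {
  if (is.na(r) || n < 4) return(c(NA_real_, NA_real_))
  z <- atanh(min(max(r, -0.9999), 0.9999))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Within-pair twin correlations per zygosity-sex group
#'
#' Same-sex groups use the double-entry Pearson correlation (each pair
#' contributes both orderings, making the estimate invariant to the
#' arbitrary within-pair order); opposite-sex pairs use the single-entry
#' Pearson correlation with the male listed first. Confidence intervals are
#' Fisher-z with n = number of pairs.
#'
#' @param pairs paired-observation table (\code{group}, \code{y1},
#'   \code{y2}; optionally a \code{stratum} column to stratify by, e.g. age
#'   group).
#' @param stratum optional column name to compute correlations within.
#' @param min_pairs below this count the correlation is reported missing.
#' @return data.frame with stratum (if any), group, r, n_pairs, ci_lo,
#'   ci_hi, and a low-n flag.
#' @export
twin_correlations <- function(pairs, stratum = NULL, min_pairs = 3L) {
  strat <- if (is.null(stratum)) rep("all", nrow(pairs)) else pairs[[stratum]]
  out <- list()
  for (s in unique(strat)) {
    for (g in TWIN_GROUPS) {
      sub <- pairs[strat == s & pairs$group == g, ]
      n <- nrow(sub)
      if (n < min_pairs) {
        r <- NA_real_
      } else if (g == "OS") {
        r <- stats::cor(sub$y1, sub$y2)
      } else {
        r <- stats::cor(c(sub$y1, sub$y2), c(sub$y2, sub$y1))
      }
      ci <- fisher_ci(r, n)
      out[[length(out) + 1L]] <- data.frame(
        stratum = s, group = g, r = r, n_pairs = n,
        ci_lo = ci[1], ci_hi = ci[2], low_n = n < 50,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Model-selection heuristics from twin correlations
#'
#' For one stratum's correlation set, flags (strict inequalities):
#' \code{genetic} when rMZ > rDZ, \code{shared_env} when rDZ > rMZ / 2, and
#' \code{sex_specific} when rOS < min(rDZM, rDZF). MZ and same-sex DZ
#' correlations are pooled across sexes by pair-count weights for the first
#' two flags. Missing groups leave the corresponding flag undetermined (NA).
#'
#' @param correlations one stratum's rows from
#'   \code{\link{twin_correlations}}.
#' @return list of flags, each carrying the compared values as attributes.
#' @export
selection_heuristics <- function(correlations) {
  gv <- function(g) {
    row <- correlations[correlations$group == g, ]
    if (nrow(row) != 1L || is.na(row$r)) NULL else row
  }
  pool <- function(gs) {
    rows <- do.call(rbind, lapply(gs, gv))
    if (is.null(rows) || nrow(rows) == 0L) return(NA_real_)
    sum(rows$r * rows$n_pairs) / sum(rows$n_pairs)
  }
  r_mz <- pool(c("MZM", "MZF"))
  r_dz <- pool(c("DZM", "DZF"))
  r_os <- if (!is.null(gv("OS"))) gv("OS")$r else NA_real_
  r_dzm <- if (!is.null(gv("DZM"))) gv("DZM")$r else NA_real_
  r_dzf <- if (!is.null(gv("DZF"))) gv("DZF")$r else NA_real_
  genetic <- if (is.na(r_mz) || is.na(r_dz)) NA else r_mz > r_dz
  shared_env <- if (is.na(r_mz) || is.na(r_dz)) NA else r_dz > r_mz / 2
  sex_specific <- if (is.na(r_os) || is.na(r_dzm) || is.na(r_dzf)) NA
                  else r_os < min(r_dzm, r_dzf)
  list(genetic = structure(genetic, r_mz = r_mz, r_dz = r_dz),
       shared_env = structure(shared_env, r_dz = r_dz, half_r_mz = r_mz / 2),
       sex_specific = structure(sex_specific, r_os = r_os,
                                r_dzm = r_dzm, r_dzf = r_dzf))
}
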
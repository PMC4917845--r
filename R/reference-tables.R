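#' Reference growth table: height by age, sex and geographic-cultural region
#'
#' Descriptive statistics (number of twin individuals, mean and SD of height
#' in cm) for each one-year age group (1--19), sex, and geographic-cultural
#' region (Europe; North-America and Australia; East-Asia), as observed in
#' large pooled twin-cohort data. These values calibrate the default mean
#' growth curves, total variances and age composition of
#' \code{\link{generator_config}}.
#'
#' @return A data.frame with columns \code{region}, \code{sex} ("M"/"F"),
#'   \code{age} (integer 1--19), \code{n}, \code{mean_cm}, \code{sd_cm}.
#' @export
growth_reference <- function() {
  regions <- c("Europe", "North-America and Australia", "East-Asia")
  # columns: n, mean, sd per age 1..19
  boys_eur <- matrix(c(
    12674, 75.3, 3.3, 10357, 87.7, 3.9, 13761, 96.8, 4.3, 7244, 103.0, 4.9,
    6014, 112.6, 5.5, 1328, 118.3, 5.6, 11136, 125.3, 6.1, 4333, 130.3, 5.8,
    4212, 135.8, 6.6, 8902, 142.1, 6.8, 6470, 145.6, 7.1, 8342, 152.7, 7.9,
    3322, 159.7, 8.8, 6308, 166.0, 9.1, 3782, 172.3, 8.8, 5806, 176.2, 7.4,
    6795, 178.2, 7.1, 6514, 179.6, 6.9, 4822, 180.0, 6.9), ncol = 3, byrow = TRUE)
  boys_naa <- matrix(c(
    547, 71.6, 8.8, 607, 85.2, 4.7, 1050, 96.3, 5.1, 1481, 101.4, 6.4,
    1080, 108.9, 6.5, 797, 114.4, 8.4, 707, 121.5, 8.8, 679, 129.6, 7.2,
    1398, 133.9, 7.4, 839, 139.2, 7.4, 951, 144.4, 8.4, 2197, 151.8, 8.2,
    1124, 157.6, 10.1, 2422, 165.7, 8.4, 1377, 171.3, 8.4, 2070, 174.9, 7.6,
    2918, 174.4, 7.5, 8063, 173.4, 7.1, 3923, 174.9, 7.8), ncol = 3, byrow = TRUE)
  boys_ea <- matrix(c(
    2213, 69.4, 3.7, 1629, 83.4, 4.6, 1987, 93.4, 3.8, 986, 99.6, 4.6,
    870, 106.5, 4.6, 986, 112.6, 4.9, 1240, 118.1, 5.2, 1243, 123.8, 5.2,
    1227, 129.4, 5.5, 1358, 135.2, 6.1, 1415, 140.5, 6.4, 1060, 146.5, 7.1,
    299, 154.7, 9.6, 166, 164.2, 7.2, 137, 166.7, 7.3, 120, 168.4, 6.1,
    100, 171.5, 6.8, 118, 170.7, 5.6, 117, 174.4, 5.3), ncol = 3, byrow = TRUE)
  girls_eur <- matrix(c(
    12498, 74.1, 3.0, 9885, 86.7, 3.8, 13949, 95.8, 4.4, 7144, 101.8, 4.9,
    5884, 111.9, 5.6, 886, 117.9, 5.3, 11368, 124.5, 6.2, 3979, 129.5, 5.9,
    3868, 134.8, 6.8, 8882, 141.6, 7.0, 6288, 145.8, 7.6, 8376, 153.7, 8.2,
    3078, 159.5, 7.4, 6644, 162.6, 6.8, 3736, 165.5, 6.7, 6516, 165.4, 6.2,
    7523, 166.1, 6.3, 5504, 167.1, 6.5, 5582, 167.2, 6.4), ncol = 3, byrow = TRUE)
  girls_naa <- matrix(c(
    583, 70.3, 9.0, 579, 84.1, 4.8, 1086, 95.1, 5.5, 1411, 100.1, 6.3,
    1010, 107.5, 7.0, 785, 113.9, 8.0, 719, 120.4, 7.5, 681, 127.6, 8.0,
    1362, 133.3, 7.5, 817, 138.7, 8.3, 953, 145.2, 8.5, 2327, 152.9, 7.9,
    1216, 156.4, 7.6, 2578, 161.4, 6.5, 1379, 162.6, 6.7, 2128, 163.9, 6.8,
    1534, 164.6, 7.0, 2037, 164.6, 7.0, 2297, 164.4, 6.9), ncol = 3, byrow = TRUE)
  girls_ea <- matrix(c(
    2355, 67.8, 3.9, 1681, 81.9, 4.4, 2137, 92.3, 3.6, 1000, 98.6, 4.5,
    902, 105.5, 4.6, 1070, 112.3, 4.8, 1358, 117.5, 5.0, 1389, 123.2, 5.4,
    1375, 129.0, 5.6, 1468, 135.4, 6.5, 1499, 142.1, 7.0, 1170, 147.7, 6.8,
    305, 153.5, 6.3, 166, 157.5, 6.0, 173, 157.6, 5.6, 150, 158.4, 6.0,
    122, 159.3, 5.5, 130, 159.5, 4.8, 127, 158.4, 5.3), ncol = 3, byrow = TRUE)
  blocks <- list(
    list(regions[1], "M", boys_eur), list(regions[2], "M", boys_naa),
    list(regions[3], "M", boys_ea), list(regions[1], "F", girls_eur),
    list(regions[2], "F", girls_naa), list(regions[3], "F", girls_ea))
  out <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(region = b[[1]], sex = b[[2]], age = 1:19,
               n = b[[3]][, 1], mean_cm = b[[3]][, 2], sd_cm = b[[3]][, 3],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Default standardized variance-component trajectories by age and sex
#'
#' Standardized additive genetic (h2), shared environmental (c2) and unique
#' environmental (e2) proportions of height variance for each one-year age
#' group and sex, used as the generating truth of the default synthetic
#' cohort. The trajectories are anchored at the reported pooled estimates
#' (boys: h2 = 0.40 and c2 = 0.48 at age 1, h2 = 0.83 at 14 and 0.82 at 16;
#' girls: h2 = 0.38 and c2 = 0.49 at age 1, peak 0.76) and interpolated
#' smoothly in between, with e2 held in the narrow 0.05--0.14 band typical of
#' height.
#'
#' @return A data.frame with columns \code{sex}, \code{age}, \code{h2},
#'   \code{c2}, \code{e2}; rows sum to 1.
#' @export
default_components <- function() {
  h2_m <- c(0.40, 0.50, 0.58, 0.63, 0.67, 0.70, 0.72, 0.73, 0.74, 0.75,
            0.75, 0.76, 0.79, 0.83, 0.79, 0.82, 0.78, 0.76, 0.75)
  c2_m <- c(0.48, 0.39, 0.31, 0.26, 0.22, 0.19, 0.17, 0.16, 0.15, 0.14,
            0.14, 0.13, 0.10, 0.05, 0.10, 0.06, 0.11, 0.13, 0.14)
  h2_f <- c(0.38, 0.48, 0.56, 0.61, 0.65, 0.68, 0.70, 0.71, 0.72, 0.73,
            0.74, 0.74, 0.76, 0.75, 0.74, 0.73, 0.72, 0.71, 0.70)
  c2_f <- c(0.49, 0.40, 0.32, 0.27, 0.23, 0.20, 0.18, 0.17, 0.16, 0.15,
            0.14, 0.14, 0.12, 0.13, 0.14, 0.15, 0.16, 0.17, 0.18)
  out <- rbind(
    data.frame(sex = "M", age = 1:19, h2 = h2_m, c2 = c2_m,
               e2 = 1 - h2_m - c2_m, stringsAsFactors = FALSE),
    data.frame(sex = "F", age = 1:19, h2 = h2_f, c2 = c2_f,
               e2 = 1 - h2_f - c2_f, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
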
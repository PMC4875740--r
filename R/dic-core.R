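#' Molar areas implied by an activator-inhibitor ratio
#'
#' Under the dental inhibitory cascade (DIC) model the three lower molar
#' areas, relative to the first, are fully determined by the ratio of
#' activator to inhibitor strength (\eqn{a/i}): \eqn{M_1 = 1},
#' \eqn{M_2 = a/i}, \eqn{M_3 = 2(a/i) - 1}.
#'
#' @param ratio positive numeric vector of activator/inhibitor ratios
#'   (\eqn{a/i}). Must be at least 0.5; below that the model predicts a
#'   negative third molar area, i.e. the agenesis regime.
#' @return a data.frame with columns `m1`, `m2`, `m3` (unitless areas,
#'   `m1` always 1). `m3` is exactly 0 at `ratio == 0.5`.
#' @examples
#' areas_from_ratio(1)    # equal-sized molars
#' areas_from_ratio(2)    # increasing molar row: 1, 2, 3
#' @seealso [predicted_m3m1()], [agenesis_threshold_ratio()]
#' @export
areas_from_ratio <- function(ratio) {
  stopifnot(is.numeric(ratio), all(is.finite(ratio)), all(ratio > 0))
  if (any(ratio < agenesis_threshold_ratio())) {
    bad <- ratio[ratio < agenesis_threshold_ratio()][1]
    stop("a/i ratio ", format(bad), " predicts a negative M3 area (",
         format(2 * bad - 1), "): agenesis regime, no valid molar triplet")
  }
  m3 <- 2 * ratio - 1
  m3[ratio == agenesis_threshold_ratio()] <- 0
  data.frame(m1 = rep(1, length(ratio)), m2 = ratio, m3 = m3)
}

#' DIC-predicted M3/M1 proportion from M2/M1
#'
#' The molar-proportion line of the inhibitory cascade:
#' \eqn{M_3/M_1 = 2(M_2/M_1) - 1}.
#'
#' @param m2m1 positive numeric vector of M2/M1 area proportions.
#' @return numeric vector of predicted M3/M1 values. Values at or below 0
#'   correspond to the third-molar agenesis regime; they are returned as-is
#'   for the caller to interpret.
#' @export
predicted_m3m1 <- function(m2m1) {
  stopifnot(is.numeric(m2m1), all(m2m1 > 0))
  2 * m2m1 - 1
}

#' M2/M1 threshold for third-molar agenesis
#'
#' The M2/M1 value at which the DIC line predicts a vanishing third molar:
#' agenesis is expected when M2 is less than half the size of M1.
#'
#' @return the scalar 0.5, the root of [predicted_m3m1()].
#' @export
agenesis_threshold_ratio <- function() 0.5

#' Classify a species' position in molar-proportion morphospace
#'
#' Morphospace regions are named by the size ordering of the three molars.
#' Two of them are compatible with the inhibitory cascade: `INCREASING`
#' (M1 < M2 < M3, high a/i) and `DECREASING` (M1 > M2 > M3, low a/i). The
#' `M2_PEAK` (M1 < M2 > M3) and `M2_TROUGH` (M1 > M2 < M3) regions cannot be
#' produced by any a/i value. Points whose orderings are ties within `tol`
#' are labelled `EQUAL`.
#'
#' @param m2m1,m3m1 numeric vectors of species molar-area proportions
#'   (M2/M1 must be positive, M3/M1 non-negative).
#' @param tol non-negative tie tolerance on the ratio comparisons.
#' @return character vector with values in `INCREASING`, `DECREASING`,
#'   `M2_PEAK`, `M2_TROUGH`, `EQUAL`.
#' @export
classify_region <- function(m2m1, m3m1, tol = 1e-9) {
  stopifnot(is.numeric(m2m1), is.numeric(m3m1), length(m2m1) == length(m3m1),
            all(m2m1 > 0), all(m3m1 >= 0), tol >= 0)
  m2_gt_m1 <- m2m1 > 1 + tol
  m2_lt_m1 <- m2m1 < 1 - tol
  m3_gt_m2 <- m3m1 > m2m1 + tol
  m3_lt_m2 <- m3m1 < m2m1 - tol
  out <- rep("EQUAL", length(m2m1))
  out[m2_gt_m1 & m3_gt_m2] <- "INCREASING"
  out[m2_lt_m1 & m3_lt_m2] <- "DECREASING"
  out[m2_gt_m1 & m3_lt_m2] <- "M2_PEAK"
  out[m2_lt_m1 & m3_gt_m2] <- "M2_TROUGH"
  # one comparison tied, the other not: still no strict cascade ordering
  out
}

#' Is a morphospace point consistent with the DIC model?
#'
#' A point is DIC-consistent when it falls in one of the two cascade-
#' compatible regions (`INCREASING`, `DECREASING`), lies exactly on the
#' molar-proportion line within `line_tol` (perpendicular distance), or is
#' an `EQUAL` tie (equal molars satisfy the line exactly).
#'
#' @inheritParams classify_region
#' @param line_tol non-negative tolerance on perpendicular distance from
#'   the DIC line; the default 0 counts only exact line membership.
#' @return logical vector.
#' @export
dic_consistent <- function(m2m1, m3m1, line_tol = 0, tol = 1e-9) {
  stopifnot(line_tol >= 0)
  region <- classify_region(m2m1, m3m1, tol = tol)
  region %in% c("INCREASING", "DECREASING", "EQUAL") |
    perpendicular_distance(m2m1, m3m1) <= line_tol
}

#' Perpendicular distance from the DIC molar-proportion line
#'
#' Absolute Euclidean distance in the (M2/M1, M3/M1) plane from the line
#' \eqn{M_3/M_1 = 2(M_2/M_1) - 1}, i.e. \eqn{|2 x - y - 1| / \sqrt{5}}.
#'
#' @inheritParams classify_region
#' @return non-negative numeric vector of distances.
#' @export
perpendicular_distance <- function(m2m1, m3m1) {
  stopifnot(is.numeric(m2m1), is.numeric(m3m1), length(m2m1) == length(m3m1))
  abs(2 * m2m1 - m3m1 - 1) / sqrt(5)
}
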
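# Two-step dissection: the single-transformation scans estimate augmented
# effects (mixtures of main and epistatic components); combining the four
# augmented epistatic estimates of a pair inverts exactly to the four
# digenic components, after which the main-effect augmentation sums can be
# subtracted.

#' Dissect a pair's augmented epistatic estimates into components
#'
#' Inverts the linear definitions `i_sum = i_aa + i_dd` (Z1),
#' `i_tilde = i_ad + i_da` (Z2), `i_diff = i_aa - i_dd` and
#' `i_asym = i_ad - i_da` (Z4):
#' `i_aa = (i_diff + i_sum)/2`, `i_dd = (i_sum - i_diff)/2`,
#' `i_ad = (i_tilde + i_asym)/2`, `i_da = (i_tilde - i_asym)/2`.
#' All inputs must be on the component-effect scale.
#'
#' @param i_sum,i_tilde,i_diff,i_asym Augmented epistatic estimates
#'   (vectorised).
#' @return Data frame with columns `iaa`, `iad`, `ida`, `idd`.
#' @export
#' @examples
#' dissect_pair(2.2, 4.4, 3.2, 2.4)  # 2.7, 3.4, 1.0, -0.5
dissect_pair <- function(i_sum, i_tilde, i_diff, i_asym) {
  data.frame(iaa = (i_diff + i_sum) / 2,
             iad = (i_tilde + i_asym) / 2,
             ida = (i_tilde - i_asym) / 2,
             idd = (i_sum - i_diff) / 2)
}

#' Dissect augmented main effects of one QTL
#'
#' Removes the epistatic contamination from the augmented main effects:
#' `a_k = a*_k - 1/2 sum_l (i_ad(kl) - i_da(kl))` and
#' `d_k = d*_k + 1/2 sum_l (i_aa(kl) - i_dd(kl))`, where the sums run over
#' the dissected pairs involving `k`. When `k` is the higher-indexed
#' member of a canonically oriented pair the asymmetric terms swap roles
#' (`i_ad` and `i_da` trade places); pass the orientation via `k_first`.
#'
#' @param a_star,d_star Augmented main-effect estimates of QTL `k`.
#' @param pair_effects Data frame of dissected components for every pair
#'   involving `k` (columns `iaa`, `iad`, `ida`, `idd`); zero rows allowed.
#' @param k_first Logical vector, one per row of `pair_effects`: `TRUE`
#'   when `k` is the lower-indexed (first) member of that pair.
#' @return Named numeric vector `c(a, d)`.
#' @export
#' @examples
#' dissect_main(3.0, 1.6,
#'              data.frame(iaa = 2.7, iad = 3.4, ida = 1.0, idd = -0.5),
#'              k_first = TRUE)  # a = 1.8, d = 3.2
dissect_main <- function(a_star, d_star, pair_effects = NULL, k_first = TRUE) {
  if (is.null(pair_effects) || !nrow(pair_effects))
    return(c(a = as.numeric(a_star), d = as.numeric(d_star)))
  k_first <- rep_len(k_first, nrow(pair_effects))
  asym <- ifelse(k_first, pair_effects$iad - pair_effects$ida,
                          pair_effects$ida - pair_effects$iad)
  c(a = as.numeric(a_star) - 0.5 * sum(asym),
    d = as.numeric(d_star) + 0.5 * sum(pair_effects$iaa - pair_effects$idd))
}

#' Dominance-degree classification
#'
#' Classifies the ratio `rho = |num / den|` (dominance over additive for a
#' QTL, `|i_dd / i_aa|` for a pair): additive `A` when `rho < 0.2`,
#' partial dominance `PD` when `0.2 <= rho < 0.8`, dominance `D` when
#' `0.8 <= rho < 1.2`, overdominance `OD` when `rho >= 1.2`. A zero
#' denominator with nonzero numerator is overdominance (`rho = Inf`);
#' both zero gives `NA`.
#'
#' @param numerator_effect,denominator_effect Effect estimates
#'   (vectorised): `d` and `a`, or `i_dd` and `i_aa`.
#' @return Character vector in `{"A", "PD", "D", "OD", NA}`.
#' @export
#' @examples
#' classify_dominance(0.00, 2.09)   # "A"
#' classify_dominance(1.86, 0.00)   # "OD"
#' classify_dominance(1.89, -1.89)  # "D"
classify_dominance <- function(numerator_effect, denominator_effect) {
  nn <- max(length(numerator_effect), length(denominator_effect))
  num <- abs(rep_len(as.numeric(numerator_effect), nn))
  den <- abs(rep_len(as.numeric(denominator_effect), nn))
  if (any(!is.finite(num)) || any(!is.finite(den))) stop("effects must be finite")
  rho <- ifelse(den == 0, ifelse(num == 0, NA_real_, Inf), num / den)
  ifelse(is.na(rho), NA_character_,
    ifelse(rho < 0.2, "A",
      ifelse(rho < 0.8, "PD", ifelse(rho < 1.2, "D", "OD"))))
}

#' Integrate scans across transformations and dissect all effects
#'
#' Matches terms across the Z1, Z2 and Z4 scan results by marker index
#' (pairs by index pair), imputes augmented components missing from a scan
#' as zero with an `incomplete` flag, applies [dissect_pair()] then
#' [dissect_main()], and attaches dominance-degree classes. A QTL enters
#' the main-effect table when its augmented additive or dominance effect
#' was detected, or when it participates in a detected pair.
#'
#' @param scan_Z1,scan_Z2,scan_Z4 `attc_scan` results from
#'   [scan_transformation()] on the same genotype set (any may be empty).
#' @param map Optional [marker_map()] for chromosome/marker annotation.
#' @param drop_incomplete If `TRUE`, pairs with a missing augmented
#'   component are dropped instead of zero-imputed.
#' @return List of class `attc_dissection`: `qtl` (data frame `marker`,
#'   `a_star`, `d_star`, `a`, `d`, `dominance_degree`, `class`,
#'   `incomplete`) and `pairs` (data frame `k`, `l`, the four augmented
#'   estimates, `iaa`, `iad`, `ida`, `idd`, `dominance_degree`, `class`,
#'   `incomplete`), plus chromosome/marker columns when `map` is given.
#' @export
integrate_scans <- function(scan_Z1, scan_Z2, scan_Z4, map = NULL,
                            drop_incomplete = FALSE) {
  pick <- function(scan, type) {
    if (is.null(scan) || !nrow(scan)) {
      return(data.frame(k = integer(), l = integer(), estimate = numeric()))
    }
    out <- scan[scan$type == type, c("k", "l", "estimate"), drop = FALSE]
    rownames(out) <- NULL
    out
  }
  a_star <- pick(scan_Z1, "a_star"); i_sum <- pick(scan_Z1, "i_sum")
  d_star <- pick(scan_Z2, "d_star"); i_tilde <- pick(scan_Z2, "i_tilde")
  i_diff <- pick(scan_Z4, "i_diff"); i_asym <- pick(scan_Z4, "i_asym")

  pair_key <- function(d) if (nrow(d)) paste(d$k, d$l) else character(0)
  keys <- unique(c(pair_key(i_sum), pair_key(i_tilde),
                   pair_key(i_diff), pair_key(i_asym)))
  look <- function(d, keys) {
    v <- d$estimate[match(keys, pair_key(d))]
    v  # NA when the component was not detected
  }
  if (length(keys)) {
    kk <- as.integer(sub(" .*", "", keys)); ll <- as.integer(sub(".* ", "", keys))
    est <- cbind(i_sum = look(i_sum, keys), i_tilde = look(i_tilde, keys),
                 i_diff = look(i_diff, keys), i_asym = look(i_asym, keys))
    incomplete <- rowSums(is.na(est)) > 0
    est[is.na(est)] <- 0
    pairs <- data.frame(k = kk, l = ll, est,
                        dissect_pair(est[, "i_sum"], est[, "i_tilde"],
                                     est[, "i_diff"], est[, "i_asym"]),
                        incomplete = incomplete)
    pairs <- pairs[order(pairs$k, pairs$l), , drop = FALSE]
    if (drop_incomplete) pairs <- pairs[!pairs$incomplete, , drop = FALSE]
    pairs$dominance_degree <- abs(pairs$idd) / abs(pairs$iaa)
    pairs$class <- classify_dominance(pairs$idd, pairs$iaa)
  } else {
    pairs <- data.frame(k = integer(), l = integer(), i_sum = numeric(),
                        i_tilde = numeric(), i_diff = numeric(),
                        i_asym = numeric(), iaa = numeric(), iad = numeric(),
                        ida = numeric(), idd = numeric(),
                        incomplete = logical(), dominance_degree = numeric(),
                        class = character())
  }

  qtl_markers <- sort(unique(c(a_star$k, d_star$k, pairs$k, pairs$l)))
  if (length(qtl_markers)) {
    a_hat <- a_star$estimate[match(qtl_markers, a_star$k)]
    d_hat <- d_star$estimate[match(qtl_markers, d_star$k)]
    incomplete_q <- is.na(a_hat) | is.na(d_hat)
    a_hat[is.na(a_hat)] <- 0; d_hat[is.na(d_hat)] <- 0
    ad <- t(vapply(seq_along(qtl_markers), function(i) {
      mk <- qtl_markers[i]
      rows <- pairs$k == mk | pairs$l == mk
      dissect_main(a_hat[i], d_hat[i], pairs[rows, , drop = FALSE],
                   k_first = pairs$k[rows] == mk)
    }, c(a = 0, d = 0)))
    qtl <- data.frame(marker = qtl_markers, a_star = a_hat, d_star = d_hat,
                      a = ad[, "a"], d = ad[, "d"],
                      dominance_degree = abs(ad[, "d"]) / abs(ad[, "a"]),
                      class = classify_dominance(ad[, "d"], ad[, "a"]),
                      incomplete = incomplete_q)
    rownames(qtl) <- NULL
  } else {
    qtl <- data.frame(marker = integer(), a_star = numeric(),
                      d_star = numeric(), a = numeric(), d = numeric(),
                      dominance_degree = numeric(), class = character(),
                      incomplete = logical())
  }
  if (!is.null(map)) {
    qtl$chr <- map$chr[qtl$marker]; qtl$marker_name <- map$marker[qtl$marker]
    pairs$chr_k <- map$chr[pairs$k]; pairs$marker_k <- map$marker[pairs$k]
    pairs$chr_l <- map$chr[pairs$l]; pairs$marker_l <- map$marker[pairs$l]
  }
  rownames(pairs) <- NULL
  structure(list(qtl = qtl, pairs = pairs), class = "attc_dissection")
}
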
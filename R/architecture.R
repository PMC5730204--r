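#' Define a QTL architecture
#'
#' A QTL architecture holds the overall mean `mu`, per-QTL additive and
#' dominance effects `(a_k, d_k)` tied to marker indices, and per-pair
#' digenic epistatic effects `(i_aa, i_ad, i_da, i_dd)`. Pairs are stored in
#' canonical orientation `k < l` by concatenated marker index: `i_ad(k, l)`
#' is additive at the lower-indexed locus crossed with dominance at the
#' higher-indexed one.
#'
#' @param mu Overall mean genotypic value.
#' @param qtl Data frame with columns `marker` (1-based concatenated marker
#'   index), `a` and `d`. May have zero rows.
#' @param pairs Data frame with columns `k`, `l` (marker indices, `k < l`),
#'   `iaa`, `iad`, `ida`, `idd`. May be `NULL` or have zero rows.
#' @return A list of class `qtl_architecture`.
#' @export
#' @examples
#' qtl_architecture(mu = 0,
#'                  qtl = data.frame(marker = c(2, 5), a = c(1, -1), d = c(0.5, 0)),
#'                  pairs = data.frame(k = 2, l = 5, iaa = 1, iad = 0, ida = 0, idd = -1))
qtl_architecture <- function(mu = 0, qtl = NULL, pairs = NULL) {
  if (is.null(qtl)) qtl <- data.frame(marker = integer(), a = numeric(), d = numeric())
  qtl <- as.data.frame(qtl)
  stopifnot(all(c("marker", "a", "d") %in% names(qtl)))
  qtl$marker <- as.integer(qtl$marker)
  if (anyDuplicated(qtl$marker)) stop("QTL marker indices must be distinct")
  if (is.null(pairs))
    pairs <- data.frame(k = integer(), l = integer(),
                        iaa = numeric(), iad = numeric(), ida = numeric(), idd = numeric())
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("k", "l", "iaa", "iad", "ida", "idd") %in% names(pairs)))
  pairs$k <- as.integer(pairs$k); pairs$l <- as.integer(pairs$l)
  if (nrow(pairs)) {
    if (any(pairs$k >= pairs$l)) stop("pairs must be in canonical orientation k < l")
    if (anyDuplicated(pairs[, c("k", "l")])) stop("each pair may be listed at most once")
  }
  eff <- c(qtl$a, qtl$d, pairs$iaa, pairs$iad, pairs$ida, pairs$idd, mu)
  if (any(!is.finite(eff))) stop("all effects must be finite")
  structure(list(mu = as.numeric(mu), qtl = qtl, pairs = pairs),
            class = "qtl_architecture")
}

#' Marker indices involved in an architecture
#' @param arch A [qtl_architecture()].
#' @return Sorted unique 1-based marker indices.
#' @export
arch_markers <- function(arch) {
  stopifnot(inherits(arch, "qtl_architecture"))
  sort(unique(c(arch$qtl$marker, arch$pairs$k, arch$pairs$l)))
}

#' Six-QTL benchmark architecture for the study harness
#'
#' Three two-locus interaction patterns on the [default_marker_map()]:
#' a pair where both loci carry main effects (markers 20 and 36), a pair
#' where only one does (markers 45 and 70), and a pair where neither does
#' (markers 80 and 95). Effects (trait units): QTL1 (a = 1.8, d = 3.2),
#' QTL2 (a = 2.8, d = -1.5) with interaction (2.7, 3.4, 1.0, -0.5);
#' QTL3 (0, 0), QTL4 (a = -2, d = 2.1) with interaction
#' (-0.7, -1.6, -3.8, 2.9); QTL5 and QTL6 (0, 0) with interaction
#' (2.8, 3.9, 0.9, -0.6); `mu = 0`.
#'
#' @return A [qtl_architecture()].
#' @export
#' @examples
#' augmented_effects(preset_architecture())$pairs
preset_architecture <- function() {
  qtl_architecture(
    mu = 0,
    qtl = data.frame(marker = c(20L, 36L, 45L, 70L, 80L, 95L),
                     a = c(1.8, 2.8, 0, -2, 0, 0),
                     d = c(3.2, -1.5, 0, 2.1, 0, 0)),
    pairs = data.frame(k = c(20L, 45L, 80L), l = c(36L, 70L, 95L),
                       iaa = c(2.7, -0.7, 2.8),
                       iad = c(3.4, -1.6, 3.9),
                       ida = c(1.0, -3.8, 0.9),
                       idd = c(-0.5, 2.9, -0.6)))
}

#' Augmented effects implied by an architecture
#'
#' Forward composition of component effects into the augmented effects that
#' the single-transformation scans estimate: per QTL `k`,
#' `a*_k = a_k + 1/2 sum_l (i_ad(kl) - i_da(kl))` and
#' `d*_k = d_k - 1/2 sum_l (i_aa(kl) - i_dd(kl))`, where for a partner `l`
#' preceding `k` in the canonical orientation the asymmetric terms swap
#' roles; per pair, `i_sum = i_aa + i_dd` (Z1), `i_tilde = i_ad + i_da`
#' (Z2), `i_diff = i_aa - i_dd` and `i_asym = i_ad - i_da` (Z4).
#'
#' @param arch A [qtl_architecture()].
#' @return List with data frames `qtl` (`marker`, `a_star`, `d_star`) and
#'   `pairs` (`k`, `l`, `i_sum`, `i_tilde`, `i_diff`, `i_asym`).
#' @export
augmented_effects <- function(arch) {
  stopifnot(inherits(arch, "qtl_architecture"))
  qtl <- arch$qtl; pr <- arch$pairs
  a_star <- qtl$a; d_star <- qtl$d
  if (nrow(pr)) for (i in seq_len(nrow(qtl))) {
    k <- qtl$marker[i]
    as_first <- pr[pr$k == k, , drop = FALSE]   # k is the lower-indexed member
    as_second <- pr[pr$l == k, , drop = FALSE]  # k is the higher-indexed member
    a_star[i] <- a_star[i] +
      0.5 * (sum(as_first$iad - as_first$ida) + sum(as_second$ida - as_second$iad))
    d_star[i] <- d_star[i] -
      0.5 * (sum(as_first$iaa - as_first$idd) + sum(as_second$iaa - as_second$idd))
  }
  list(qtl = data.frame(marker = qtl$marker, a_star = a_star, d_star = d_star),
       pairs = data.frame(k = pr$k, l = pr$l,
                          i_sum = pr$iaa + pr$idd,
                          i_tilde = pr$iad + pr$ida,
                          i_diff = pr$iaa - pr$idd,
                          i_asym = pr$iad - pr$ida))
}
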
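# Oversaturated genome-wide design matrices: one main-effect column per
# marker (Z1/Z2) plus one or two interaction columns per marker pair.
# Codings follow the transformation expectations exactly, so a noiseless
# regression of oracle Z values on the design recovers the augmented
# effects to round-off (asserted in the test suite).

all_marker_pairs <- function(q) {
  k <- rep.int(seq_len(q - 1L), (q - 1L):1L)
  l <- sequence((q - 1L):1L) + k
  cbind(k = k, l = l)
}

#' Build the oversaturated design matrix for a transformation
#'
#' For lines coded `x_k` in `{+1, -1}` per marker:
#' \describe{
#'   \item{Z1}{main columns `x_k` (coefficients are augmented additive
#'     effects `a*_k`) and pair columns `(1 + x_k x_l)/2` in `{1, 0}`
#'     (coefficients `i_aa + i_dd`).}
#'   \item{Z2}{main columns `-x_k` (coefficients `d*_k`) and pair columns
#'     `(1 - x_k x_l)/2` (coefficients `i_ad + i_da`).}
#'   \item{Z4}{no main columns; per pair, a `(i_aa - i_dd)` column
#'     `-x_k x_l / 2` and a `(i_ad - i_da)` column `(x_k - x_l)/2`. The
#'     default `scale = "effect"` yields coefficients directly on the
#'     component-effect scale; `scale = "printed"` uses the `{-1, +1}`
#'     codes for the first column, under which its fitted coefficient is
#'     half of `i_aa - i_dd` and reported estimates are doubled
#'     downstream.}
#'   \item{Z5, Z6}{codings derived by enumeration from the family-mean
#'     oracle (loci independent within L3 families). These designs satisfy
#'     the oracle identity but are partially aliased with the intercept
#'     and main columns (Z5) and omit the constant `i_dd` column (Z6);
#'     they are provided for expectation checks, not for joint fitting.}
#' }
#'
#' `coding = "product"` replaces the Z1/Z2 pair columns by the raw
#' element-wise product `x_k x_l` (a sensitivity mode only: it is an affine
#' transform of the default coding that halves the interaction coefficient
#' and shifts the intercept).
#'
#' @param genotypes Homozygous line codes, `n x q` matrix of `+1`/`-1`.
#' @param which Transformation: `"Z1"`, `"Z2"`, `"Z4"`, `"Z5"` or `"Z6"`.
#' @param scale `"effect"` or `"printed"` (Z4 only; see above).
#' @param coding `"standard"` or `"product"` (Z1/Z2 only; see above).
#' @return Numeric matrix of class `attc_design` with attributes
#'   `terms` (data frame `type`, `k`, `l` of 1-based marker indices),
#'   `transformation` and `scale`. For Z1/Z2, `p = q + q(q-1)/2` columns.
#' @export
#' @examples
#' g <- rbind(c(1, -1), c(-1, -1))
#' build_design(g, "Z1")
build_design <- function(genotypes, which = c("Z1", "Z2", "Z4", "Z5", "Z6"),
                         scale = c("effect", "printed"),
                         coding = c("standard", "product")) {
  which <- match.arg(which)
  scale <- match.arg(scale)
  coding <- match.arg(coding)
  G <- unclass(genotypes)
  if (is.null(dim(G))) G <- matrix(G, nrow = 1)
  storage.mode(G) <- "double"
  if (!all(G %in% c(-1, 1))) stop("genotypes must be homozygous +1/-1 codes")
  q <- ncol(G)
  pr <- all_marker_pairs(q)
  XX <- G[, pr[, "k"], drop = FALSE] * G[, pr[, "l"], drop = FALSE]  # x_k * x_l
  lbl <- function(type, k, l = NA_integer_)
    ifelse(is.na(l), paste0(type, ":", k), paste0(type, ":", k, ":", l))
  if (which %in% c("Z1", "Z2")) {
    main_type <- if (which == "Z1") "a_star" else "d_star"
    pair_type <- if (which == "Z1") "i_sum" else "i_tilde"
    M <- if (which == "Z1") G else -G
    P <- if (coding == "product") XX
         else if (which == "Z1") (1 + XX) / 2 else (1 - XX) / 2
    X <- cbind(M, P)
    terms <- data.frame(type = c(rep(main_type, q), rep(pair_type, nrow(pr))),
                        k = c(seq_len(q), pr[, "k"]),
                        l = c(rep(NA_integer_, q), pr[, "l"]))
  } else if (which == "Z4") {
    half <- if (scale == "effect") 0.5 else 1
    D <- -XX * half                                    # (i_aa - i_dd) column
    A <- (G[, pr[, "k"], drop = FALSE] - G[, pr[, "l"], drop = FALSE]) / 2
    X <- cbind(D, A)
    terms <- data.frame(type = rep(c("i_diff", "i_asym"), each = nrow(pr)),
                        k = c(pr[, "k"], pr[, "k"]),
                        l = c(pr[, "l"], pr[, "l"]))
  } else if (which == "Z5") {
    Gk <- G[, pr[, "k"], drop = FALSE]; Gl <- G[, pr[, "l"], drop = FALSE]
    X <- cbind(1.5 * G, (3 * XX + 2) / 4, (3 * Gk - 2 * Gl) / 4,
               (3 * Gl - 2 * Gk) / 4, (3 + 2 * XX) / 4)
    terms <- data.frame(
      type = c(rep("a", q), rep(c("i_aa", "i_ad", "i_da", "i_dd"), each = nrow(pr))),
      k = c(seq_len(q), rep(pr[, "k"], 4)),
      l = c(rep(NA_integer_, q), rep(pr[, "l"], 4)))
  } else {  # Z6; the i_dd coefficient is constant (1/2) and absorbed by the intercept
    Gk <- G[, pr[, "k"], drop = FALSE]; Gl <- G[, pr[, "l"], drop = FALSE]
    X <- cbind(-XX / 2, Gk / 2, Gl / 2)
    terms <- data.frame(type = rep(c("i_aa", "i_ad", "i_da"), each = nrow(pr)),
                        k = rep(pr[, "k"], 3), l = rep(pr[, "l"], 3))
  }
  colnames(X) <- lbl(terms$type, terms$k, terms$l)
  structure(X, terms = terms, transformation = which, scale = scale,
            class = c("attc_design", class(X)))
}

#' True intercept of a transformation's linear predictor
#'
#' The value that, together with the design columns of [build_design()] and
#' the augmented effects of [augmented_effects()] (raw effects for Z5/Z6),
#' reproduces the oracle [expected_Z()] exactly: `2 mu + sum(d_k)` for Z1,
#' `sum(a_k)` for Z2, `mu + sum(d_k) + 1/2 sum(i_aa + i_dd)` for Z4,
#' `3 mu + 3/2 sum(d_k)` for Z5 and `mu + sum(d_k) + 1/2 sum(i_dd)` for Z6.
#'
#' @param arch A [qtl_architecture()].
#' @param which Transformation id.
#' @return Scalar intercept.
#' @export
oracle_intercept <- function(arch, which = c("Z1", "Z2", "Z4", "Z5", "Z6")) {
  which <- match.arg(which)
  sd_ <- sum(arch$qtl$d); sa <- sum(arch$qtl$a)
  switch(which,
    Z1 = 2 * arch$mu + sd_,
    Z2 = sa,
    Z4 = arch$mu + sd_ + 0.5 * sum(arch$pairs$iaa + arch$pairs$idd),
    Z5 = 3 * arch$mu + 1.5 * sd_,
    Z6 = arch$mu + sd_ + 0.5 * sum(arch$pairs$idd))
}
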
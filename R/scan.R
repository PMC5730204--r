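# Second stage of a genome scan: ordinary least squares on the columns
# retained by the shrinkage scan, a per-term likelihood-ratio test, and
# LOD-thresholded reporting on the component-effect scale.

#' Refit retained columns and test each term
#'
#' Ordinary least squares (with intercept) on the retained design columns.
#' Identical columns — common with tightly linked markers — are collapsed
#' first, keeping the column that appears earliest in design order (lowest
#' marker index); columns aliased after deduplication are dropped with a
#' message. Each term is then tested by a likelihood-ratio comparison of
#' the full model against the model with that term removed:
#' `LOD = (n/2) log10(RSS_reduced / RSS_full)`, with the chi-square
#' p-value of the equivalent deviance, and the variance explained
#' `100 (RSS_reduced - RSS_full) / TSS`.
#'
#' @param y Response vector.
#' @param X Design matrix of class `attc_design` (or plain matrix).
#' @param retained Integer indices of retained columns (non-empty).
#' @param lod_threshold Report only terms with LOD above this (default 2.5).
#' @param t_values Optional named/indexed vector of first-stage `t`
#'   statistics, carried through to the report.
#' @return Data frame of class `attc_scan` (possibly zero rows): columns
#'   `term`, `type`, `k`, `l`, `estimate`, `t`, `lod`, `p_value`,
#'   `var_explained_pct`, plus attributes `intercept`, `transformation`
#'   and `scale` when `X` carries them. For a Z4 design built at
#'   `scale = "printed"`, `i_diff` estimates are doubled so that all
#'   reported estimates are on the component-effect scale.
#' @export
refit_and_test <- function(y, X, retained, lod_threshold = 2.5, t_values = NULL) {
  y <- as.numeric(y)
  terms <- attr(X, "terms")
  trans <- attr(X, "transformation")
  dscale <- attr(X, "scale")
  Xm <- unclass(X)
  retained <- sort(unique(as.integer(retained)))
  if (!length(retained)) stop("retained set is empty")
  n <- length(y)
  Xr <- Xm[, retained, drop = FALSE]
  # collapse exactly identical columns, keeping the first in design order
  dup <- duplicated(lapply(seq_len(ncol(Xr)), function(j) Xr[, j]))
  if (any(dup)) {
    message("collapsing ", sum(dup), " duplicated design column(s)")
    retained <- retained[!dup]
    Xr <- Xr[, !dup, drop = FALSE]
  }
  qrX <- qr(cbind(`(Intercept)` = 1, Xr))
  if (qrX$rank < ncol(Xr) + 1L) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    keep <- keep[keep > 1L] - 1L
    message("dropping ", ncol(Xr) - length(keep), " aliased design column(s)")
    retained <- retained[keep]
    Xr <- Xr[, keep, drop = FALSE]
    qrX <- qr(cbind(`(Intercept)` = 1, Xr))
  }
  coefs <- qr.coef(qrX, y)
  rss_full <- sum(qr.resid(qrX, y)^2)
  tss <- sum((y - mean(y))^2)
  kcols <- ncol(Xr)
  lod <- p_value <- varexp <- numeric(kcols)
  for (j in seq_len(kcols)) {
    qr_j <- qr(cbind(1, Xr[, -j, drop = FALSE]))
    rss_j <- sum(qr.resid(qr_j, y)^2)
    lod[j] <- (n / 2) * log10(rss_j / max(rss_full, 1e-300))
    p_value[j] <- stats::pchisq(2 * log(10) * lod[j], df = 1, lower.tail = FALSE)
    varexp[j] <- 100 * (rss_j - rss_full) / tss
  }
  est <- coefs[-1]
  tv <- if (is.null(t_values)) rep(NA_real_, kcols) else as.numeric(t_values[retained])
  if (is.null(terms))
    terms <- data.frame(type = rep(NA_character_, ncol(Xm)),
                        k = NA_integer_, l = NA_integer_)
  tr <- terms[retained, , drop = FALSE]
  labels <- colnames(Xm) %||% paste0("V", seq_len(ncol(Xm)))
  # printed-scale Z4 compatibility: the +-1 coding estimates (i_aa - i_dd)/2
  if (identical(dscale, "printed") && identical(trans, "Z4")) {
    dbl <- tr$type == "i_diff"
    est[dbl] <- 2 * est[dbl]
  }
  out <- data.frame(term = labels[retained], type = tr$type,
                    k = tr$k, l = tr$l, estimate = unname(est), t = tv,
                    lod = lod, p_value = p_value,
                    var_explained_pct = varexp, stringsAsFactors = FALSE)
  out <- out[out$lod > lod_threshold, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, intercept = unname(coefs[1]), transformation = trans,
            scale = dscale, retained = retained,
            class = c("attc_scan", "data.frame"))
}

#' Genome scan of one transformation
#'
#' Builds the oversaturated design for the requested transformation, runs
#' the shrinkage scan ([eb_lasso_fit()] by default, or a cross-validated
#' L1 path via \pkg{glmnet} with `backend = "lasso"`), keeps columns with
#' first-stage `t > t_threshold`, and refits them by
#' [refit_and_test()]. An empty scan (no retained term, or none passing
#' the LOD threshold) returns a zero-row result.
#'
#' For Z4 the per-pair `(i_ad - i_da)` columns are mutually aliased
#' (each is a difference of two marker vectors), so the scan instead fits
#' the equivalent identifiable basis of marker main columns plus
#' element-wise product columns, in which each pair loads
#' `-(i_aa - i_dd)/2` on its product column and `+/-(i_ad - i_da)/2` on
#' its two marker columns, and reports the pair-level terms: `i_diff`
#' from the product coefficient (doubled, sign-flipped) and `i_asym` as
#' the difference of the two marker loadings with a 2-df
#' likelihood-ratio LOD. Marker loadings are paired through the detected
#' product pairs, and by magnitude matching otherwise; see the package
#' vignette.
#'
#' @param z Observed transformation vector (e.g. a column of
#'   `simulate_phenotypes()$Z`).
#' @param genotypes RIL genotype matrix.
#' @param which Transformation id (`"Z1"`, `"Z2"` or `"Z4"` for fitting).
#' @param a,b EBLASSO hyperparameters.
#' @param t_threshold First-stage filter on `|beta|/posterior sd`
#'   (default 2.0).
#' @param lod_threshold Second-stage LOD threshold (default 2.5).
#' @param backend `"eb_lasso"` or `"lasso"`.
#' @param scale Z4 scale convention passed to [build_design()].
#' @param seed Seed for the lasso backend's fold assignment.
#' @return An `attc_scan` data frame (see [refit_and_test()]).
#' @export
#' @examples
#' g <- simulate_ril_genotypes(marker_map(rep(1, 10), seq(0, 90, 10)), 150, seed = 4)
#' arch <- qtl_architecture(qtl = data.frame(marker = 3, a = 2, d = 0))
#' ph <- simulate_phenotypes(arch, g, h = 0.8, m = 5, seed = 5,
#'                           transformations = "Z1")
#' scan_transformation(ph$Z$Z1, g, "Z1")
scan_transformation <- function(z, genotypes, which, a = 1, b = 3e-4,
                                t_threshold = 2.0, lod_threshold = 2.5,
                                backend = c("eb_lasso", "lasso"),
                                scale = c("effect", "printed"), seed = 1L) {
  backend <- match.arg(backend)
  scale <- match.arg(scale)
  if (identical(which, "Z4"))
    return(.scan_z4(z, genotypes, a = a, b = b, t_threshold = t_threshold,
                    lod_threshold = lod_threshold, backend = backend,
                    seed = seed))
  X <- build_design(genotypes, which, scale = scale)
  empty <- function() {
    out <- data.frame(term = character(), type = character(),
                      k = integer(), l = integer(), estimate = numeric(),
                      t = numeric(), lod = numeric(), p_value = numeric(),
                      var_explained_pct = numeric(), stringsAsFactors = FALSE)
    structure(out, intercept = mean(z), transformation = which, scale = scale,
              class = c("attc_scan", "data.frame"))
  }
  sel <- .select_columns(z, X, a, b, t_threshold, backend, seed)
  if (!length(sel$retained)) return(empty())
  refit_and_test(z, X, sel$retained, lod_threshold = lod_threshold,
                 t_values = sel$tvals)
}

# First-stage column selection shared by the scan paths: EBLASSO posterior
# t filter, or a cross-validated L1 path with an OLS t filter.
.select_columns <- function(z, X, a, b, t_threshold, backend, seed) {
  if (backend == "eb_lasso") {
    fit <- eb_lasso_fit(z, X, a = a, b = b)
    return(list(retained = which(fit$t > t_threshold), tvals = fit$t))
  }
  if (!requireNamespace("glmnet", quietly = TRUE))
    stop("backend 'lasso' requires the glmnet package")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  cv <- glmnet::cv.glmnet(unclass(X), z, nfolds = 5)
  bhat <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  sel <- which(bhat != 0)
  tvals <- numeric(ncol(X))
  if (length(sel)) {
    fit <- stats::lm(z ~ unclass(X)[, sel, drop = FALSE])
    ok <- which(!is.na(stats::coef(fit)))
    ct <- stats::coef(summary(fit))
    tvals[sel[ok[-1] - 1L]] <- abs(ct[-1, "t value"])
  }
  list(retained = which(tvals > t_threshold), tvals = tvals)
}

# Z4 genome scan in the identifiable marker-plus-product parametrization.
#
# The pair-level (i_ad - i_da) columns (x_k - x_l)/2 of the Z4 design are
# mutually aliased (every column lies in the span of the marker vectors),
# so a sparse scan on them cannot distinguish pairings with similar
# effects. The expectation of Z4 is, however, exactly linear in the
# marker main columns x_k and the product columns x_k x_l: each pair
# loads -(i_aa - i_dd)/2 on its product column and +(i_ad - i_da)/2 /
# -(i_ad - i_da)/2 on its two marker columns. The scan therefore fits
# that basis and reports the pair-level contract: `i_diff` from product
# columns (doubled and sign-flipped), and `i_asym` as the difference of
# the two marker loadings, with marker pairs matched primarily through
# the detected product pairs and by magnitude otherwise. The `i_asym`
# LOD is the 2-df likelihood-ratio drop of both marker columns.
.scan_z4 <- function(z, genotypes, a, b, t_threshold, lod_threshold,
                     backend, seed) {
  G <- unclass(genotypes)
  storage.mode(G) <- "double"
  q <- ncol(G)
  pr <- all_marker_pairs(q)
  XX <- G[, pr[, "k"], drop = FALSE] * G[, pr[, "l"], drop = FALSE]
  X <- cbind(G, XX)
  terms <- data.frame(type = c(rep("gamma", q), rep("prod", nrow(pr))),
                      k = c(seq_len(q), pr[, "k"]),
                      l = c(rep(NA_integer_, q), pr[, "l"]))
  colnames(X) <- ifelse(is.na(terms$l), paste0("g:", terms$k),
                        paste0("p:", terms$k, ":", terms$l))
  empty <- structure(
    data.frame(term = character(), type = character(), k = integer(),
               l = integer(), estimate = numeric(), t = numeric(),
               lod = numeric(), p_value = numeric(),
               var_explained_pct = numeric(), stringsAsFactors = FALSE),
    intercept = mean(z), transformation = "Z4", scale = "effect",
    class = c("attc_scan", "data.frame"))
  sel <- .select_columns(z, X, a, b, t_threshold, backend, seed)
  if (!length(sel$retained)) return(empty)
  attr(X, "terms") <- terms
  raw <- refit_and_test(z, X, sel$retained, lod_threshold = -Inf,
                        t_values = sel$tvals)
  kept <- attr(raw, "retained")
  n <- length(z)
  Xr <- X[, kept, drop = FALSE]
  qr_full <- qr(cbind(1, Xr))
  rss_full <- sum(qr.resid(qr_full, z)^2)
  tss <- sum((z - mean(z))^2)
  sig <- raw[raw$lod > lod_threshold, , drop = FALSE]
  prods <- sig[sig$type == "prod", , drop = FALSE]
  gammas <- sig[sig$type == "gamma", , drop = FALSE]
  rows <- list()
  if (nrow(prods))
    rows$i_diff <- data.frame(
      term = paste0("i_diff:", prods$k, ":", prods$l), type = "i_diff",
      k = prods$k, l = prods$l, estimate = -2 * prods$estimate,
      t = prods$t, lod = prods$lod, p_value = prods$p_value,
      var_explained_pct = prods$var_explained_pct, stringsAsFactors = FALSE)
  # pair up the significant marker loadings
  avail <- gammas[order(-gammas$lod), , drop = FALSE]
  matched <- list()
  for (i in seq_len(nrow(prods))) {
    pk <- prods$k[i]; pl <- prods$l[i]
    if (pk %in% avail$k && pl %in% avail$k) {
      matched[[length(matched) + 1L]] <- c(pk, pl)
      avail <- avail[!avail$k %in% c(pk, pl), , drop = FALSE]
    }
  }
  if (nrow(avail) >= 2L) {   # magnitude matching of leftover loadings
    pos <- avail[avail$estimate > 0, , drop = FALSE]
    neg <- avail[avail$estimate < 0, , drop = FALSE]
    pos <- pos[order(-abs(pos$estimate)), , drop = FALSE]
    neg <- neg[order(-abs(neg$estimate)), , drop = FALSE]
    for (i in seq_len(min(nrow(pos), nrow(neg))))
      matched[[length(matched) + 1L]] <- c(pos$k[i], neg$k[i])
  }
  if (length(matched)) {
    asym <- do.call(rbind, lapply(matched, function(kl) {
      kk <- min(kl); ll <- max(kl)
      gk <- gammas$estimate[match(kk, gammas$k)]
      gl <- gammas$estimate[match(ll, gammas$k)]
      drop_idx <- which(colnames(Xr) %in% paste0("g:", c(kk, ll)))
      qr_red <- qr(cbind(1, Xr[, -drop_idx, drop = FALSE]))
      rss_red <- sum(qr.resid(qr_red, z)^2)
      lod2 <- (n / 2) * log10(rss_red / max(rss_full, 1e-300))
      data.frame(term = paste0("i_asym:", kk, ":", ll), type = "i_asym",
                 k = kk, l = ll, estimate = gk - gl,
                 t = min(gammas$t[match(c(kk, ll), gammas$k)]),
                 lod = lod2,
                 p_value = stats::pchisq(2 * log(10) * lod2, df = 2,
                                         lower.tail = FALSE),
                 var_explained_pct = 100 * (rss_red - rss_full) / tss,
                 stringsAsFactors = FALSE)
    }))
    rows$i_asym <- asym[asym$lod > lod_threshold, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) return(empty)
  rownames(out) <- NULL
  structure(out, intercept = attr(raw, "intercept"), transformation = "Z4",
            scale = "effect", class = c("attc_scan", "data.frame"))
}
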
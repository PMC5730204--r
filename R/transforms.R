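#' Residual standard deviation matching a target heritability
#'
#' Heritability is defined here at the transformation level on family-mean
#' combined data: `h = VarG(Z) / (VarG(Z) + c * sigma_e^2 / m)`, where
#' `VarG(Z)` is the empirical variance of the exact expected transformation
#' values over the supplied lines, `m` is the number of replicate
#' observations per family, and `c` is the sum of squared family-mean
#' weights of the transformation (2 for Z1/Z2, 3 for Z4, 6 for Z3, 3 for
#' Z5, 5 for Z6) under one common per-observation residual sd for every
#' family type. Solving gives
#' `sigma_e^2 = VarG(Z) * (1 - h) * m / (h * c)`.
#'
#' @param arch A [qtl_architecture()].
#' @param genotypes RIL genotype matrix.
#' @param h Target heritability in (0, 1).
#' @param m Replicates per family.
#' @param which Transformation anchoring the calibration.
#' @return Per-observation residual standard deviation `sigma_e`.
#' @export
#' @examples
#' g <- simulate_ril_genotypes(default_marker_map(), 200, seed = 1)
#' calibrate_residual_sd(preset_architecture(), g, h = 0.8, m = 10, which = "Z1")
calibrate_residual_sd <- function(arch, genotypes, h, m, which = "Z1") {
  if (!(is.numeric(h) && length(h) == 1 && h > 0 && h < 1))
    stop("'h' must be in (0, 1)")
  m <- as.integer(m)
  stopifnot(m >= 1L)
  varG <- stats::var(expected_Z(genotypes, arch, which))
  if (varG <= 0) stop("degenerate architecture: VarG(", which, ") = 0")
  cc <- sum(transformation_weights(which)^2)
  sqrt(varG * (1 - h) * m / (h * cc))
}

#' Simulate aTTC family phenotypes and transformation data
#'
#' Each replicate observation of family `t` of line `i` is the family-mean
#' genotypic value plus independent `N(0, sigma_e^2)` noise; transformation
#' vectors are linear combinations of the resulting family means, e.g.
#' `Z1_i = L1bar_i + L2bar_i`. With `sigma_e = 0` the Z vectors equal the
#' exact oracle values [expected_Z()].
#'
#' @param arch A [qtl_architecture()].
#' @param genotypes RIL genotype matrix (`+1`/`-1` codes).
#' @param h Target heritability passed to [calibrate_residual_sd()];
#'   ignored when `sigma_e` is given.
#' @param m Replicates per family (>= 1).
#' @param seed Optional integer seed (local RNG state).
#' @param transformations Character vector among `"Z1" ... "Z6"`.
#' @param sigma_e Optional per-observation residual sd overriding the
#'   heritability calibration (use `0` for noiseless data, or an explicit
#'   value when `VarG = 0`, e.g. a null architecture).
#' @param calibrate Transformation anchoring the calibration (default the
#'   first requested one). A single shared `sigma_e` cannot hit the same
#'   `h` for every transformation at once; see the package vignette.
#' @return A list of class `attc_phenotypes`: `Z` (data frame, one column
#'   per transformation), `family_means` (data frame `L1 ... L4` as
#'   needed), `family_obs` (list of `n x m` matrices), and metadata
#'   (`n`, `m`, `h`, `sigma_e`, `seed`, `transformations`).
#' @export
#' @examples
#' g <- simulate_ril_genotypes(default_marker_map(), 50, seed = 2)
#' ph <- simulate_phenotypes(preset_architecture(), g, h = 0.8, m = 10, seed = 3)
#' head(ph$Z)
simulate_phenotypes <- function(arch, genotypes, h = 0.8, m = 10, seed = NULL,
                                transformations = c("Z1", "Z2", "Z4"),
                                sigma_e = NULL, calibrate = transformations[1]) {
  stopifnot(inherits(arch, "qtl_architecture"))
  transformations <- match.arg(transformations, c("Z1", "Z2", "Z3", "Z4", "Z5", "Z6"),
                               several.ok = TRUE)
  m <- as.integer(m)
  stopifnot(m >= 1L)
  G <- unclass(genotypes)
  n <- nrow(G)
  if (is.null(sigma_e))
    sigma_e <- calibrate_residual_sd(arch, genotypes, h, m, which = calibrate)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  W <- vapply(transformations, transformation_weights, numeric(4))
  families <- rownames(W)[rowSums(W != 0) > 0]
  family_obs <- list()
  family_means <- matrix(0, n, length(families), dimnames = list(NULL, families))
  for (t in families) {
    gv <- family_values(G, arch, t)
    obs <- gv + matrix(stats::rnorm(n * m, 0, sigma_e), n, m)
    family_obs[[t]] <- obs
    family_means[, t] <- rowMeans(obs)
  }
  Z <- matrix(0, n, length(transformations),
              dimnames = list(NULL, transformations))
  for (z in transformations)
    Z[, z] <- family_means[, families, drop = FALSE] %*% W[families, z]
  structure(list(Z = as.data.frame(Z),
                 family_means = as.data.frame(family_means),
                 family_obs = family_obs,
                 n = n, m = m, h = h, sigma_e = sigma_e,
                 seed = seed, transformations = transformations),
            class = "attc_phenotypes")
}
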
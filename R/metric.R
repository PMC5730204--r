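#' F-infinity metric dummy codes of a genotype class
#'
#' Under the F-infinity metric the additive code is +1/0/-1 for MM/Mm/mm and
#' the heterozygote carries the dominance term: the dominance code is 0/1/0.
#'
#' @param locus_genotype Character vector with entries in `"MM"`, `"Mm"`,
#'   `"mm"`.
#' @return A numeric matrix with columns `x_a` and `x_d`.
#' @export
#' @examples
#' fq_codes(c("MM", "Mm", "mm"))
fq_codes <- function(locus_genotype) {
  g <- as.character(locus_genotype)
  bad <- !g %in% c("MM", "Mm", "mm")
  if (any(bad)) stop("invalid genotype class: ", paste(unique(g[bad]), collapse = ", "))
  cbind(x_a = ifelse(g == "MM", 1, ifelse(g == "mm", -1, 0)),
        x_d = ifelse(g == "Mm", 1, 0))
}

# Expected F-infinity codes per locus for each tester family, as functions of
# the homozygous line code x in {+1,-1}. Loci treated as independent, so
# family-mean expectations of epistatic products factorize.
.family_code_expectations <- function(x, tester) {
  switch(tester,
    L1 = list(EA = (x + 1) / 2, ED = (1 - x) / 2),
    L2 = list(EA = (x - 1) / 2, ED = (1 + x) / 2),
    L3 = list(EA = x / 2, ED = rep(0.5, length(x))),
    L4 = list(EA = x, ED = rep(0, length(x))),
    stop("unknown family type ", tester))
}

#' Expected genotypic value under a per-locus genotype distribution
#'
#' Computes `E[mu + sum_k (a_k x_a,k + d_k x_d,k) + sum_{k<l} (i_aa x_a,k
#' x_a,l + i_ad x_a,k x_d,l + i_da x_d,k x_a,l + i_dd x_d,k x_d,l)]` over a
#' distribution that is independent across loci, e.g. the output of
#' [progeny_distribution()].
#'
#' @param dist Matrix with one row per marker locus of the genome (columns
#'   `MM`, `Mm`, `mm`), or with rownames naming marker indices; every QTL
#'   locus of `arch` must be covered. Row order is the concatenated marker
#'   order, so row `j` is marker index `j` unless rownames say otherwise.
#' @param arch A [qtl_architecture()].
#' @return Scalar expected genotypic value.
#' @export
#' @examples
#' arch <- preset_architecture()
#' d <- progeny_distribution(rep(1, 100), "SELF")
#' genotypic_value(d, arch)  # mu + a1 + ... + i_aa sums
genotypic_value <- function(dist, arch) {
  stopifnot(inherits(arch, "qtl_architecture"))
  dist <- as.matrix(dist)
  stopifnot(ncol(dist) == 3)
  if (any(abs(rowSums(dist) - 1) > 1e-8)) stop("genotype masses must sum to 1 per locus")
  idx <- arch_markers(arch)
  if (max(idx, 0L) > nrow(dist)) stop("QTL locus missing from distribution")
  EA <- dist[, 1] - dist[, 3]  # E[x_a]
  ED <- dist[, 2]              # E[x_d]
  qtl <- arch$qtl; pr <- arch$pairs
  val <- arch$mu + sum(qtl$a * EA[qtl$marker]) + sum(qtl$d * ED[qtl$marker])
  if (nrow(pr))
    val <- val + sum(pr$iaa * EA[pr$k] * EA[pr$l] + pr$iad * EA[pr$k] * ED[pr$l] +
                     pr$ida * ED[pr$k] * EA[pr$l] + pr$idd * ED[pr$k] * ED[pr$l])
  val
}

# Family-mean genotypic values for all lines at once.
# G: n x q matrix of +1/-1 codes; returns n-vector for family t.
family_values <- function(G, arch, family = c("L1", "L2", "L3", "L4")) {
  family <- match.arg(family)
  stopifnot(inherits(arch, "qtl_architecture"))
  G <- unclass(G)
  idx <- arch_markers(arch)
  if (max(idx, 0L) > ncol(G)) stop("QTL index exceeds marker count")
  qtl <- arch$qtl; pr <- arch$pairs
  val <- rep(arch$mu, nrow(G))
  EAc <- function(m) .family_code_expectations(G[, m], family)$EA
  EDc <- function(m) .family_code_expectations(G[, m], family)$ED
  for (i in seq_len(nrow(qtl)))
    val <- val + qtl$a[i] * EAc(qtl$marker[i]) + qtl$d[i] * EDc(qtl$marker[i])
  for (i in seq_len(nrow(pr)))
    val <- val + pr$iaa[i] * EAc(pr$k[i]) * EAc(pr$l[i]) +
                 pr$iad[i] * EAc(pr$k[i]) * EDc(pr$l[i]) +
                 pr$ida[i] * EDc(pr$k[i]) * EAc(pr$l[i]) +
                 pr$idd[i] * EDc(pr$k[i]) * EDc(pr$l[i])
  val
}

# Family-mean weights defining each transformation (L1, L2, L3, L4).
transformation_weights <- function(which) {
  w <- switch(which,
    Z1 = c(1, 1, 0, 0), Z2 = c(1, -1, 0, 0), Z3 = c(1, 1, -2, 0),
    Z4 = c(1, 1, 0, -1), Z5 = c(1, 1, 1, 0), Z6 = c(0, 0, 2, -1),
    stop("unknown transformation ", which))
  names(w) <- c("L1", "L2", "L3", "L4")
  w
}

#' Exact expected value of a data transformation
#'
#' The brute-force oracle: for each line, computes the family-mean genotypic
#' values of L1 (line x P1), L2 (line x P2), L3 (line x F1) and L4 (selfed
#' line) via [progeny_distribution()] expectations and combines them per the
#' transformation definition (Z1 = L1 + L2, Z2 = L1 - L2, Z3 = L1 + L2 - 2 L3,
#' Z4 = L1 + L2 - L4, Z5 = L1 + L2 + L3, Z6 = 2 L3 - L4).
#'
#' @param genotypes Matrix of homozygous line codes (`+1`/`-1`), lines in
#'   rows; a single line may be given as a vector.
#' @param arch A [qtl_architecture()].
#' @param which One of `"Z1" ... "Z6"`.
#' @return Numeric vector of expected values, one per line.
#' @export
#' @examples
#' g <- rbind(c(1, 1), c(1, -1))
#' arch <- qtl_architecture(qtl = data.frame(marker = 1:2, a = c(1, 2), d = c(0.5, -0.5)))
#' expected_Z(g, arch, "Z1")
expected_Z <- function(genotypes, arch, which = c("Z1", "Z2", "Z3", "Z4", "Z5", "Z6")) {
  which <- match.arg(which)
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  G <- unclass(genotypes)
  if (!all(G %in% c(-1, 1))) stop("lines must be homozygous at all loci (+1/-1 codes)")
  w <- transformation_weights(which)
  out <- numeric(nrow(G))
  for (t in names(w)) if (w[[t]] != 0)
    out <- out + w[[t]] * family_values(G, arch, t)
  out
}
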
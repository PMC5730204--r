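# Small reusable fixtures, built in code.

# one-chromosome map with evenly spaced markers
tiny_map <- function(q = 10, spacing = 10) {
  marker_map(chr = rep("C1", q), pos = spacing * (seq_len(q) - 1))
}

# two-chromosome map for cross-chromosome checks
two_chr_map <- function(q_per = 6, spacing = 10) {
  marker_map(chr = rep(c("C1", "C2"), each = q_per),
             pos = rep(spacing * (seq_len(q_per) - 1), 2))
}

# random architecture on q markers: n_qtl main-effect loci with either all
# pairs among them epistatic or disjoint pairs (1-2, 3-4, ...; the layout
# under which the Z4 asymmetric block is identifiable), effects ~ N(0, 1.5^2)
random_architecture <- function(q, n_qtl = 3, seed = 1, mu = NULL,
                                pairs = c("all", "disjoint")) {
  pairs <- match.arg(pairs)
  set.seed(seed)
  mk <- sort(sample.int(q, n_qtl))
  pr <- if (pairs == "all") t(utils::combn(mk, 2)) else
    matrix(mk[seq_len(n_qtl %/% 2 * 2)], ncol = 2, byrow = TRUE)
  qtl_architecture(
    mu = if (is.null(mu)) rnorm(1) else mu,
    qtl = data.frame(marker = mk, a = rnorm(n_qtl, 0, 1.5),
                     d = rnorm(n_qtl, 0, 1.5)),
    pairs = data.frame(k = pr[, 1], l = pr[, 2],
                       iaa = rnorm(nrow(pr), 0, 1.5),
                       iad = rnorm(nrow(pr), 0, 1.5),
                       ida = rnorm(nrow(pr), 0, 1.5),
                       idd = rnorm(nrow(pr), 0, 1.5)))
}

# assemble an attc_scan data frame from known terms (for dissection tests)
fake_scan <- function(transformation, type, k, l = NA_integer_, estimate) {
  if (!length(k)) {
    out <- data.frame(term = character(), type = character(), k = integer(),
                      l = integer(), estimate = numeric(), t = numeric(),
                      lod = numeric(), p_value = numeric(),
                      var_explained_pct = numeric(), stringsAsFactors = FALSE)
    return(structure(out, transformation = transformation,
                     class = c("attc_scan", "data.frame")))
  }
  l <- rep_len(l, length(k))
  out <- data.frame(term = paste0(type, ":", k,
                                  ifelse(is.na(l), "", paste0(":", l))),
                    type = type, k = k, l = l, estimate = estimate,
                    t = 10, lod = 10, p_value = 0,
                    var_explained_pct = 5, stringsAsFactors = FALSE)
  structure(out, transformation = transformation,
            class = c("attc_scan", "data.frame"))
}

# exact augmented-truth scans for an architecture (noiseless "perfect" scans)
oracle_scans <- function(arch) {
  ae <- augmented_effects(arch)
  list(
    Z1 = rbind(fake_scan("Z1", "a_star", ae$qtl$marker,
                         estimate = ae$qtl$a_star),
               fake_scan("Z1", "i_sum", ae$pairs$k, ae$pairs$l,
                         ae$pairs$i_sum)),
    Z2 = rbind(fake_scan("Z2", "d_star", ae$qtl$marker,
                         estimate = ae$qtl$d_star),
               fake_scan("Z2", "i_tilde", ae$pairs$k, ae$pairs$l,
                         ae$pairs$i_tilde)),
    Z4 = rbind(fake_scan("Z4", "i_diff", ae$pairs$k, ae$pairs$l,
                         ae$pairs$i_diff),
               fake_scan("Z4", "i_asym", ae$pairs$k, ae$pairs$l,
                         ae$pairs$i_asym)))
}
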
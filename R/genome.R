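#' Build a marker map
#'
#' A marker map lists ordered marker positions (cM) on one or more
#' chromosomes and defines the recombination structure used when simulating
#' recombinant inbred line (RIL) genotypes.
#'
#' @param chr Chromosome identifier per marker (coercible to character).
#' @param pos Numeric marker position in centimorgans; must be strictly
#'   increasing within each chromosome.
#' @param marker Optional marker labels; defaults to `M1 ... Mq` in
#'   concatenated genome order.
#'
#' @return A data frame of class `marker_map` with columns `chr`, `marker`
#'   and `pos_cM`, rows in concatenated genome order. Marker indices used
#'   throughout the package are 1-based row indices of this table.
#' @seealso [default_marker_map()], [simulate_ril_genotypes()]
#' @export
#' @examples
#' marker_map(chr = c(1, 1, 2), pos = c(0, 5, 0))
marker_map <- function(chr, pos, marker = NULL) {
  chr <- as.character(chr)
  pos <- as.numeric(pos)
  if (length(chr) != length(pos))
    stop("'chr' and 'pos' must have the same length")
  q <- length(pos)
  if (q < 2L) stop("a marker map needs at least 2 markers")
  if (anyNA(pos) || any(!is.finite(pos))) stop("marker positions must be finite")
  # keep chromosomes in order of first appearance, markers in given order
  chr_levels <- unique(chr)
  ord <- order(match(chr, chr_levels))
  chr <- chr[ord]; pos <- pos[ord]
  for (cc in chr_levels) {
    p <- pos[chr == cc]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within chromosome ", cc)
  }
  if (is.null(marker)) marker <- paste0("M", seq_len(q))
  if (anyDuplicated(marker)) stop("marker labels must be unique")
  mp <- data.frame(chr = chr, marker = as.character(marker), pos_cM = pos,
                   stringsAsFactors = FALSE)
  class(mp) <- c("marker_map", "data.frame")
  mp
}

#' Default simulation map: 100 markers on four chromosomes
#'
#' Four chromosomes of 25 markers each, evenly spaced at 5 cM, i.e. 99
#' consecutive 5-cM intervals and 495 cM of consecutive map length in total.
#'
#' @param n_chr Number of chromosomes.
#' @param markers_per_chr Markers per chromosome.
#' @param spacing_cM Inter-marker distance in cM.
#' @return A [marker_map()] with `n_chr * markers_per_chr` markers.
#' @export
#' @examples
#' map <- default_marker_map()
#' nrow(map)          # 100
#' map_length_cM(map) # 495
default_marker_map <- function(n_chr = 4L, markers_per_chr = 25L, spacing_cM = 5) {
  q <- n_chr * markers_per_chr
  marker_map(chr = rep(paste0("C", seq_len(n_chr)), each = markers_per_chr),
             pos = rep(spacing_cM * (seq_len(markers_per_chr) - 1L), n_chr))
}

#' Consecutive map length in cM
#'
#' Sum over chromosomes of the span between first and last marker.
#'
#' @param map A [marker_map()].
#' @return Total length in cM.
#' @export
map_length_cM <- function(map) {
  stopifnot(inherits(map, "marker_map"))
  sum(vapply(split(map$pos_cM, map$chr), function(p) max(p) - min(p), 0))
}

#' Haldane map function: cM to recombination fraction
#'
#' `r = (1 - exp(-2 d_Morgan)) / 2` with no interference.
#'
#' @param d_cM Map distance in centimorgans.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' RIL (selfed to fixation) recombination frequency
#'
#' Between two loci with meiotic recombination fraction `r`, the probability
#' that a recombinant inbred line fixes a recombinant haplotype is
#' `R = 2r / (1 + 2r)`, the standard selfed-RIL result.
#'
#' @param r Meiotic recombination fraction.
#' @return RIL recombination frequency.
#' @export
ril_recomb <- function(r) 2 * r / (1 + 2 * r)

#' Simulate RIL base-population genotypes
#'
#' Lines are fully homozygous: each marker carries either the P1 allele
#' (coded `+1`, genotype MM) or the P2 allele (coded `-1`, genotype mm).
#' Along a chromosome, genotypes form a Markov chain: the first marker is
#' `+1` or `-1` with probability 1/2 and adjacent markers disagree with the
#' RIL recombination frequency [ril_recomb()] applied to the Haldane
#' recombination fraction of the interval. Chromosomes and lines are
#' independent.
#'
#' @param map A [marker_map()].
#' @param n Number of lines (>= 1).
#' @param seed Optional integer seed; if supplied, the RNG state is set
#'   locally and restored on exit.
#' @return An `n x q` integer matrix with entries in `{+1, -1}` and marker
#'   labels as column names; class `c("ril_genotypes", "matrix")`, with the
#'   map attached as attribute `map`.
#' @export
#' @examples
#' g <- simulate_ril_genotypes(default_marker_map(), n = 10, seed = 1)
#' table(g)
simulate_ril_genotypes <- function(map, n, seed = NULL) {
  stopifnot(inherits(map, "marker_map"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  q <- nrow(map)
  G <- matrix(1L, n, q)
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    G[, idx[1]] <- ifelse(stats::runif(n) < 0.5, 1L, -1L)
    if (length(idx) > 1L) {
      R <- ril_recomb(haldane_r(diff(map$pos_cM[idx])))
      for (j in seq_along(R)) {
        flip <- stats::runif(n) < R[j]
        G[, idx[j + 1L]] <- ifelse(flip, -G[, idx[j]], G[, idx[j]])
      }
    }
  }
  colnames(G) <- map$marker
  structure(G, map = map, class = c("ril_genotypes", class(G)))
}

#' Tester-progeny genotype distribution of a homozygous line
#'
#' For a fully homozygous line, returns the per-locus genotype distribution
#' of its progeny family under each tester: crossing to P1 turns mm into Mm
#' and leaves MM; crossing to P2 turns MM into Mm and leaves mm; selfing
#' (`SELF`, the L4 family) leaves the genotype unchanged; crossing to the F1
#' tester segregates `{MM: 1/2, Mm: 1/2}` from an MM locus and
#' `{Mm: 1/2, mm: 1/2}` from an mm locus. Loci are treated as independent;
#' family means only are used downstream, so within-family linkage
#' disequilibrium affects only within-family variance.
#'
#' @param line_genotypes Vector of `+1`/`-1` codes (one line's genotypes).
#' @param tester One of `"P1"`, `"P2"`, `"F1"`, `"SELF"`.
#' @return A numeric matrix with one row per locus and columns
#'   `MM`, `Mm`, `mm` giving the genotype-class probabilities.
#' @export
#' @examples
#' progeny_distribution(c(1, -1), "P1")
progeny_distribution <- function(line_genotypes, tester = c("P1", "P2", "F1", "SELF")) {
  tester <- match.arg(tester)
  x <- as.numeric(line_genotypes)
  if (!all(x %in% c(-1, 1)))
    stop("line must be homozygous at every marker (codes +1/-1)")
  mm_ <- x < 0  # P2-homozygote loci
  P <- matrix(0, length(x), 3, dimnames = list(names(x), c("MM", "Mm", "mm")))
  switch(tester,
    P1 = { P[!mm_, "MM"] <- 1; P[mm_, "Mm"] <- 1 },
    P2 = { P[!mm_, "Mm"] <- 1; P[mm_, "mm"] <- 1 },
    SELF = { P[!mm_, "MM"] <- 1; P[mm_, "mm"] <- 1 },
    F1 = {
      P[!mm_, "MM"] <- 0.5; P[!mm_, "Mm"] <- 0.5
      P[mm_, "Mm"] <- 0.5; P[mm_, "mm"] <- 0.5
    })
  P
}
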
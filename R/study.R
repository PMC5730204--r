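# Monte Carlo harness: repeated simulate -> scan -> dissect cycles over a
# grid of sample sizes, heritabilities and replication numbers, with
# empirical power and conditional summaries per true effect.

#' Study configuration
#'
#' @param arch True [qtl_architecture()] (default [preset_architecture()]).
#' @param map Marker map (default [default_marker_map()]).
#' @param n_levels,h_levels,m_levels Treatment levels; the benchmark grid
#'   is `n` in 800/400/200, `h` in 0.8/0.5/0.2 and `m` in 10/5.
#' @param R Replicates per treatment (>= 1).
#' @param seed Master integer seed; every replicate draws its own
#'   substream seeds from it.
#' @param transformations Transformations to scan (fitting supports Z1,
#'   Z2, Z4).
#' @param a,b EBLASSO hyperparameters, fixed across replicates (select
#'   once with [select_hyperparameters()] if desired).
#' @param t_threshold,lod_threshold Scan thresholds.
#' @param calibrate Either `"each"` (default) — every transformation is
#'   simulated as its own experiment, with the residual sd calibrated so
#'   that that transformation attains `h` — or a single transformation id
#'   anchoring one shared dataset (a shared residual sd cannot give every
#'   transformation the same heritability at once).
#' @param sigma_e Optional fixed per-observation residual sd overriding the
#'   heritability calibration (0 gives noiseless data; a null architecture
#'   with no explicit `sigma_e` uses 1).
#' @param match_window Detection window in marker indices around the true
#'   position (0 = exact match).
#' @param backend Scan backend, see [scan_transformation()].
#' @param progress Emit per-replicate messages.
#' @return List of class `study_config`.
#' @export
study_config <- function(arch = preset_architecture(), map = default_marker_map(),
                         n_levels = 800, h_levels = 0.8, m_levels = 10,
                         R = 20L, seed = 1L,
                         transformations = c("Z1", "Z2", "Z4"),
                         a = 1, b = 3e-4,
                         t_threshold = 2.0, lod_threshold = 2.5,
                         calibrate = "each", match_window = 0L, sigma_e = NULL,
                         backend = "eb_lasso", progress = FALSE) {
  stopifnot(inherits(arch, "qtl_architecture"), inherits(map, "marker_map"),
            R >= 1L)
  structure(list(arch = arch, map = map, n_levels = as.integer(n_levels),
                 h_levels = h_levels, m_levels = as.integer(m_levels),
                 R = as.integer(R), seed = as.integer(seed),
                 transformations = transformations, a = a, b = b,
                 t_threshold = t_threshold, lod_threshold = lod_threshold,
                 calibrate = calibrate, match_window = as.integer(match_window),
                 sigma_e = sigma_e,
                 backend = backend, progress = isTRUE(progress)),
            class = "study_config")
}

# true augmented terms tracked per transformation
.study_truth <- function(arch) {
  ae <- augmented_effects(arch)
  nq <- nrow(ae$qtl); np <- nrow(ae$pairs)
  rbind(
    data.frame(transformation = rep("Z1", nq), type = rep("a_star", nq),
               k = ae$qtl$marker, l = rep(NA_integer_, nq), truth = ae$qtl$a_star),
    data.frame(transformation = rep("Z1", np), type = rep("i_sum", np),
               k = ae$pairs$k, l = ae$pairs$l, truth = ae$pairs$i_sum),
    data.frame(transformation = rep("Z2", nq), type = rep("d_star", nq),
               k = ae$qtl$marker, l = rep(NA_integer_, nq), truth = ae$qtl$d_star),
    data.frame(transformation = rep("Z2", np), type = rep("i_tilde", np),
               k = ae$pairs$k, l = ae$pairs$l, truth = ae$pairs$i_tilde),
    data.frame(transformation = rep("Z4", np), type = rep("i_diff", np),
               k = ae$pairs$k, l = ae$pairs$l, truth = ae$pairs$i_diff),
    data.frame(transformation = rep("Z4", np), type = rep("i_asym", np),
               k = ae$pairs$k, l = ae$pairs$l, truth = ae$pairs$i_asym))
}

# dissected component truth table
.dissect_truth <- function(arch) {
  nq <- nrow(arch$qtl); np <- nrow(arch$pairs)
  qpart <- function(eff, v)
    data.frame(effect = rep(eff, nq), k = arch$qtl$marker,
               l = rep(NA_integer_, nq), truth = v)
  ppart <- function(eff, v)
    data.frame(effect = rep(eff, np), k = arch$pairs$k, l = arch$pairs$l,
               truth = v)
  rbind(qpart("a", arch$qtl$a), qpart("d", arch$qtl$d),
        ppart("iaa", arch$pairs$iaa), ppart("iad", arch$pairs$iad),
        ppart("ida", arch$pairs$ida), ppart("idd", arch$pairs$idd))
}

# match a scan row to a true term within the window; returns estimate or NA
.match_term <- function(scan, type, k, l, window) {
  if (is.null(scan) || !nrow(scan)) return(NA_real_)
  rows <- scan$type == type & abs(scan$k - k) <= window
  rows <- rows & if (is.na(l)) is.na(scan$l) else
    (!is.na(scan$l) & abs(scan$l - l) <= window)
  if (!any(rows)) return(NA_real_)
  hit <- scan[rows, , drop = FALSE]
  hit$estimate[which.max(hit$lod)]
}

#' Run a Monte Carlo power and parameter-recovery study
#'
#' For each treatment (combination of `n`, `h`, `m`) and replicate: fresh
#' RIL genotypes and family phenotypes, a scan of every requested
#' transformation, and integration/dissection of the scan results. A true
#' augmented term counts as detected when a significant scan term of the
#' same kind lies at its marker index (pair: both indices) within
#' `match_window`; empirical power is the fraction of detecting
#' replicates. Means and standard deviations of augmented and dissected
#' estimates are reported over detecting replicates (conditional
#' summaries), together with a zero-imputed mean over all replicates.
#'
#' @param config A [study_config()].
#' @return List of class `attc_study`: `augmented` (per treatment x true
#'   augmented term: `truth`, `power`, `n_detect`, `mean`, `sd`,
#'   `mean_all`), `dissected` (per treatment x component effect: `truth`,
#'   `n_detect`, `mean`, `sd`, `mean_all`), `config`, and `n_lod_hits`
#'   (per treatment x replicate, total significant terms — useful for
#'   null architectures).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  arch <- config$arch; map <- config$map
  truth_aug <- .study_truth(arch)
  truth_dis <- .dissect_truth(arch)
  null_arch <- nrow(arch$qtl) == 0L ||
    (all(arch$qtl$a == 0) && all(arch$qtl$d == 0) &&
     (!nrow(arch$pairs) ||
      all(arch$pairs$iaa == 0 & arch$pairs$iad == 0 &
          arch$pairs$ida == 0 & arch$pairs$idd == 0)))
  treatments <- expand.grid(n = config$n_levels, h = config$h_levels,
                            m = config$m_levels, KEEP.OUT.ATTRS = FALSE)
  R <- config$R
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  seed_pool <- matrix(sample.int(.Machine$integer.max - 10L,
                                 2L * R * nrow(treatments)),
                      ncol = 2L)
  aug_rows <- list(); dis_rows <- list(); hit_rows <- list()
  rep_counter <- 0L
  for (ti in seq_len(nrow(treatments))) {
    n <- treatments$n[ti]; h <- treatments$h[ti]; m <- treatments$m[ti]
    aug_est <- matrix(NA_real_, R, nrow(truth_aug))
    dis_est <- matrix(NA_real_, R, nrow(truth_dis))
    n_hits <- integer(R)
    for (r in seq_len(R)) {
      rep_counter <- rep_counter + 1L
      s_geno <- seed_pool[rep_counter, 1L]; s_phen <- seed_pool[rep_counter, 2L]
      g <- simulate_ril_genotypes(map, n, seed = s_geno)
      sig_e <- config$sigma_e
      if (is.null(sig_e) && null_arch) sig_e <- 1
      per_transformation <- identical(config$calibrate, "each")
      if (!per_transformation)
        ph <- simulate_phenotypes(arch, g, h = h, m = m, seed = s_phen,
                                  transformations = config$transformations,
                                  sigma_e = sig_e,
                                  calibrate = config$calibrate)
      scans <- list()
      for (zi in seq_along(config$transformations)) {
        z <- config$transformations[zi]
        zv <- if (per_transformation)
          simulate_phenotypes(arch, g, h = h, m = m, seed = s_phen + zi,
                              transformations = z, sigma_e = sig_e,
                              calibrate = z)$Z[[z]]
        else ph$Z[[z]]
        scans[[z]] <- scan_transformation(
          zv, g, z, a = config$a, b = config$b,
          t_threshold = config$t_threshold,
          lod_threshold = config$lod_threshold, backend = config$backend)
      }
      n_hits[r] <- sum(vapply(scans, nrow, 0L))
      for (j in seq_len(nrow(truth_aug)))
        aug_est[r, j] <- .match_term(scans[[truth_aug$transformation[j]]],
                                     truth_aug$type[j], truth_aug$k[j],
                                     truth_aug$l[j], config$match_window)
      dis <- integrate_scans(scans[["Z1"]], scans[["Z2"]], scans[["Z4"]])
      for (j in seq_len(nrow(truth_dis))) {
        eff <- truth_dis$effect[j]
        if (eff %in% c("a", "d")) {
          row <- which(dis$qtl$marker == truth_dis$k[j])
          if (length(row)) dis_est[r, j] <- dis$qtl[[eff]][row[1]]
        } else {
          row <- which(dis$pairs$k == truth_dis$k[j] &
                       dis$pairs$l == truth_dis$l[j])
          if (length(row)) dis_est[r, j] <- dis$pairs[[eff]][row[1]]
        }
      }
      if (config$progress)
        message(sprintf("[%s] n=%d h=%.2f m=%d replicate %d/%d (%d terms)",
                        format(Sys.time(), "%H:%M:%S"), n, h, m, r, R,
                        n_hits[r]))
    }
    summ <- function(est, truth_tab) {
      det <- colSums(!is.na(est))
      data.frame(n = rep(n, nrow(truth_tab)), h = rep(h, nrow(truth_tab)),
                 m = rep(m, nrow(truth_tab)), truth_tab,
                 power = det / R, n_detect = det,
                 mean = ifelse(det > 0, colMeans(est, na.rm = TRUE), NA),
                 sd = apply(est, 2, stats::sd, na.rm = TRUE),
                 mean_all = colMeans(replace(est, is.na(est), 0)))
    }
    aug_rows[[ti]] <- summ(aug_est, truth_aug)
    dis_rows[[ti]] <- summ(dis_est, truth_dis)
    hit_rows[[ti]] <- data.frame(n = n, h = h, m = m,
                                 replicate = seq_len(R), n_terms = n_hits)
  }
  structure(list(augmented = do.call(rbind, aug_rows),
                 dissected = do.call(rbind, dis_rows),
                 n_lod_hits = do.call(rbind, hit_rows),
                 config = config),
            class = "attc_study")
}
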
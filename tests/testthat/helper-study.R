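# Shared Monte Carlo runs for the acceptance-level tests. The benchmark
# study (n = 800, h = 0.8, m = 10, 20 replicates) takes a few minutes, so
# it is computed once per test session and reused across test blocks.

.study_cache <- new.env(parent = emptyenv())

benchmark_study <- function() {
  if (is.null(.study_cache$benchmark))
    .study_cache$benchmark <- run_study(study_config(R = 20L, seed = 1L))
  .study_cache$benchmark
}

null_study <- function() {
  if (is.null(.study_cache$null)) {
    null_arch <- qtl_architecture(
      mu = 0, qtl = data.frame(marker = c(20L, 36L), a = 0, d = 0))
    .study_cache$null <- run_study(
      study_config(arch = null_arch, n_levels = 200, R = 20L, seed = 5L))
  }
  .study_cache$null
}

# pull one summary row out of a study table
study_row <- function(tab, ...) {
  keys <- list(...)
  rows <- rep(TRUE, nrow(tab))
  for (nm in names(keys))
    rows <- rows & !is.na(tab[[nm]]) & tab[[nm]] == keys[[nm]]
  stopifnot(sum(rows) == 1L)
  tab[rows, , drop = FALSE]
}
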
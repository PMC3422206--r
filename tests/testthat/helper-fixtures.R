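# Shared fixtures.  The full standard scenario and its pipeline run are
# expensive, so they are computed once per test session and cached.

scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function(seed = 1L) {
  key <- paste0("sim", seed)
  if (is.null(scenario_cache[[key]])) {
    scenario_cache[[key]] <- simulate_scenario(seed = seed)
  }
  scenario_cache[[key]]
}

cached_pipeline <- function(seed = 1L) {
  key <- paste0("res", seed)
  if (is.null(scenario_cache[[key]])) {
    sim <- cached_scenario(seed)
    locus <- as.list(sim$truth$layout[
      sim$truth$layout$kind == "single_copy_locus", c("chrom", "start", "end")])
    scenario_cache[[key]] <- run_censat(sim, locus = locus)
  }
  scenario_cache[[key]]
}

# a small one-chromosome simulation for unit tests
mini_sim <- function(seed = 11L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chromosomes = 1L, chrom_len = 60000L,
         blocks = c(10L, 6L, 10L), chip_n = 8000L, unplaced_frac = 0.3,
         pericentric_window = 5000L),
    list(...))
  do.call(simulate_scenario, args)
}

# adjusted Rand index between two labelings (independent of the clustering
# code under test)
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c_ / choose(n, 2)
  maxi <- (b + c_) / 2
  (a - expected) / (maxi - expected)
}

random_seq_tbl <- function(n, len, seed = 1L, prefix = "s") {
  withr::with_seed(seed, {
    seq_tbl(paste0(prefix, seq_len(n)),
            vapply(seq_len(n), function(i) {
              paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
            }, character(1)))
  })
}
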
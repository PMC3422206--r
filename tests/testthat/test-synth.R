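test_that("subfamily templates carry the requested divergence", {
  # zero divergence: identical templates
  t0 <- generate_subfamilies(738, 2, between_divergence = 0,
                             within_divergence = 0, seed = 1)
  expect_equal(t0$sequence[2], t0$sequence[3])
  expect_equal(nchar(t0$sequence[1]), 738)

  # 5% from the ancestor: pairwise difference near 2 * 0.05 * (1 - corr)
  # within 3 binomial SDs, counted by a direct mismatch oracle
  tm <- generate_subfamilies(738, 2, between_divergence = 0.05, seed = 2)
  a <- strsplit(tm$sequence[2], "")[[1]]
  b <- strsplit(tm$sequence[3], "")[[1]]
  observed <- sum(a != b)
  # two independent mutation sets of rate d; a site differs unless untouched
  # by both or coincidentally equal: p = 2d(1 - d) + d^2 * 2/3... direct:
  d <- 0.05
  p_diff <- 2 * d * (1 - d) + d * d * (2 / 3)
  expect_lt(abs(observed - 738 * p_diff), 3 * sqrt(738 * p_diff * (1 - p_diff)))

  expect_error(generate_subfamilies(738, 2, between_divergence = 0.4),
               "divergences")
})

test_that("satellite arrays have exact length and complete truth spans", {
  tm <- generate_subfamilies(300, 2, 0.05, seed = 3)
  tmpl <- tm[tm$role == "template", ]
  layout <- tibble::tibble(subfamily = c("S1", "S2"), n_monomers = c(10L, 5L))

  # zero divergence, no TE: pure template repetition
  arr0 <- build_satellite_array(tmpl, tibble::tibble(subfamily = "S1",
                                                     n_monomers = 10L),
                                within_divergence = 0, seed = 4)
  expect_equal(arr0$sequence, strrep(tmpl$sequence[tmpl$subfamily == "S1"], 10))
  expect_equal(nrow(arr0$spans), 10)

  te <- tibble::tibble(name = "TE1", sequence = strrep("ACG", 100),
                       monomer_index = 3L, offset = 150L)
  arr <- build_satellite_array(tmpl, layout, te_insertions = te,
                               within_divergence = 0.01, seed = 5)
  expect_equal(nchar(arr$sequence), 15 * 300 + 300)
  expect_true("TE1" %in% arr$spans$label[arr$spans$type == "te"])
  # spans tile the array without overlap
  sp <- dplyr::arrange(arr$spans, start)
  expect_equal(sp$start[-1], sp$end[-nrow(sp)])
  expect_equal(sp$end[nrow(sp)], nchar(arr$sequence))

  expect_error(build_satellite_array(tmpl, layout,
                                     te_insertions = tibble::tibble(
                                       name = "T", sequence = "ACGT",
                                       monomer_index = 99L, offset = 1L)),
               "out of range")
})

test_that("assembly arithmetic is exact and gaps are recorded", {
  tm <- generate_subfamilies(300, 1, 0.02, seed = 6)
  arr <- build_satellite_array(tm[tm$role == "template", ],
                               tibble::tibble(subfamily = "S1",
                                              n_monomers = 20L),
                               within_divergence = 0.01, seed = 7)
  arr$family <- "FamA"
  g <- assemble_genome(list(arr), flank_len = 12000, unplaced_frac = 0,
                       seed = 8)
  expect_equal(nrow(g$gaps), 1)
  expect_equal(nrow(g$chrun), 0)
  expect_equal(sum(nchar(g$genome$seq)),
               sum(nchar(g$assembly$seq)) + nchar(arr$sequence))

  g2 <- assemble_genome(list(arr), flank_len = 12000, unplaced_frac = 0.4,
                        gap_edge_retain = 600, seed = 9)
  expect_equal(sum(nchar(g2$genome$seq)),
               sum(nchar(g2$assembly$seq)) + nchar(arr$sequence) - 600)
  expect_gt(nrow(g2$chrun), 0)
  # retained contigs are genuine array subsequences
  expect_true(all(vapply(g2$chrun$seq, grepl, logical(1),
                         x = arr$sequence, fixed = TRUE)))
})

test_that("paired read counts follow the coverage formula and are reproducible", {
  g <- seq_tbl("chr1", withr::with_seed(10, censatr:::rand_dna(100000)))
  rr <- simulate_paired_reads(g, coverage = 7.5, read_len = 500,
                              insert_mean = 2000, insert_sd = 100, seed = 11)
  expect_equal(nrow(rr$pairs), 750)
  expect_equal(nrow(rr$reads), 1500)
  rr2 <- simulate_paired_reads(g, coverage = 7.5, read_len = 500,
                               insert_mean = 2000, insert_sd = 100, seed = 11)
  expect_identical(rr$reads, rr2$reads)
  rr3 <- simulate_paired_reads(g, coverage = 7.5, read_len = 500,
                               insert_mean = 2000, insert_sd = 100, seed = 12)
  expect_false(identical(rr$reads$seq, rr3$reads$seq))
  expect_error(simulate_paired_reads(g, coverage = -1), "coverage")
  expect_error(simulate_paired_reads(g, coverage = 5, read_len = 500,
                                     insert_mean = 900), "insert_mean")

  # right mates are reverse complements from the fragment end
  o <- rr$origin[rr$origin$strand == "-", ][1, ]
  frag <- substr(g$seq, o$start + 1, o$end)
  expect_equal(rr$reads$seq[rr$reads$id == o$read_id], revcomp(frag))

  # per-base depth at random interior positions within 4 Poisson SDs
  withr::with_seed(13, {
    pos <- sample(10000:90000, 20)
  })
  depth <- vapply(pos, function(p) {
    sum(rr$origin$start < p & rr$origin$end >= p + 1)
  }, numeric(1))
  expect_true(all(abs(depth - 7.5) <= 4 * sqrt(7.5)))
})

test_that("ChIP read origins follow the fold mixture", {
  g <- seq_tbl("chr1", withr::with_seed(14, censatr:::rand_dna(50000)))
  dom <- tibble::tibble(chrom = "chr1", start = 10000L, end = 15000L)
  # fold = 1: uniform, in-domain fraction ~ D/G
  u <- simulate_chip_reads(g, dom, fold = 1, n_reads = 5000, seed = 15)
  p0 <- 5000 / 50000
  expect_lt(abs(mean(u$labels$in_domain) - p0), 3 * sqrt(p0 * (1 - p0) / 5000))
  # fold = 10: mixture weight fold*D/(fold*D + G - D)
  e <- simulate_chip_reads(g, dom, fold = 10, n_reads = 5000, seed = 16)
  p1 <- 10 * 5000 / (10 * 5000 + 45000)
  expect_lt(abs(mean(e$labels$in_domain) - p1), 3 * sqrt(p1 * (1 - p1) / 5000))
  expect_true(all(nchar(e$reads$seq) == 72))
  expect_error(simulate_chip_reads(g, dom, fold = 10, n_reads = 0), "n_reads")
})

test_that("truth labels are consistent with the layout at read origins", {
  sim <- mini_sim()
  lt <- sim$truth$wgs_labels
  org <- sim$truth$wgs_origin
  mono <- sim$truth$monomers
  arr_lo <- min(mono$start); arr_hi <- max(mono$end)
  inside <- org$chrom == mono$chrom[1] & org$start >= arr_lo &
    org$end <= arr_hi
  # reads fully inside the array must be satellite-labeled (modulo TE bp)
  expect_gt(mean(!is.na(lt$family[inside])), 0.95)
  # reads fully in flanks are unlabeled
  outside <- org$end <= arr_lo - 1
  expect_true(all(is.na(lt$family[outside])))
  # every read id appears exactly once
  expect_equal(anyDuplicated(org$read_id), 0)
  expect_setequal(org$read_id, sim$wgs$id)
})
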
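test_that("k-mer extraction is canonical and conserves totals", {
  # every position contributes one window; reverse complements collapse
  kt <- extract_kmers(seq_tbl("a", "ACGTACGTTT"), k = 8)
  expect_equal(kt$count[kt$kmer == "ACGTACGT"], 1L)   # itself canonical
  expect_equal(kt$count[kt$kmer == "AACGTACG"], 1L)   # from CGTACGTT
  expect_equal(kmer_total(kt), 3)
  expect_equal(canonical_kmers(c("CGT", "ACG", "GTA")),
               c("ACG", "ACG", "GTA"))
  expect_error(extract_kmers(seq_tbl("a", "ACGTACGT"), k = 7), "k must be")

  # reverse-complement symmetry on random reads
  reads <- random_seq_tbl(20, 120, seed = 41)
  rc <- seq_tbl(reads$id, revcomp(reads$seq))
  t1 <- extract_kmers(reads, k = 31)
  t2 <- extract_kmers(rc, k = 31)
  expect_equal(as.data.frame(t1), as.data.frame(t2))

  # N k-mers and short reads are skipped, and the conservation law holds
  mixed <- seq_tbl(c("a", "b"), c("ACGTACGTNACGTACGTA", "ACG"))
  kt2 <- extract_kmers(mixed, k = 8)
  expect_equal(kmer_total(kt2), 11 - 8)    # 8 of 11 windows contain the N
  expect_equal(attr(kt2, "n_skipped"), 9L) # 8 N-windows + 1 short read
})

test_that("assembly subtraction removes exactly the shared k-mers", {
  reads <- random_seq_tbl(10, 200, seed = 42)
  kt <- extract_kmers(reads, k = 50)
  # assembly containing read 1 verbatim removes all its k-mers
  asm <- seq_tbl("chr", paste0(reads$seq[1], strrep("A", 60)))
  out <- subtract_assembly_kmers(kt, asm)
  r1 <- extract_kmers(reads[1, ], k = 50)
  expect_false(any(r1$kmer %in% out$kmer))
  expect_true(all(setdiff(kt$kmer, r1$kmer) %in% out$kmer))
  # empty assembly is the identity
  out2 <- subtract_assembly_kmers(kt, seq_tbl(character(), character()))
  expect_equal(nrow(out2), nrow(kt))
  # chrUn is excluded from subtraction by default
  out3 <- subtract_assembly_kmers(kt, seq_tbl("c", strrep("G", 80)),
                                  chrun = reads[2, ])
  expect_true(all(extract_kmers(reads[2, ], 50)$kmer %in% out3$kmer))
  out4 <- subtract_assembly_kmers(kt, seq_tbl("c", strrep("G", 80)),
                                  chrun = reads[2, ], exclude_chrun = FALSE)
  expect_false(any(extract_kmers(reads[2, ], 50)$kmer %in% out4$kmer))
})

test_that("single-copy calibration matches the closed form", {
  cal <- single_copy_calibration("simulated", k = 50, coverage = 7.5,
                                 read_len = 100, seed = 43)
  expect_equal(cal$mu_sc, 7.5 * 51 / 100, tolerance = 0.03)
  expect_error(single_copy_calibration("simulated", k = 50, coverage = 7.5,
                                       read_len = 50), "read_len")
  expect_error(single_copy_calibration("observed", k = 50, coverage = 7.5,
                                       read_len = 100,
                                       table = tibble::tibble(),
                                       locus_seq = "ACGT"), "locus")
})

test_that("observed-locus calibration agrees with the closed form over seeds", {
  mus <- vapply(1:10, function(s) {
    g <- seq_tbl("chr1", withr::with_seed(s + 500, censatr:::rand_dna(60000)))
    rr <- simulate_paired_reads(g, coverage = 7.5, read_len = 100,
                                insert_mean = 300, insert_sd = 20, seed = s)
    kt <- extract_kmers(rr$reads, k = 50)
    single_copy_calibration("observed", k = 50, coverage = 7.5,
                            read_len = 100, table = kt,
                            locus_seq = substr(g$seq, 20001, 24000))$mu_sc
  }, numeric(1))
  expected <- 7.5 * 51 / 100
  se <- sd(mus) / sqrt(length(mus))
  expect_lt(abs(mean(mus) - expected), 3 * max(se, 0.02))
})

test_that("copy classification applies the mu + 2 sd rule strictly", {
  cal <- structure(list(mu_sc = 3.825, sd_sc = 1.96, coverage = 7.5,
                        source = "simulated"), class = "copy_calibration")
  tab <- tibble::tibble(kmer = c("a", "b", "c"),
                        count = c(30, 3.825, 3.825 + 2 * 1.96))
  out <- classify_kmer_copy(tab, cal)
  expect_equal(out$copy_class, c("multi", "single", "single"))  # strict >
  expect_equal(out$est_copies[1], 30 / 3.825, tolerance = 1e-12)
  out2 <- classify_kmer_copy(tibble::tibble(kmer = "d",
                                            count = 3.825 + 2 * 1.96 + 1e-9),
                             cal)
  expect_equal(out2$copy_class, "multi")
})

test_that("copy classes recover planted copy numbers from simulation", {
  sim <- cached_scenario()
  res <- cached_pipeline()
  kt_all <- extract_kmers(sim$wgs, 50)
  cal <- res$calibration
  cls <- classify_kmer_copy(kt_all, cal)
  # truth: k-mers of a monomer template (high copy) vs flank k-mers
  tm <- sim$truth$templates
  s2 <- tm$sequence[tm$subfamily == "CenSatA.S2"]
  tmpl_kmers <- unique(canonical_kmers(censatr:::seq_kmers_chr(
    paste0(s2, substr(s2, 1, 49)), 50)))
  tmpl_kmers <- tmpl_kmers[tmpl_kmers %in% cls$kmer]
  multi_rate <- mean(cls$copy_class[match(tmpl_kmers, cls$kmer)] == "multi")
  expect_gte(multi_rate, 0.95)
  flank <- substr(sim$assembly$seq[1], 30001, 60000)
  fl_kmers <- unique(canonical_kmers(censatr:::seq_kmers_chr(flank, 50)))
  fl_kmers <- fl_kmers[fl_kmers %in% cls$kmer]
  single_rate <- mean(cls$copy_class[match(fl_kmers, cls$kmer)] == "single")
  expect_gte(single_rate, 0.95)
})

test_that("junction k-mers straddle class boundaries with full counts", {
  s <- random_seq_tbl(1, 400, seed = 44)
  spans <- tibble::tibble(seq_id = s$id, start = c(0L, 150L, 250L),
                          end = c(150L, 250L, 400L),
                          label = c("SF1", "TE1", "SF1"),
                          type = c("satellite", "te", "satellite"))
  jk <- junction_kmers(s, spans, k = 50)
  # two satellite|te boundaries, 49 windows each
  expect_equal(nrow(jk), 98)
  expect_setequal(unique(jk$junction), c("SF1|TE1", "TE1|SF1"))
  # boundary near the sequence edge yields fewer windows, never negative
  spans_edge <- tibble::tibble(seq_id = s$id, start = c(0L, 380L),
                               end = c(380L, 400L), label = c("SF1", "TE1"),
                               type = c("satellite", "te"))
  jke <- junction_kmers(s, spans_edge, k = 50)
  expect_lt(nrow(jke), 49)
  expect_gt(nrow(jke), 0)
  # satellite blocks of the same class yield no junction
  spans_sat <- tibble::tibble(seq_id = s$id, start = c(0L, 200L),
                              end = c(200L, 400L), label = c("A", "B"),
                              type = "satellite")
  expect_equal(nrow(junction_kmers(s, spans_sat, k = 50)), 0)
})

test_that("planted TE junction k-mers survive assembly subtraction", {
  sim <- cached_scenario()
  res <- cached_pipeline()
  # truth junction k-mers around the planted TE
  mono <- sim$truth$monomers
  te <- mono[mono$type == "te", ]
  expect_equal(nrow(te), 1)
  genome_chr <- sim$genome$seq[sim$genome$id == te$chrom]
  tr_spans <- tibble::tibble(seq_id = te$chrom, start = mono$start,
                             end = mono$end, label = mono$label,
                             type = mono$type)[mono$chrom == te$chrom, ]
  jk <- junction_kmers(seq_tbl(te$chrom, genome_chr), tr_spans, k = 50)
  te_jk <- jk$kmer[grepl("TE1", jk$junction)]
  expect_gte(sum(unique(te_jk) %in% res$kmers$kmer), 1)
})
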
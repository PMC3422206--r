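make_density <- function(masked_adj, masked_other, n_other = 18) {
  tibble::tibble(
    chrom = "chr1",
    start = as.integer(seq(0, by = 1000, length.out = 2 + n_other)),
    end = as.integer(seq(1000, by = 1000, length.out = 2 + n_other)),
    gap_adjacent = c(TRUE, TRUE, rep(FALSE, n_other)),
    family = "F",
    masked_bp = c(masked_adj, masked_other)
  )
}

test_that("pericentric fold uses the 1 bp pseudocount", {
  d <- make_density(c(1000, 1000), rep(10, 18))
  pe <- pericentric_enrichment(d, n_permutations = 200, seed = 1)
  expect_equal(pe$fold, (1000 + 1) / (10 + 1), tolerance = 1e-12)
})

test_that("uniform families are not pericentrically enriched", {
  withr::with_seed(2, {
    d <- make_density(rpois(2, 50), rpois(18, 50))
  })
  pe <- pericentric_enrichment(d, n_permutations = 500, seed = 3)
  expect_lt(abs(pe$fold - 1), 0.5)
  expect_gt(pe$p_value, 0.05)
})

test_that("a pericentric-only family attains the permutation floor", {
  # enough windows that re-drawing the true labeling is rare: p sits at
  # the permutation floor 1/(N+1) up to those coincidences
  d <- make_density(c(5000, 5000), rep(0, 58), n_other = 58)
  pe <- pericentric_enrichment(d, n_permutations = 1000, seed = 4)
  expect_gte(pe$p_value, 1 / 1001)
  expect_lte(pe$p_value, 5 / 1001)
  expect_error(pericentric_enrichment(dplyr::mutate(d, gap_adjacent = FALSE)),
               "no gap-adjacent")
})

test_that("permutation p-values are valid under the null", {
  # scattered family: p <= 0.05 in at most 7% of runs
  sig <- vapply(1:200, function(s) {
    d <- withr::with_seed(s + 1000, make_density(rpois(2, 30), rpois(18, 30)))
    pericentric_enrichment(d, n_permutations = 200, seed = s)$p_value <= 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.07)
})

test_that("windowed density tiles from the gap and conserves masked bp", {
  asm <- tibble::tibble(chrom = "chr1", length = 10500L)
  gaps <- tibble::tibble(seq_id = "chr1", start = 10499L, end = 10500L,
                         label = "centromere_gap", strand = "+", identity = 1)
  ann <- tibble::tibble(seq_id = "chr1", start = c(9000L, 1200L),
                        end = c(10400L, 1500L), label = "F", strand = "+",
                        identity = 1, type = "satellite")
  d <- windowed_family_density(ann, gaps, asm, window_len = 2000)
  expect_equal(nrow(d), 5)                       # partial far-end window dropped
  expect_equal(sum(d$gap_adjacent), 1)
  expect_equal(d$end[d$gap_adjacent], 10500L)    # anchored at the gap
  # conservation over windows (all annotation falls inside full windows)
  expect_equal(sum(d$masked_bp), 1400 + 300)
  # family present only next to the gap has zero density elsewhere
  d2 <- windowed_family_density(ann[1, ], gaps, asm, window_len = 2000)
  expect_equal(d2$masked_bp[!d2$gap_adjacent], rep(0, 4))
})

test_that("oversized windows degrade to one whole-chromosome window", {
  asm <- tibble::tibble(chrom = "c", length = 900L)
  gaps <- tibble::tibble(seq_id = "c", start = 899L, end = 900L,
                         label = "centromere_gap", strand = "+", identity = 1)
  ann <- tibble::tibble(seq_id = "c", start = 0L, end = 100L, label = "F",
                        strand = "+", identity = 1, type = "satellite")
  expect_warning(d <- windowed_family_density(ann, gaps, asm, 2000),
                 "whole-chromosome")
  expect_equal(nrow(d), 1)
})

test_that("mate-pair networks count nodes and edges conservatively", {
  classes <- tibble::tibble(read_id = c("p1/1", "p1/2", "p2/1", "p2/2",
                                        "p3/1", "p3/2"),
                            class = c("A", "A", "A", "B", "B", "B"))
  pairs <- tibble::tibble(pair_id = c("p1", "p2", "p3"),
                          left_id = c("p1/1", "p2/1", "p3/1"),
                          right_id = c("p1/2", "p2/2", "p3/2"))
  net <- mate_pair_matrix(classes, pairs)
  expect_equal(sum(net$edges$count), nrow(pairs))
  expect_equal(net$edges$count[net$edges$a == "A" & net$edges$b == "A"], 1L)
  expect_equal(net$edges$count[net$edges$a == "A" & net$edges$b == "B"], 1L)
  expect_equal(sum(net$nodes$weight), nrow(classes))
  bad <- pairs; bad$right_id[1] <- "ghost"
  expect_error(mate_pair_matrix(classes, bad), "ghost")
})

test_that("seed expansion honors the mate-pair threshold and is monotone", {
  net <- structure(list(
    nodes = tibble::tibble(label = c("A", "B", "C", "nonsatellite"),
                           weight = c(10L, 5L, 3L, 100L)),
    edges = tibble::tibble(a = c("A", "B", "A"),
                           b = c("B", "C", "nonsatellite"),
                           count = c(12L, 3L, 500L)),
    edge_threshold = 0L), class = "pair_network")
  ex <- seed_network_expansion(net, "A", min_pair_edge = 10)
  expect_setequal(ex$anchored, c("A", "B"))           # B via 12 pairs, C not
  ex1 <- seed_network_expansion(net, "A", min_pair_edge = 1)
  expect_setequal(ex1$anchored, c("A", "B", "C"))     # all family nodes
  # monotone: raising the threshold never adds families
  for (thr in c(2, 5, 13, 100)) {
    expect_true(all(seed_network_expansion(net, "A", thr)$anchored %in%
                      ex1$anchored))
  }
  expect_error(seed_network_expansion(net, "Z"), "unknown seed")
})

test_that("expansion read accounting is disjoint and complete", {
  sim <- cached_scenario()
  res <- cached_pipeline()
  ex <- res$expansion
  expect_equal(anyDuplicated(ex$reads$read_id), 0)
  n_cls <- sum(ex$reads$source == "classified")
  n_resc <- sum(ex$reads$source == "mate_rescued")
  expect_equal(nrow(ex$reads), n_cls + n_resc)
  # rescued reads are exactly the mates of classified reads not themselves
  # classified to an anchored family
  expect_gt(n_resc, 0)
})

test_that("TE co-occurrence matches the rate-ratio arithmetic", {
  # 2x2 table [[20, 80], [10, 190]]: 100 reads carry family-A sequence,
  # 30 reads carry the TE, 20 of them on A-containing reads
  classes <- tibble::tibble(
    read_id = paste0("r", 1:300),
    class = c(rep("A", 100), rep("nonsatellite", 200)))
  te_reads <- c(paste0("r", 1:20), paste0("r", 101:110))
  spans <- dplyr::bind_rows(
    tibble::tibble(seq_id = paste0("r", 1:100), start = 100L, end = 400L,
                   label = "A", strand = "+", identity = 1,
                   type = "satellite"),
    tibble::tibble(seq_id = te_reads, start = 0L, end = 60L,
                   label = "TE1", strand = "+", identity = 1, type = "te"))
  te <- te_cooccurrence(classes, spans)
  expect_equal(te$fold, (20 / 100) / (10 / 200))
  # Fisher p agrees with the exhaustive hypergeometric oracle
  p_oracle <- local({
    a <- 20; m <- 100; n <- 200; k <- 30
    probs <- stats::dhyper(0:30, m, n, k)
    sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
  })
  expect_equal(te$p_value, p_oracle, tolerance = 1e-8)
})

test_that("identical TE rates give fold 1", {
  classes <- tibble::tibble(read_id = paste0("r", 1:100),
                            class = rep(c("A", "nonsatellite"), each = 50))
  te_reads <- c(paste0("r", 1:10), paste0("r", 51:60))
  spans <- dplyr::bind_rows(
    tibble::tibble(seq_id = paste0("r", 1:50), start = 100L, end = 400L,
                   label = "A", strand = "+", identity = 1,
                   type = "satellite"),
    tibble::tibble(seq_id = te_reads, start = 0L, end = 60L,
                   label = "TE1", strand = "+", identity = 1, type = "te"))
  te <- te_cooccurrence(classes, spans)
  expect_equal(te$fold, 1)
  expect_gt(te$p_value, 0.99)
})
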
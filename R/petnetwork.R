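# Anchoring satellite families to centromeric regions: windowed density in
# the gapped assembly, fold enrichment next to centromere gaps, mate-pair
# family networks, seed expansion into the centromeric read database, and
# TE co-occurrence.

#' Per-window satellite density in a gapped assembly
#'
#' Tiles each assembly chromosome with fixed windows anchored at the
#' centromere-gap side (so the gap-adjacent window is always full-length),
#' sums annotated bp per family per window, and flags windows within
#' `pericentric_window` of a gap.
#'
#' @param annotations spans over assembly chromosomes.
#' @param gaps gap marker spans (one per gapped chromosome), as produced by
#'   [assemble_genome()].
#' @param chrom_lengths tibble `(chrom, length)` or a sequence tibble of
#'   assembly chromosomes.
#' @param window_len window size in bp.
#' @param pericentric_window distance from a gap within which windows are
#'   flagged `gap_adjacent` (defaults to `window_len`).
#' @return Tibble `(chrom, start, end, gap_adjacent, family, masked_bp)`
#'   with a row per window and annotated family (plus an `"(none)"` row for
#'   windows with no annotation, so window counts are preserved).
#' @export
windowed_family_density <- function(annotations, gaps, chrom_lengths,
                                    window_len,
                                    pericentric_window = window_len) {
  if ("seq" %in% names(chrom_lengths)) {
    chrom_lengths <- tibble(chrom = chrom_lengths$id,
                            length = nchar(chrom_lengths$seq))
  }
  wins <- list()
  for (i in seq_len(nrow(chrom_lengths))) {
    ch <- chrom_lengths$chrom[i]; len <- chrom_lengths$length[i]
    gap <- gaps[gaps$seq_id == ch, , drop = FALSE]
    if (window_len > len) {
      warn(sprintf("window_len exceeds %s; using one whole-chromosome window",
                   ch))
      starts <- 0L; ends <- len
    } else if (nrow(gap) > 0 && gap$end[1] >= len - 1) {
      # gap at the chromosome end: tile backwards from the gap
      ends <- seq(len, window_len, by = -window_len)
      starts <- ends - window_len
    } else {
      starts <- seq(0L, len - window_len, by = window_len)
      ends <- starts + window_len
    }
    gpos <- if (nrow(gap) > 0) gap$end[1] else NA_integer_
    adj <- if (is.na(gpos)) rep(FALSE, length(starts)) else
      (pmin(ends, gpos) > pmax(starts, gpos - pericentric_window))
    wins[[ch]] <- tibble(chrom = ch, start = as.integer(starts),
                         end = as.integer(ends), gap_adjacent = adj)
  }
  wins <- bind_rows(wins) |> arrange(.data$chrom, .data$start)
  fams <- sort(unique(annotations$label))
  if (length(fams) == 0) {
    wins$family <- "(none)"; wins$masked_bp <- 0
    return(wins)
  }
  grid <- tidyr::crossing(wins, family = fams)
  grid$masked_bp <- 0
  for (f in fams) {
    sp <- annotations[annotations$label == f, , drop = FALSE]
    for (ch in unique(sp$seq_id)) {
      wi <- which(grid$family == f & grid$chrom == ch)
      if (length(wi) == 0) next
      sr <- IRanges::reduce(IRanges::IRanges(sp$start[sp$seq_id == ch] + 1L,
                                             sp$end[sp$seq_id == ch]))
      qr <- IRanges::IRanges(grid$start[wi] + 1L, grid$end[wi])
      hits <- IRanges::findOverlaps(qr, sr)
      if (length(hits) == 0) next
      w <- IRanges::width(IRanges::pintersect(
        qr[S4Vectors::queryHits(hits)], sr[S4Vectors::subjectHits(hits)]))
      bp <- tapply(w, S4Vectors::queryHits(hits), sum)
      grid$masked_bp[wi[as.integer(names(bp))]] <- as.numeric(bp)
    }
  }
  grid
}

#' Pericentric fold enrichment with a permutation p-value
#'
#' For each family, the fold is the mean masked bp per gap-adjacent window
#' over the mean in the remaining windows, with a pseudocount of 1 bp per
#' window on both sides (families absent from the background would
#' otherwise give infinite folds).  The p-value permutes the gap-adjacent
#' flag over windows: `p = (1 + #{perm fold >= observed}) / (1 + N)`.
#'
#' @param densities window density tibble from [windowed_family_density()].
#' @param n_permutations permutation count (default 1000).
#' @param seed optional integer seed.
#' @return Tibble `(family, fold, p_value, mean_adjacent_bp, mean_other_bp)`.
#' @export
pericentric_enrichment <- function(densities, n_permutations = 1000L,
                                   seed = NULL) {
  wins <- densities |> distinct(.data$chrom, .data$start, .data$gap_adjacent)
  if (!any(wins$gap_adjacent)) abort("no gap-adjacent windows")
  if (sum(!wins$gap_adjacent) < 2) {
    abort("need at least 2 non-gap-adjacent windows")
  }
  wide <- densities |>
    tidyr::pivot_wider(id_cols = c("chrom", "start", "gap_adjacent"),
                       names_from = "family", values_from = "masked_bp",
                       values_fill = 0)
  flag <- wide$gap_adjacent
  M <- as.matrix(wide[, setdiff(names(wide), c("chrom", "start",
                                               "gap_adjacent")),
                      drop = FALSE])
  fold_fun <- function(fl) {
    (colMeans(M[fl, , drop = FALSE]) + 1) /
      (colMeans(M[!fl, , drop = FALSE]) + 1)
  }
  obs <- fold_fun(flag)
  with_seed_opt(seed, function() {
    n_ge <- numeric(ncol(M))
    for (b in seq_len(n_permutations)) {
      n_ge <- n_ge + (fold_fun(sample(flag)) >= obs)
    }
    tibble(family = colnames(M), fold = unname(obs),
           p_value = unname((1 + n_ge) / (1 + n_permutations)),
           mean_adjacent_bp = unname(colMeans(M[flag, , drop = FALSE])),
           mean_other_bp = unname(colMeans(M[!flag, , drop = FALSE])))
  })
}

#' Mate-pair family network
#'
#' Nodes are read class labels weighted by read count; an edge between two
#' labels counts the mate pairs whose reads carry those labels (self-edges
#' count intra-family pairs).
#'
#' @param read_classes tibble `(read_id, class)` from [classify_reads()].
#' @param pairs mate-pair tibble `(pair_id, left_id, right_id)`.
#' @param edge_threshold edges below this count are dropped from the edge
#'   table (default 0 keeps all; [seed_network_expansion()] applies the
#'   network threshold).
#' @return A `pair_network`: `list(nodes, edges, edge_threshold)` with
#'   `nodes = (label, weight)` and `edges = (a, b, count)`, `a <= b`.
#' @export
mate_pair_matrix <- function(read_classes, pairs, edge_threshold = 0L) {
  cls <- setNames(read_classes$class, read_classes$read_id)
  la <- cls[pairs$left_id]; lb <- cls[pairs$right_id]
  dangling <- c(pairs$left_id[is.na(la)], pairs$right_id[is.na(lb)])
  if (length(dangling) > 0) {
    abort(paste0("mate id(s) without a class label: ",
                 paste(head(dangling, 5), collapse = ", ")))
  }
  nodes <- read_classes |> count(label = .data$class, name = "weight")
  e <- tibble(a = pmin(la, lb), b = pmax(la, lb)) |>
    count(.data$a, .data$b, name = "count") |>
    filter(.data$count >= edge_threshold)
  structure(list(nodes = nodes, edges = e,
                 edge_threshold = as.integer(edge_threshold)),
            class = "pair_network")
}

#' @export
print.pair_network <- function(x, ...) {
  cat(sprintf("<pair_network> %d nodes, %d edges (threshold %d)\n",
              nrow(x$nodes), nrow(x$edges), x$edge_threshold))
  invisible(x)
}

#' Expand seed families through the mate-pair network
#'
#' Breadth-first closure from the seed families over edges carrying at
#' least `min_pair_edge` mate pairs, restricted to family nodes (the
#' `"nonsatellite"` and `"mixed"` pools are not traversed).  The centromeric
#' read set is every read classified to an anchored family plus every read
#' mate-paired to such a read — capturing satellite-adjacent non-satellite
#' sequence.
#'
#' @param network a `pair_network`.
#' @param seed_families character vector of seed labels (must be nodes).
#' @param min_pair_edge edge threshold (default 10 mate pairs).
#' @param read_classes,pairs the tables behind the network, used to build
#'   the read set; omit to get only the anchored family set.
#' @return `list(anchored, reads)`; `reads` is a tibble
#'   `(read_id, source)` with `source` either `"classified"` or
#'   `"mate_rescued"` (disjoint sets).
#' @export
seed_network_expansion <- function(network, seed_families,
                                   min_pair_edge = 10L,
                                   read_classes = NULL, pairs = NULL) {
  labels <- network$nodes$label
  unknown <- setdiff(seed_families, labels)
  if (length(unknown) > 0) {
    abort(paste0("unknown seed label(s): ", paste(unknown, collapse = ", ")))
  }
  blocked <- c("nonsatellite", "mixed")
  e <- network$edges |> filter(.data$count >= min_pair_edge,
                               !.data$a %in% blocked,
                               !.data$b %in% blocked)
  anchored <- unique(seed_families)
  frontier <- anchored
  while (length(frontier) > 0) {
    nb <- unique(c(e$b[e$a %in% frontier], e$a[e$b %in% frontier]))
    frontier <- setdiff(nb, anchored)
    anchored <- c(anchored, frontier)
  }
  anchored <- sort(anchored)
  reads <- NULL
  if (!is.null(read_classes) && !is.null(pairs)) {
    classified <- read_classes$read_id[read_classes$class %in% anchored]
    mate_of <- c(setNames(pairs$right_id, pairs$left_id),
                 setNames(pairs$left_id, pairs$right_id))
    rescued <- setdiff(unname(mate_of[classified]), classified)
    rescued <- rescued[!is.na(rescued)]
    reads <- bind_rows(
      tibble(read_id = classified, source = "classified"),
      tibble(read_id = rescued, source = "mate_rescued"))
    censat_log(sprintf(
      "network expansion: %d anchored families; %d classified + %d rescued reads",
      length(anchored), length(classified), length(rescued)))
  }
  list(anchored = anchored, reads = reads)
}

#' Transposable element co-occurrence within satellite reads
#'
#' For each (satellite family, TE) pair, builds the 2x2 read table
#' (contains family sequence yes/no x contains TE yes/no), reports the
#' rate ratio and the two-sided Fisher exact p-value.  Membership is by
#' annotated content — a read "contains" a family or TE when it carries at
#' least one annotated span of it — since an embedded TE displaces
#' satellite bp and would otherwise push its host reads out of a
#' majority-class definition.  Zero-margin tables yield `NA` fold.
#'
#' @param read_classes tibble `(read_id, class)` defining the read
#'   universe.
#' @param spans annotation spans over the same reads (`type` column
#'   distinguishes `"satellite"` from `"te"`).
#' @return Tibble `(family, te, n_family_te, n_family, n_te, n_reads, fold,
#'   p_value)`.
#' @export
te_cooccurrence <- function(read_classes, spans) {
  te_by_read <- spans |> filter(.data$type == "te") |>
    distinct(.data$seq_id, te = .data$label)
  fam_by_read <- spans |> filter(.data$type == "satellite") |>
    distinct(.data$seq_id, family = .data$label)
  fams <- unique(fam_by_read$family)
  tes <- unique(te_by_read$te)
  out <- list()
  N <- nrow(read_classes)
  for (f in fams) {
    in_f <- read_classes$read_id %in%
      fam_by_read$seq_id[fam_by_read$family == f]
    for (t in tes) {
      has_t <- read_classes$read_id %in%
        te_by_read$seq_id[te_by_read$te == t]
      a <- sum(in_f & has_t); b <- sum(in_f & !has_t)
      c_ <- sum(!in_f & has_t); d <- sum(!in_f & !has_t)
      fold <- if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0) NA_real_
              else (a / (a + b)) / if (c_ > 0) (c_ / (c_ + d)) else
                (0.5 / (c_ + d))  # Haldane-style continuity when no outside hits
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
      out[[length(out) + 1]] <- tibble(
        family = f, te = t, n_family_te = a, n_family = a + b, n_te = a + c_,
        n_reads = N, fold = fold, p_value = p)
    }
  }
  if (length(out) == 0) {
    return(tibble(family = character(), te = character(),
                  n_family_te = integer(), n_family = integer(),
                  n_te = integer(), n_reads = integer(), fold = double(),
                  p_value = double()))
  }
  bind_rows(out)
}
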
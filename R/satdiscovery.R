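# Phase I: tandem repeat detection, non-redundant satellite family
# construction, read classification, unmasked-segment extraction and array
# size estimation.

#' Detect tandem repeats
#'
#' A simplified tandem repeat finder: candidate periods are the spacings at
#' which exact 12-mers recur; each candidate span is validated by folding it
#' at the period and scoring it against the column-majority (wraparound)
#' consensus.  Overlapping hits are resolved to the highest score
#' (identity x span length).  Score parity with alignment-matrix tandem
#' repeat engines is not attempted; recovery of planted periods and spans is
#' the contract.
#'
#' @param seqs sequence tibble.
#' @param min_period,max_period period search range in bp (max 2000 mirrors
#'   the satellite discovery ceiling used at study scale).
#' @param min_copies minimum copy number of a reported hit.
#' @param min_frac_identity minimum identity of the span to its period
#'   consensus.
#' @return Tibble `(seq_id, start, end, period, copy_number, consensus,
#'   identity, score)`; 0-based half-open coordinates.
#' @export
detect_tandem_repeats <- function(seqs, min_period = 10L, max_period = 2000L,
                                  min_copies = 3L, min_frac_identity = 0.8) {
  if (min_period < 2) abort("min_period must be >= 2")
  bind_rows(lapply(seq_len(nrow(seqs)), function(i) {
    detect_tandem_one(seqs$id[i], seqs$seq[i], min_period, max_period,
                      min_copies, min_frac_identity)
  }))
}

detect_tandem_one <- function(id, seq, min_period, max_period, min_copies,
                              min_frac_identity) {
  empty <- tibble(seq_id = character(), start = integer(), end = integer(),
                  period = integer(), copy_number = double(),
                  consensus = character(), identity = double(),
                  score = double())
  n <- nchar(seq)
  if (n < 2 * min_period) return(empty)
  max_period <- min(max_period, n %/% 2)
  kms <- seq_kmers_chr(seq, SEED_K)
  pos <- seq_along(kms) - 1L
  keep <- !grepl("N", kms, fixed = TRUE)
  grp <- split(pos[keep], kms[keep])
  grp <- grp[lengths(grp) >= 2]
  if (length(grp) == 0) return(empty)
  sp_pos <- list(); sp_d <- list()
  for (g in grp) {
    d <- diff(g)
    ok <- d >= min_period & d <= max_period
    sp_pos[[length(sp_pos) + 1]] <- g[-length(g)][ok]
    sp_d[[length(sp_d) + 1]] <- d[ok]
  }
  sp_pos <- unlist(sp_pos); sp_d <- unlist(sp_d)
  if (length(sp_d) == 0) return(empty)
  counts <- sort(table(sp_d), decreasing = TRUE)
  cand <- as.integer(names(counts[counts >= max(2, min_copies - 1)]))
  if (length(cand) == 0) return(empty)
  cand <- sort(cand)
  seq_chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hits <- list()
  for (p in cand) {
    support <- sort(sp_pos[sp_d == p])
    runs <- merge_runs(support, SEED_K + p, gap = 2L * p)
    for (r in seq_len(nrow(runs))) {
      s0 <- runs$start[r]; s1 <- min(runs$end[r], n)
      span_len <- s1 - s0
      if (span_len < 2 * p * 0.9) next
      cons <- wrap_consensus(seq_chars, s0, s1, p)
      ident <- cons$identity
      copies <- span_len / p
      if (copies >= min_copies && ident >= min_frac_identity) {
        hits[[length(hits) + 1]] <- tibble(
          seq_id = id, start = as.integer(s0), end = as.integer(s1),
          period = as.integer(p), copy_number = copies,
          consensus = cons$consensus, identity = ident,
          score = ident * span_len)
      }
    }
  }
  if (length(hits) == 0) return(empty)
  hits <- bind_rows(hits) |> arrange(desc(.data$score), .data$period)
  # greedy overlap resolution to the highest score
  kept <- rep(FALSE, nrow(hits))
  for (j in seq_len(nrow(hits))) {
    if (!any(kept)) { kept[j] <- TRUE; next }
    prev <- hits[kept, , drop = FALSE]
    ov <- pmax(0, pmin(prev$end, hits$end[j]) - pmax(prev$start, hits$start[j]))
    if (all(ov <= 0.5 * (hits$end[j] - hits$start[j]))) kept[j] <- TRUE
  }
  hits[kept, , drop = FALSE] |> arrange(.data$start)
}

# column-majority consensus over the monomer stack obtained by folding
# [s0, s1) at period p, and the identity of the span to it
wrap_consensus <- function(seq_chars, s0, s1, p) {
  idx <- (s0 + 1):s1
  col <- ((idx - s0 - 1) %% p) + 1
  ch <- seq_chars[idx]
  best <- character(p)
  for (b in c("A", "C", "G", "T")) {
    cnt <- tabulate(col[ch == b], nbins = p)
    if (b == "A") {
      bestcnt <- cnt; best <- rep(b, p)
    } else {
      upd <- cnt > bestcnt
      best[upd] <- b; bestcnt[upd] <- cnt[upd]
    }
  }
  list(consensus = paste(best, collapse = ""),
       identity = mean(ch == best[col]))
}

#' Cluster tandem repeat consensi into satellite families
#'
#' Single-linkage clustering over pairwise local alignments; two consensi
#' are linked when their best alignment (both strands, all circular
#' rotations of the shorter, realized by aligning against the doubled
#' longer sequence) exceeds `min_identity` over at least `min_overlap`
#' aligned bp.  Each family's consensus is the medoid (maximum summed
#' identity to the other members); families are named `SF001`, `SF002`, ...
#' by decreasing member count.
#'
#' @param consensi character vector of consensus sequences (optionally
#'   named).
#' @param min_identity linking identity (default 0.95, i.e. the >95% rule).
#' @param min_overlap minimum aligned length in bp (default 100).
#' @return Tibble `(name, consensus, period, n_members, members)`.
#' @export
cluster_consensi <- function(consensi, min_identity = 0.95,
                             min_overlap = 100L) {
  if (length(consensi) == 0) abort("consensi must be non-empty")
  n <- length(consensi)
  if (is.null(names(consensi))) names(consensi) <- paste0("cons", seq_len(n))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  mat <- sub_matrix()
  pair_identity <- function(a, b) {
    if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
    subj <- Biostrings::DNAString(paste0(b, b))
    best <- c(0, 0)
    for (s in c(a, revcomp(a))) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(s), subj, type = "local",
        substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
      w <- Biostrings::nchar(pa)  # alignment length
      pidv <- Biostrings::pid(pa, type = "PID1") / 100
      if (pidv * w > best[1] * best[2]) best <- c(pidv, w)
    }
    best
  }
  ident_mat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pi <- pair_identity(consensi[i], consensi[j])
      ident_mat[i, j] <- ident_mat[j, i] <- pi[1]
      if (pi[1] > min_identity && pi[2] >= min_overlap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  comp <- comp[order(-lengths(comp), vapply(comp, min, integer(1)))]
  bind_rows(lapply(seq_along(comp), function(ci) {
    members <- comp[[ci]]
    medoid <- members[which.max(colSums(ident_mat[members, members,
                                                  drop = FALSE]))]
    tibble(name = sprintf("SF%03d", ci),
           consensus = unname(consensi[medoid]),
           period = nchar(consensi[medoid]),
           n_members = length(members),
           members = list(names(consensi)[members]))
  }))
}

#' Identity of a query to a (circular) reference consensus
#'
#' Best local-alignment identity of `query` against `reference` (doubled
#' when `circular`, so every monomer rotation is reachable), over both
#' strands.
#'
#' @param query,reference sequences.
#' @param circular treat the reference as circular (default TRUE).
#' @return Identity fraction (PID1) of the best alignment.
#' @export
consensus_identity <- function(query, reference, circular = TRUE) {
  subj <- Biostrings::DNAString(if (circular) paste0(reference, reference)
                                else reference)
  mat <- sub_matrix()
  best <- 0
  for (s in c(query, revcomp(query))) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(s), subj, type = "local",
      substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
    best <- max(best, Biostrings::pid(pa, type = "PID1") / 100)
  }
  best
}

#' Discover satellite families from sequences
#'
#' Convenience wrapper: tandem repeat detection on the input sequences
#' (typically unplaced contigs) followed by consensus clustering into a
#' non-redundant family library.
#'
#' @param seqs sequence tibble.
#' @inheritParams detect_tandem_repeats
#' @inheritParams cluster_consensi
#' @return `list(hits, families)` where `families` is ready to use as the
#'   satellite part of an annotation library (`type = "satellite"`).
#' @export
discover_families <- function(seqs, min_period = 10L, max_period = 2000L,
                              min_copies = 3L, min_frac_identity = 0.8,
                              min_identity = 0.95, min_overlap = 100L) {
  hits <- detect_tandem_repeats(seqs, min_period, max_period, min_copies,
                                min_frac_identity)
  if (nrow(hits) == 0) {
    return(list(hits = hits,
                families = tibble(name = character(), sequence = character(),
                                  type = character())))
  }
  fams <- cluster_consensi(setNames(hits$consensus,
                                    paste0(hits$seq_id, ":", hits$start)),
                           min_identity, min_overlap)
  censat_log(sprintf("family discovery: %d tandem hits -> %d families",
                     nrow(hits), nrow(fams)))
  list(hits = hits,
       families = tibble(name = fams$name, sequence = fams$consensus,
                         type = "satellite"),
       clusters = fams)
}

#' Classify reads by their annotated satellite content
#'
#' A read is assigned the satellite family with the most masked bp when that
#' family covers at least half the read, `"mixed"` when no family reaches
#' half but two families each cover at least a quarter, and
#' `"nonsatellite"` otherwise.
#'
#' @param reads sequence tibble.
#' @param spans annotation spans from [annotate_sequences()] (already
#'   overlap-resolved).
#' @param min_family_frac fraction of the read a family must cover.
#' @param mixed_frac per-family fraction forcing the `"mixed"` label.
#' @return Tibble `(read_id, class, masked_bp, top_family, top_bp)`.
#' @export
classify_reads <- function(reads, spans, min_family_frac = 0.5,
                           mixed_frac = 0.25) {
  read_len <- setNames(nchar(reads$seq), reads$id)
  sat <- spans[spans$type == "satellite", , drop = FALSE]
  base <- tibble(read_id = reads$id, class = "nonsatellite",
                 masked_bp = 0L, top_family = NA_character_, top_bp = 0L)
  if (nrow(sat) == 0) return(base)
  per <- sat |>
    mutate(bp = .data$end - .data$start) |>
    group_by(.data$seq_id, .data$label) |>
    summarise(bp = sum(.data$bp), .groups = "drop")
  cls <- per |> group_by(.data$seq_id) |>
    arrange(desc(.data$bp), .by_group = TRUE) |>
    summarise(
      masked_bp = sum(.data$bp),
      top_family = first(.data$label), top_bp = first(.data$bp),
      second_bp = if (n() > 1) .data$bp[2] else 0L,
      .groups = "drop")
  cls$len <- read_len[cls$seq_id]
  cls$class <- ifelse(
    cls$top_bp >= min_family_frac * cls$len, cls$top_family,
    ifelse(cls$top_bp >= mixed_frac * cls$len &
             cls$second_bp >= mixed_frac * cls$len, "mixed", "nonsatellite"))
  out <- base
  m <- match(cls$seq_id, out$read_id)
  out$class[m] <- cls$class
  out$masked_bp[m] <- as.integer(cls$masked_bp)
  out$top_family[m] <- cls$top_family
  out$top_bp[m] <- as.integer(cls$top_bp)
  out
}

#' Extract unmasked segments
#'
#' Complements the masked spans on each sequence and reports contiguous
#' unmasked stretches of at least `min_len` bp (the candidates for novel,
#' non-repetitive sequence adjacent to satellites).
#'
#' @param seqs sequence tibble.
#' @param spans annotation spans.
#' @param min_len minimum segment length (default 100).
#' @return Span tibble labeled `"unmasked"`.
#' @export
extract_unmasked_segments <- function(seqs, spans, min_len = 100L) {
  out <- lapply(seq_len(nrow(seqs)), function(i) {
    len <- nchar(seqs$seq[i])
    df <- spans[spans$seq_id == seqs$id[i], , drop = FALSE]
    masked <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
    free <- IRanges::setdiff(IRanges::IRanges(1L, len), masked)
    free <- free[IRanges::width(free) >= min_len]
    if (length(free) == 0) return(NULL)
    tibble(seq_id = seqs$id[i], start = IRanges::start(free) - 1L,
           end = IRanges::end(free), label = "unmasked", strand = "+",
           identity = NA_real_)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(seq_id = character(), start = integer(), end = integer(),
                  label = character(), strand = character(),
                  identity = double())
  }
  res
}

#' Estimate genomic array size from read-space satellite content
#'
#' With reads at `coverage`-fold depth, the genomic bp of a satellite
#' family is its total masked bp across reads divided by the coverage.
#'
#' @param total_masked_bp masked bp summed over reads (per family).
#' @param coverage fold read coverage.
#' @return Estimated array size in bp (vectorized over families).
#' @export
#' @examples
#' estimate_array_size(327.5e6, 7.5) / 1e6  # ~43.7 Mb
estimate_array_size <- function(total_masked_bp, coverage) {
  if (any(coverage <= 0)) abort("coverage must be positive")
  total_masked_bp / coverage
}

#' Per-family masked bp and array size estimates over a read set
#'
#' @param spans annotation spans over reads.
#' @param coverage fold read coverage.
#' @return Tibble `(family, masked_bp, est_array_bp)` for satellite labels.
#' @export
family_array_sizes <- function(spans, coverage) {
  sat <- spans[spans$type == "satellite", , drop = FALSE]
  sat |>
    mutate(bp = .data$end - .data$start) |>
    group_by(family = .data$label) |>
    summarise(masked_bp = sum(.data$bp), .groups = "drop") |>
    mutate(est_array_bp = estimate_array_size(.data$masked_bp, coverage))
}
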
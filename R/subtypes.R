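# Monomer subtype discovery: reads are standardized onto the family
# consensus by local alignment against the doubled consensus (absorbing the
# arbitrary circular register), projected into fixed 200 bp consensus
# windows, one-hot encoded and clustered by k-means with silhouette-based
# model selection; subtype strings and mate-pair subtype networks follow.

#' Anchor reads onto a family consensus
#'
#' Each read is locally aligned (both strands) against the consensus
#' concatenated with itself, so any monomer phase is reachable.  The best
#' alignment gives the read's offset into the consensus (mod period) and a
#' per-base consensus coordinate map: insertions relative to the consensus
#' are dropped and deletions become gap symbols.  Reads failing
#' `min_identity` over `min_len` aligned bp are dropped (count logged).
#'
#' @param reads sequence tibble (typically the reads classified to the
#'   family).
#' @param consensus the family consensus sequence (>= 100 bp).
#' @param min_identity anchoring identity floor (default 0.7).
#' @param min_len minimum aligned length (default 100 bp).
#' @return An `anchored_reads` tibble `(read_id, strand, offset, start, end,
#'   identity, chars)` where `start`/`end` delimit the covered interval on
#'   the doubled consensus (0-based half-open), `offset = start %% period`,
#'   and `chars` is the list column of per-coordinate characters
#'   (`A/C/G/T/-`).  Attribute `period` carries the consensus length.
#' @export
anchor_reads <- function(reads, consensus, min_identity = 0.7,
                         min_len = 100L) {
  period <- nchar(consensus)
  if (period < 100) abort("consensus must be >= 100 bp")
  if (nrow(reads) == 0) {
    return(structure(tibble(read_id = character(), strand = character(),
                            offset = integer(), start = integer(),
                            end = integer(), identity = double(),
                            chars = list()),
                     period = period, class = c("anchored_reads",
                                                "tbl_df", "tbl", "data.frame")))
  }
  # subject doubled, long enough for reads longer than one period
  reps <- max(2L, ceiling(max(nchar(reads$seq)) / period) + 1L)
  subj <- Biostrings::DNAString(strrep(consensus, reps))
  mat <- sub_matrix()
  aln <- function(seqs) {
    Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(seqs), subj,
                                  type = "local", substitutionMatrix = mat,
                                  gapOpening = 4, gapExtension = 1)
  }
  fwd <- aln(reads$seq)
  rev <- aln(revcomp(reads$seq))
  use_rev <- Biostrings::score(rev) > Biostrings::score(fwd)
  rows <- vector("list", nrow(reads))
  n_drop <- 0L
  for (i in seq_len(nrow(reads))) {
    pa <- if (use_rev[i]) rev[i] else fwd[i]
    pid <- Biostrings::pid(pa, type = "PID1") / 100
    alen <- Biostrings::nchar(pa)
    if (pid < min_identity || alen < min_len) { n_drop <- n_drop + 1L; next }
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    s0 <- Biostrings::start(Biostrings::subject(pa))  # 1-based on subject
    keep <- as_ != "-"                                # drop read insertions
    chars <- ap[keep]                                 # '-' marks deletions
    start0 <- (s0 - 1L) %% (2L * period)
    rows[[i]] <- tibble(
      read_id = reads$id[i], strand = if (use_rev[i]) "-" else "+",
      offset = start0 %% period, start = start0,
      end = start0 + length(chars), identity = pid, chars = list(chars))
  }
  if (n_drop > 0) {
    censat_log(sprintf("anchor_reads: %d of %d reads failed anchoring",
                       n_drop, nrow(reads)))
  }
  out <- bind_rows(rows)
  structure(out, period = period,
            class = c("anchored_reads", class(out)))
}

#' Extract per-window character matrices in consensus coordinates
#'
#' Fixed windows of `window_len` bp sliding by `window_slide` over the
#' consensus; a read contributes a row to every window it covers by at
#' least 90%.  Deletions relative to the consensus are padded by `-`;
#' positions a read does not reach (up to 10% at the window edges) are
#' imputed with the column consensus over covered rows, so partial edge
#' coverage does not manufacture artificial clusters.  Only full windows
#' are used (a 738 bp consensus yields the six full 200/100 windows
#' starting at 0, 100, ..., 500).
#'
#' @param anchored an `anchored_reads` table.
#' @param window_len window length (default 200).
#' @param window_slide slide (default 100).
#' @param min_cover_frac fraction of the window a read must cover.
#' @return Named list of character matrices (rows = reads, 200 columns),
#'   one per window start; class `window_matrices` with attribute
#'   `window_starts`.
#' @export
extract_windows <- function(anchored, window_len = 200L, window_slide = 100L,
                            min_cover_frac = 0.9) {
  period <- attr(anchored, "period")
  if (window_len > period) abort("window_len exceeds the consensus period")
  starts <- seq(0L, period - window_len, by = window_slide)
  mats <- list()
  for (w in starts) {
    rows <- list()
    for (i in seq_len(nrow(anchored))) {
      r0 <- anchored$start[i]; r1 <- anchored$end[i]
      # the window appears at w and w + period on the doubled consensus
      for (wpos in c(w, w + period)) {
        ov <- min(r1, wpos + window_len) - max(r0, wpos)
        if (ov < min_cover_frac * window_len) next
        row <- rep(".", window_len)        # '.' marks uncovered edges
        lo <- max(r0, wpos); hi <- min(r1, wpos + window_len)
        row[(lo - wpos + 1):(hi - wpos)] <-
          anchored$chars[[i]][(lo - r0 + 1):(hi - r0)]
        rows[[anchored$read_id[i]]] <- row
        break
      }
    }
    if (length(rows) > 0) {
      m <- do.call(rbind, rows)
      rownames(m) <- names(rows)
      # impute uncovered edge positions with the column consensus
      for (j in which(colSums(m == ".") > 0)) {
        col <- m[, j]
        tab <- sort(table(col[col != "."]), decreasing = TRUE)
        m[col == ".", j] <- if (length(tab) > 0) names(tab)[1] else "-"
      }
      mats[[paste0("w", w)]] <- m
    }
  }
  structure(mats, window_starts = starts, class = "window_matrices")
}

#' One-hot encode a window character matrix
#'
#' Five indicator features (A, C, G, T, gap) per column, so the squared
#' Euclidean distance between two rows is twice their Hamming distance.
#'
#' @param mat character matrix over `{A, C, G, T, -}`.
#' @return Numeric matrix with `5 * ncol(mat)` columns.
#' @export
encode_onehot <- function(mat) {
  lv <- c("A", "C", "G", "T", "-")
  bad <- !(mat %in% lv)
  if (any(bad)) {
    abort(paste0("non-alphabet symbol(s) in window matrix: ",
                 paste(unique(mat[bad]), collapse = ", ")))
  }
  n <- nrow(mat); p <- ncol(mat)
  out <- matrix(0, n, 5L * p)
  idx <- match(mat, lv)                      # column-major over mat
  cols <- (rep(seq_len(p), each = n) - 1L) * 5L + idx
  out[cbind(rep(seq_len(n), p), cols)] <- 1
  rownames(out) <- rownames(mat)
  out
}

#' Select k by mean silhouette and cluster
#'
#' Runs k-means (squared Euclidean geometry; `n_restarts` restarts per k
#' under a seed derived from `seed` and k) for each k in `k_range`, scores
#' each solution by the mean silhouette width computed on squared Euclidean
#' dissimilarities, and keeps the k with the highest mean silhouette (ties
#' to the smaller k).  Cluster ids are renumbered by decreasing cluster
#' size for determinism.
#'
#' @param features numeric feature matrix (rows = reads).
#' @param k_range integer vector `c(lower, upper)` (default 2..20).
#' @param n_restarts k-means restarts per k (default 10).
#' @param seed integer seed.
#' @return A `window_clustering`: `list(chosen_k, mean_silhouette,
#'   assignments, silhouettes, sizes)` with `assignments = (row, cluster)`
#'   and `silhouettes = (k, mean_silhouette)`.
#' @export
select_k_and_cluster <- function(features, k_range = c(2L, 20L),
                                 n_restarts = 10L, seed = 1L) {
  n <- nrow(features)
  ks <- seq.int(k_range[1], k_range[length(k_range)])
  if (n < ks[1] + 1) abort("fewer rows than the smallest k + 1")
  n_distinct <- nrow(unique(features))
  ks <- ks[ks <= min(n - 1L, n_distinct)]
  if (length(ks) == 0) abort("fewer distinct rows than the smallest k")
  d2 <- as.matrix(dist(features))^2
  sils <- numeric(length(ks))
  fits <- vector("list", length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    fit <- withr::with_seed(as.integer(seed) + 7919L * k, {
      kmeans(features, centers = k, nstart = n_restarts, iter.max = 200L)
    })
    sw <- cluster::silhouette(fit$cluster, dmatrix = d2)
    sils[j] <- mean(sw[, "sil_width"])
    fits[[j]] <- fit$cluster
  }
  best <- which.max(sils)           # which.max takes the first (smallest k)
  assign <- fits[[best]]
  # renumber by decreasing cluster size, ties by original id
  sizes <- sort(table(assign), decreasing = TRUE)
  remap <- setNames(seq_along(sizes), names(sizes))
  assign <- unname(remap[as.character(assign)])
  structure(list(
    chosen_k = ks[best],
    mean_silhouette = sils[best],
    assignments = tibble(row = rownames(features) %||%
                           as.character(seq_len(n)),
                         cluster = assign),
    silhouettes = tibble(k = ks, mean_silhouette = sils),
    sizes = as.integer(table(assign))
  ), class = "window_clustering")
}

#' @export
print.window_clustering <- function(x, ...) {
  cat(sprintf("<window_clustering> k=%d (mean silhouette %.3f), sizes: %s\n",
              x$chosen_k, x$mean_silhouette,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Cluster every consensus window of a family
#'
#' Convenience wrapper: one-hot encodes and clusters each window matrix.
#'
#' @param windows a `window_matrices` list.
#' @inheritParams select_k_and_cluster
#' @param max_rows optional cap on rows per window (deterministic
#'   subsample) to bound run time.
#' @return Named list of `window_clustering` objects.
#' @export
cluster_windows <- function(windows, k_range = c(2L, 20L), n_restarts = 10L,
                            seed = 1L, max_rows = NULL) {
  out <- list()
  for (nm in names(windows)) {
    m <- windows[[nm]]
    if (!is.null(max_rows) && nrow(m) > max_rows) {
      pick <- withr::with_seed(as.integer(seed),
                               sort(sample.int(nrow(m), max_rows)))
      m <- m[pick, , drop = FALSE]
    }
    out[[nm]] <- select_k_and_cluster(encode_onehot(m), k_range = k_range,
                                      n_restarts = n_restarts, seed = seed)
  }
  out
}

#' Label reads by ordered window-cluster subtype
#'
#' A read's subtype is the concatenation of its cluster ids across the
#' windows it occupies, in window order (cluster ids are already
#' size-renumbered within each window).  Reads appearing in no window are
#' excluded and logged.
#'
#' @param clusterings named list of `window_clustering` objects (from
#'   [cluster_windows()]), names in window order.
#' @return Tibble `(read_id, subtype, n_windows)`.
#' @export
label_read_subtype <- function(clusterings) {
  long <- bind_rows(lapply(names(clusterings), function(nm) {
    a <- clusterings[[nm]]$assignments
    tibble(read_id = a$row, window = nm, cluster = a$cluster)
  }))
  if (nrow(long) == 0) {
    return(tibble(read_id = character(), subtype = character(),
                  n_windows = integer()))
  }
  long$worder <- match(long$window, names(clusterings))
  long |> arrange(.data$read_id, .data$worder) |>
    group_by(.data$read_id) |>
    summarise(subtype = paste(.data$cluster, collapse = "-"),
              n_windows = n(), .groups = "drop")
}

#' Mate-pair subtype network and transitional reads
#'
#' Nodes are subtype (or cluster) labels weighted by read depth; edges
#' count mate pairs between labels and are kept at `min_edge` or above.
#' Transitional reads are CENP-A[+] reads whose mate is CENP-A[-] (and
#' vice versa), reported separately.
#'
#' @param read_info tibble `(read_id, label, status)` with `status` in
#'   `plus`/`minus` (from [classify_reads_cenpa()]); reads without a label
#'   are ignored.
#' @param pairs mate-pair tibble.
#' @param min_edge minimum mate pairs per retained edge.
#' @return `list(network, transitional)` where `network` is a
#'   `pair_network` and `transitional` a tibble
#'   `(pair_id, plus_read, minus_read)`.
#' @export
subtype_pair_network <- function(read_info, pairs, min_edge = 10L) {
  lab <- setNames(read_info$label, read_info$read_id)
  st <- setNames(read_info$status, read_info$read_id)
  la <- lab[pairs$left_id]; lb <- lab[pairs$right_id]
  keep <- !is.na(la) & !is.na(lb)
  nodes <- read_info |> count(label = .data$label, name = "weight")
  edges <- tibble(a = pmin(la[keep], lb[keep]),
                  b = pmax(la[keep], lb[keep])) |>
    count(.data$a, .data$b, name = "count") |>
    filter(.data$count >= min_edge)
  net <- structure(list(nodes = nodes, edges = edges,
                        edge_threshold = as.integer(min_edge)),
                   class = "pair_network")
  sa <- st[pairs$left_id]; sb <- st[pairs$right_id]
  tr <- which(!is.na(sa) & !is.na(sb) & sa != sb)
  transitional <- tibble(
    pair_id = pairs$pair_id[tr],
    plus_read = unname(ifelse(sa[tr] == "plus", pairs$left_id[tr],
                              pairs$right_id[tr])),
    minus_read = unname(ifelse(sa[tr] == "plus", pairs$right_id[tr],
                               pairs$left_id[tr])))
  list(network = net, transitional = transitional)
}
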
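# Phase III: CENP-A ChIP enrichment of library k-mers against sampled
# genomic background replicates, read-level CENP-A classification, and
# projection of enrichment onto contigs.

#' Draw genomic background read replicates
#'
#' Independent uniform samples without replacement from the WGS read set;
#' replicate seeds are derived deterministically from the master seed.
#'
#' @param wgs sequence tibble of WGS reads.
#' @param n_reads reads per replicate (at most `nrow(wgs)`).
#' @param n_reps number of replicates (default 10).
#' @param seed master seed.
#' @return List of `n_reps` sequence tibbles.
#' @export
draw_background <- function(wgs, n_reads, n_reps = 10L, seed = NULL) {
  if (n_reads > nrow(wgs)) {
    abort(sprintf("n_reads (%d) exceeds WGS read count (%d)",
                  n_reads, nrow(wgs)))
  }
  rep_seeds <- with_seed_opt(seed, function() {
    sample.int(.Machine$integer.max - 1L, n_reps)
  })
  lapply(rep_seeds, function(s) {
    withr::with_seed(s, wgs[sample.int(nrow(wgs), n_reads), , drop = FALSE])
  })
}

#' Score library k-mers for ChIP enrichment
#'
#' For each k-mer of the centromere-specific library and each background
#' replicate `r`, the score is the log2 of the pseudocounted, total-
#' normalized frequency ratio:
#' `s_r = log2(((c_chip + pc) / T_chip) / ((c_bg_r + pc) / T_bg_r))`
#' where `T` is the total k-mer count of each table.
#'
#' @param library a `kmer_table` of centromere-specific k-mers (e.g. after
#'   [subtract_assembly_kmers()]); its counts are kept as `wgs_count`.
#' @param chip_table ChIP read `kmer_table`.
#' @param bg_tables list of background `kmer_table`s.
#' @param pseudocount smoothing count (default 1).
#' @return An `enrichment_records` tibble: `kmer`, `wgs_count`,
#'   `chip_count`, `bg_1..R`, `score_1..R`; attribute `n_reps`.
#' @export
kmer_chip_score <- function(library, chip_table, bg_tables, pseudocount = 1) {
  if (nrow(chip_table) == 0) abort("ChIP k-mer table is empty")
  ks <- c(kmer_k(library), kmer_k(chip_table),
          vapply(bg_tables, kmer_k, integer(1)))
  if (length(unique(ks)) != 1) abort("all tables must share k")
  rec <- tibble(kmer = library$kmer, wgs_count = library$count)
  cc <- chip_table$count[match(rec$kmer, chip_table$kmer)]
  rec$chip_count <- ifelse(is.na(cc), 0L, cc)
  t_chip <- kmer_total(chip_table)
  for (r in seq_along(bg_tables)) {
    bt <- bg_tables[[r]]
    bc <- bt$count[match(rec$kmer, bt$kmer)]
    bc <- ifelse(is.na(bc), 0L, bc)
    rec[[paste0("bg_", r)]] <- bc
    rec[[paste0("score_", r)]] <- log2(((rec$chip_count + pseudocount) / t_chip) /
                                         ((bc + pseudocount) / kmer_total(bt)))
  }
  structure(rec, n_reps = length(bg_tables), k = kmer_k(library),
            class = c("enrichment_records", class(rec)))
}

#' Call enriched k-mers
#'
#' A k-mer is enriched when its score reaches the threshold in each of the
#' first `n_calling_reps` background comparisons (the both-comparisons
#' rule).
#'
#' @param records `enrichment_records` from [kmer_chip_score()].
#' @param threshold_log2 log2 ratio threshold (default 1, i.e. 2-fold).
#' @param n_calling_reps number of comparisons a call must pass (default 2).
#' @return `records` with an added logical `enriched` column.
#' @export
call_enriched <- function(records, threshold_log2 = 1, n_calling_reps = 2L) {
  n_reps <- attr(records, "n_reps")
  if (n_reps < n_calling_reps) {
    abort("records carry fewer scores than n_calling_reps")
  }
  enr <- rep(TRUE, nrow(records))
  for (r in seq_len(n_calling_reps)) {
    enr <- enr & records[[paste0("score_", r)]] >= threshold_log2
  }
  records$enriched <- enr
  attr(records, "threshold_log2") <- threshold_log2
  attr(records, "n_calling_reps") <- as.integer(n_calling_reps)
  censat_log(sprintf("called %d of %d k-mers enriched", sum(enr),
                     length(enr)))
  records
}

#' Satellite family enrichment in ChIP reads
#'
#' Classifies ChIP reads and each background replicate against the family
#' library by near-exact seed matching, then reports per family the ratio
#' of its ChIP read fraction to its mean background read fraction, an
#' empirical tail p-value over the replicate fractions and a normal-
#' approximation p-value (replicate counts are small).
#'
#' @param chip_reads ChIP sequence tibble.
#' @param bg_sets list of background sequence tibbles (from
#'   [draw_background()]).
#' @param library annotation library tibble `(name, sequence, type)`.
#' @param min_span minimum matched span within a read (default half the
#'   shortest read).
#' @return Tibble `(family, frac_chip, mean_frac_bg, fold, p_empirical,
#'   p_normal)`.
#' @export
family_enrichment <- function(chip_reads, bg_sets, library,
                              min_span = NULL) {
  min_span <- min_span %||% max(25L, min(nchar(chip_reads$seq)) %/% 2)
  fams <- library$name[library$type == "satellite"]
  classify_set <- function(reads) {
    spans <- annotate_sequences(reads, library, min_span = min_span,
                                mode = "seed")
    classify_reads(reads, spans)
  }
  cls_chip <- classify_set(chip_reads)
  fc <- vapply(fams, function(f) mean(cls_chip$class == f), numeric(1))
  # background replicates overlap heavily; classify each read once
  bg_union <- dplyr::distinct(bind_rows(bg_sets), .data$id, .keep_all = TRUE)
  cls_bg <- classify_set(bg_union)
  bg_class <- setNames(cls_bg$class, cls_bg$read_id)
  fb <- vapply(bg_sets, function(s) {
    cl <- bg_class[s$id]
    vapply(fams, function(f) mean(cl == f), numeric(1))
  }, numeric(length(fams)))
  fb <- matrix(fb, nrow = length(fc))
  mu <- rowMeans(fb)
  sdv <- apply(fb, 1, sd)
  fold <- ifelse(mu > 0, fc / mu, NA_real_)
  n_rep <- ncol(fb)
  p_emp <- (1 + rowSums(fb >= fc)) / (1 + n_rep)
  z <- (fc - mu) / ifelse(sdv > 0, sdv, NA_real_)
  tibble(family = names(fc), frac_chip = unname(fc),
         mean_frac_bg = unname(mu), fold = unname(fold),
         p_empirical = unname(p_emp), p_normal = unname(pnorm(-z)))
}

#' Classify reads CENP-A positive or negative
#'
#' Computes, per read, the union of positions covered by enriched k-mers;
#' a read is `"plus"` when its longest continuous covered run reaches
#' `min_continuous_bp`, `"minus"` when no enriched k-mer occurs, and
#' `"minus"` with `partial = TRUE` for nonzero sub-threshold coverage.
#' Reads shorter than k are `"minus"` with a warning.
#'
#' @param reads sequence tibble.
#' @param enriched_kmers character vector of enriched canonical k-mers.
#' @param k k-mer length.
#' @param min_continuous_bp run length required for a `"plus"` call
#'   (default 50, one full k-mer).
#' @return Tibble `(read_id, status, covered_bp, max_run_bp, partial)`.
#' @export
classify_reads_cenpa <- function(reads, enriched_kmers, k = 50L,
                                 min_continuous_bp = 50L) {
  lens <- nchar(reads$seq)
  if (any(lens < k)) {
    warn(sprintf("%d reads shorter than k classified minus", sum(lens < k)))
  }
  enriched_kmers <- unique(enriched_kmers)
  long <- which(lens >= k)
  covered <- numeric(nrow(reads)); max_run <- numeric(nrow(reads))
  if (length(long) > 0) {
    n_i <- lens[long] - k + 1L
    pos <- sequence(n_i)
    ri <- rep(long, n_i)
    km <- canonical_kmers(substring(rep(reads$seq[long], n_i), pos,
                                    pos + k - 1L))
    hit <- km %in% enriched_kmers
    hr <- ri[hit]; hp <- pos[hit]          # sorted by (read, pos)
    if (length(hr) > 0) {
      # fixed-width windows: a covered run breaks when the next start is
      # beyond the previous window end
      brk <- c(TRUE, diff(hr) != 0 | diff(hp) > k)
      run_id <- cumsum(brk)
      end_idx <- c(which(brk)[-1] - 1L, length(hp))
      w <- hp[end_idx] + k - hp[brk]       # run widths
      rread <- hr[brk]
      covered[unique(rread)] <- tapply(w, rread, sum)[as.character(unique(rread))]
      max_run[unique(rread)] <- tapply(w, rread, max)[as.character(unique(rread))]
    }
  }
  status <- ifelse(max_run >= min_continuous_bp, "plus", "minus")
  partial <- status == "minus" & covered > 0
  if (any(partial)) {
    censat_log(sprintf("%d reads with sub-threshold enriched coverage labeled minus (partial)",
                       sum(partial)))
  }
  tibble(read_id = reads$id, status = status, covered_bp = covered,
         max_run_bp = max_run, partial = partial)
}

#' Map enriched k-mers onto contigs as a coverage track
#'
#' Per-base count of enriched k-mer windows overlapping each contig
#' position, emitted as BEDGraph-style runs (zero runs omitted).
#'
#' @param contigs sequence tibble.
#' @param enriched_kmers character vector of enriched canonical k-mers.
#' @param k k-mer length.
#' @return Track tibble `(seq_id, start, end, value)`.
#' @export
map_enrichment_to_contigs <- function(contigs, enriched_kmers, k = 50L) {
  enriched_kmers <- unique(enriched_kmers)
  out <- list()
  for (i in seq_len(nrow(contigs))) {
    n <- nchar(contigs$seq[i])
    if (n < k) next
    win <- canonical_kmers(seq_kmers_chr(contigs$seq[i], k))
    hit <- which(win %in% enriched_kmers)
    if (length(hit) == 0) next
    delta <- numeric(n + 1L)
    for (h in hit) {
      delta[h] <- delta[h] + 1
      delta[h + k] <- delta[h + k] - 1
    }
    cov <- cumsum(delta[seq_len(n)])
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values > 0
    if (!any(keep)) next
    out[[length(out) + 1]] <- tibble(
      seq_id = contigs$id[i], start = as.integer(starts[keep]),
      end = as.integer(ends[keep]), value = r$values[keep])
  }
  if (length(out) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  value = double()))
  }
  bind_rows(out)
}
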
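# Phase II: the centromere-specific 50-mer feature library.  Reads are
# reformatted to canonical k-mers (50 bp window, 1 bp slide), k-mers that
# occur verbatim in the genome assembly are subtracted, and the remainder
# is classified single- versus multi-copy against a calibrated single-copy
# depth model.

#' Canonical k-mer form
#'
#' The canonical form of a k-mer is the lexicographic minimum of itself and
#' its reverse complement, so counting is strand-collapsed.
#'
#' @param kmers character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmers <- function(kmers) {
  rc <- revcomp(kmers)
  swap <- rc < kmers
  kmers[swap] <- rc[swap]
  kmers
}

#' Count canonical k-mers across reads
#'
#' Every position of every read contributes one k-mer (window `k`, slide 1);
#' k-mers containing N are skipped, as are reads shorter than `k` (counted
#' and logged).
#'
#' @param reads sequence tibble.
#' @param k k-mer length (default 50; must be >= 8).
#' @return A `kmer_table`: tibble `(kmer, count)` with attributes `k`,
#'   `total_kmers` (sum of counts) and `n_skipped`.
#' @export
#' @examples
#' extract_kmers(seq_tbl("a", "ACGTACGTTT"), k = 8)
extract_kmers <- function(reads, k = 50L) {
  if (k < 8) abort("k must be >= 8")
  lens <- nchar(reads$seq)
  short <- lens < k
  if (any(short)) {
    censat_log(sprintf("%d reads shorter than k=%d skipped", sum(short), k))
  }
  keep <- reads$seq[!short]
  n_i <- nchar(keep) - k + 1L
  pos <- sequence(n_i)
  km <- substring(rep(keep, n_i), pos, pos + k - 1L)
  hasN <- grepl("N", km, fixed = TRUE)
  km <- canonical_kmers(km[!hasN])
  tab <- tibble(kmer = km) |> count(.data$kmer, name = "count")
  new_kmer_table(tab, k = k, n_skipped = sum(hasN) + sum(short))
}

# per-read canonical k-mer instances; lets subset tables (e.g. background
# replicates drawn from one read set) be counted without re-extraction
kmer_instances <- function(reads, k) {
  lens <- nchar(reads$seq)
  keep <- which(lens >= k)
  n_i <- lens[keep] - k + 1L
  pos <- sequence(n_i)
  km <- substring(rep(reads$seq[keep], n_i), pos, pos + k - 1L)
  rid <- rep(reads$id[keep], n_i)
  ok <- !grepl("N", km, fixed = TRUE)
  list(read_id = rid[ok], kmer = canonical_kmers(km[ok]), k = as.integer(k))
}

kmer_table_from_instances <- function(inst, ids) {
  sel <- inst$read_id %in% ids
  tab <- tibble(kmer = inst$kmer[sel]) |> count(.data$kmer, name = "count")
  new_kmer_table(tab, k = inst$k)
}

new_kmer_table <- function(tab, k, n_skipped = 0L) {
  structure(as_tibble(tab), k = as.integer(k),
            total_kmers = sum(tab$count), n_skipped = as.integer(n_skipped),
            class = c("kmer_table", class(as_tibble(tab))))
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table> k=%d, %d distinct k-mers, %g total\n",
              attr(x, "k"), nrow(x), attr(x, "total_kmers")))
  NextMethod()
}

#' k of a k-mer table
#' @param table a `kmer_table`.
#' @return Integer k.
#' @export
kmer_k <- function(table) attr(table, "k")

#' Total k-mer count of a table
#' @param table a `kmer_table`.
#' @return Sum of counts.
#' @export
kmer_total <- function(table) attr(table, "total_kmers")

#' Subtract assembly-matching k-mers
#'
#' Removes from a read k-mer table every canonical k-mer with at least one
#' exact occurrence in the assembly, leaving k-mers specific to sequence
#' hidden in the centromere gaps.  Unplaced (chrUn) contigs are excluded
#' from the subtraction by default, since they are themselves gap sequence.
#'
#' @param table a `kmer_table` of read k-mers.
#' @param assembly sequence tibble of assembly chromosomes.
#' @param chrun optional sequence tibble of unplaced contigs; only
#'   subtracted when `exclude_chrun = FALSE`.
#' @param exclude_chrun keep chrUn out of the subtraction (default TRUE).
#' @return The filtered `kmer_table` (total recomputed).
#' @export
subtract_assembly_kmers <- function(table, assembly, chrun = NULL,
                                    exclude_chrun = TRUE) {
  k <- kmer_k(table)
  src <- assembly
  if (!exclude_chrun && !is.null(chrun) && nrow(chrun) > 0) {
    src <- bind_rows(assembly, chrun)
  }
  if (nrow(src) == 0) return(table)
  asm <- extract_kmers(src, k)
  out <- table[!table$kmer %in% asm$kmer, , drop = FALSE]
  censat_log(sprintf("assembly subtraction removed %d of %d k-mers",
                     nrow(table) - nrow(out), nrow(table)))
  new_kmer_table(out, k = k, n_skipped = attr(table, "n_skipped"))
}

#' Calibrate the single-copy k-mer depth model
#'
#' The count of a k-mer from single-copy sequence under `coverage`-fold
#' reads of length `read_len` has mean `coverage * (read_len - k + 1) /
#' read_len` (only read windows fully containing the k-mer count).  Modes:
#' `"simulated"` draws Poisson counts from that closed form (binomially
#' thinned by the per-window error-free probability when `error_rate > 0`);
#' `"observed"` takes the counts of the k-mers of a known single-copy locus
#' from the read k-mer table; `"pooled"` averages both.
#'
#' @param mode `"simulated"`, `"observed"` or `"pooled"`.
#' @param k k-mer length.
#' @param coverage fold read coverage.
#' @param read_len read length (must exceed k).
#' @param error_rate per-base substitution error rate used for thinning in
#'   simulated mode.
#' @param table read `kmer_table` (observed/pooled modes).
#' @param locus_seq the single-copy locus sequence (observed/pooled modes).
#' @param n_sim number of simulated draws.
#' @param seed optional integer seed.
#' @return A `copy_calibration`: `list(mu_sc, sd_sc, coverage, source)`.
#' @export
single_copy_calibration <- function(mode = c("simulated", "observed",
                                             "pooled"),
                                    k, coverage, read_len,
                                    error_rate = 0,
                                    table = NULL, locus_seq = NULL,
                                    n_sim = 20000L, seed = NULL) {
  mode <- match.arg(mode)
  if (read_len <= k) abort("read_len must exceed k")
  if (coverage <= 0) abort("coverage must be positive")
  lambda <- coverage * (read_len - k + 1) / read_len
  p_clean <- (1 - error_rate)^k
  sim_part <- function() {
    counts <- rbinom(n_sim, rpois(n_sim, lambda), p_clean)
    c(mu = mean(counts), sd = sd(counts))
  }
  obs_part <- function() {
    if (is.null(table) || is.null(locus_seq)) {
      abort("observed mode needs `table` and `locus_seq`")
    }
    if (nchar(locus_seq) < k) abort("locus shorter than k")
    lk <- unique(canonical_kmers(seq_kmers_chr(locus_seq, k)))
    counts <- table$count[match(lk, table$kmer)]
    counts[is.na(counts)] <- 0
    c(mu = mean(counts), sd = sd(counts))
  }
  est <- with_seed_opt(seed, function() {
    switch(mode,
           simulated = sim_part(),
           observed = obs_part(),
           pooled = (sim_part() + obs_part()) / 2)
  })
  if (est[["mu"]] <= 0) abort("calibrated single-copy mean must be positive")
  structure(list(mu_sc = unname(est[["mu"]]), sd_sc = unname(est[["sd"]]),
                 coverage = coverage, source = mode),
            class = "copy_calibration")
}

#' @export
print.copy_calibration <- function(x, ...) {
  cat(sprintf("<copy_calibration> mu=%.3f sd=%.3f (coverage %.2gx, %s)\n",
              x$mu_sc, x$sd_sc, x$coverage, x$source))
  invisible(x)
}

#' Classify k-mers single- versus multi-copy
#'
#' A k-mer is multi-copy when its count exceeds the single-copy mean by more
#' than `copy_sd_mult` standard deviations (strict inequality); estimated
#' copies are `count / mu_sc`.
#'
#' @param table a `kmer_table` (or any tibble with a `count` column).
#' @param calibration a `copy_calibration`.
#' @param copy_sd_mult standard-deviation multiplier (default 2).
#' @return The table with added columns `copy_class` (`"single"`/`"multi"`)
#'   and `est_copies`.
#' @export
classify_kmer_copy <- function(table, calibration, copy_sd_mult = 2) {
  thr <- calibration$mu_sc + copy_sd_mult * calibration$sd_sc
  table$copy_class <- ifelse(table$count > thr, "multi", "single")
  table$est_copies <- table$count / calibration$mu_sc
  table
}

#' Junction k-mers across annotation boundaries
#'
#' Reports every k-mer whose window straddles a boundary between a
#' satellite span and a non-satellite span (TE or unannotated sequence),
#' labeled by the flanking pair.  An internal boundary yields up to `k - 1`
#' straddling windows before canonical deduplication.
#'
#' @param seqs sequence tibble.
#' @param spans spans with `seq_id`, `start`, `end`, `label` and `type`
#'   columns (truth spans or annotations); spans must tile without overlap.
#' @param k k-mer length.
#' @return Tibble `(kmer, junction, seq_id, pos)` with `pos` the 0-based
#'   window start.
#' @export
junction_kmers <- function(seqs, spans, k = 50L) {
  out <- list()
  for (i in seq_len(nrow(seqs))) {
    id <- seqs$id[i]; s <- seqs$seq[i]; len <- nchar(s)
    df <- spans[spans$seq_id == id, , drop = FALSE] |> arrange(.data$start)
    if (nrow(df) == 0) next
    # boundary set: span edges where the satellite/non-satellite class flips
    bounds <- list()
    add_bound <- function(b, left, right) {
      bounds[[length(bounds) + 1]] <<- tibble(b = b, junction =
                                                paste(left, right, sep = "|"))
    }
    for (j in seq_len(nrow(df))) {
      left_lab <- if (j == 1) NULL else df$label[j - 1]
      left_type <- if (j == 1) "unique" else df$type[j - 1]
      if (df$start[j] > 0) {
        lt <- if (!is.null(left_lab) && df$end[j - 1] == df$start[j])
          left_type else "unique"
        ll <- if (lt == "unique") "unique" else left_lab
        if (xor(lt == "satellite", df$type[j] == "satellite")) {
          add_bound(df$start[j], ll, df$label[j])
        }
      }
      nxt_is_adjacent <- j < nrow(df) && df$start[j + 1] == df$end[j]
      if (df$end[j] < len && !nxt_is_adjacent &&
          df$type[j] == "satellite") {
        add_bound(df$end[j], df$label[j], "unique")
      }
    }
    if (length(bounds) == 0) next
    bounds <- bind_rows(bounds) |> distinct()
    for (j in seq_len(nrow(bounds))) {
      b <- bounds$b[j]
      starts <- max(0L, b - k + 1L):min(b - 1L, len - k)
      starts <- starts[starts >= 0]
      if (length(starts) == 0) next
      win <- substring(s, starts + 1L, starts + k)
      keep <- !grepl("N", win, fixed = TRUE)
      if (!any(keep)) next
      out[[length(out) + 1]] <- tibble(
        kmer = canonical_kmers(win[keep]), junction = bounds$junction[j],
        seq_id = id, pos = as.integer(starts[keep]))
    }
  }
  if (length(out) == 0) {
    return(tibble(kmer = character(), junction = character(),
                  seq_id = character(), pos = integer()))
  }
  bind_rows(out)
}
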
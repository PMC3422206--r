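# Seed-and-extend matching of library elements against reads and contigs:
# 12-mer exact seeds locate candidate regions, banded local alignment
# (Biostrings) validates and delimits them.  Satellite monomers are matched
# as tandem concatemers so hits absorb the arbitrary monomer phase.

SEED_K <- 12L

sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = FALSE)
}

seq_kmers_chr <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# seeds of an element; satellites are circular, so wraparound 12-mers count
element_seeds <- function(seq, circular) {
  s <- if (circular) paste0(seq, substr(seq, 1, SEED_K - 1)) else seq
  unique(seq_kmers_chr(s, SEED_K))
}

# tandem concatemer long enough to cover a query segment plus one period of
# slack on both sides
concatemer <- function(seq, target_len) {
  reps <- max(1L, ceiling(target_len / nchar(seq)) + 2L)
  strrep(seq, reps)
}

# batched local alignment of query segments against one subject, splitting
# each segment at accepted hits and realigning the remainders so several
# hits per segment (e.g. an array interrupted by a TE) are recovered
align_segments <- function(segments, subject, min_identity, min_span,
                           max_rounds = 8L) {
  hits <- list()
  mat <- sub_matrix()
  subj <- Biostrings::DNAString(subject)
  round_i <- 0L
  while (nrow(segments) > 0 && round_i < max_rounds) {
    round_i <- round_i + 1L
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(segments$s), subject = subj,
      type = "local", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 1)
    ps <- Biostrings::start(Biostrings::pattern(pa))
    pe <- Biostrings::end(Biostrings::pattern(pa))
    pid <- Biostrings::pid(pa, type = "PID1") / 100
    score <- Biostrings::score(pa)
    ok <- which(pe - ps + 1 >= min_span & pid >= min_identity)
    if (length(ok) == 0) break
    hits[[round_i]] <- tibble(
      seq_id = segments$seq_id[ok],
      start = segments$off[ok] + ps[ok] - 1L,
      end = segments$off[ok] + pe[ok],
      identity = pid[ok], score = score[ok])
    nxt <- list()
    for (j in ok) {
      n <- nchar(segments$s[j])
      if (ps[j] - 1 >= min_span) {
        nxt[[length(nxt) + 1]] <- tibble(
          seq_id = segments$seq_id[j], off = segments$off[j],
          s = substr(segments$s[j], 1L, ps[j] - 1L))
      }
      if (n - pe[j] >= min_span) {
        nxt[[length(nxt) + 1]] <- tibble(
          seq_id = segments$seq_id[j], off = segments$off[j] + pe[j],
          s = substr(segments$s[j], pe[j] + 1L, n))
      }
    }
    segments <- if (length(nxt) > 0) bind_rows(nxt) else
      tibble(seq_id = character(), off = integer(), s = character())
  }
  if (length(hits) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  identity = double(), score = double()))
  }
  bind_rows(hits)
}

# concatenate sequences with N spacers so one matchPDict call yields seed
# positions for every sequence; findInterval maps positions back
concat_index <- function(seqs) {
  lens <- nchar(seqs$seq)
  offs <- cumsum(c(0, head(lens + SEED_K, -1)))  # N spacer of SEED_K bases
  big <- paste(seqs$seq, collapse = strrep("N", SEED_K))
  list(big = Biostrings::DNAString(big), offs = offs, lens = lens,
       ids = seqs$id)
}

seed_positions <- function(idx, seeds) {
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  m <- Biostrings::matchPDict(pd, idx$big)
  st <- unlist(IRanges::start(m), use.names = FALSE)
  if (length(st) == 0) {
    return(tibble(seq_i = integer(), pos = integer()))
  }
  seq_i <- findInterval(st, idx$offs + 1L)
  tibble(seq_i = seq_i, pos = st - idx$offs[seq_i] - 1L)  # 0-based in seq
}

#' Annotate sequences against a satellite and repeat library
#'
#' Seed-and-extend masking: 12-mer exact seeds of every library element
#' (both strands; satellite elements also as tandem concatemers covering
#' the arbitrary monomer phase) locate candidate regions, which banded
#' local alignment validates.  Spans above the identity and length floors
#' are reported; overlaps are resolved highest-identity-first, trimming the
#' lower-identity span.  `mode = "seed"` skips the alignment and reports
#' merged exact-seed runs (near-exact matching for short-read screening);
#' those spans carry `identity = NA`.
#'
#' @param seqs sequence tibble to annotate.
#' @param library tibble `(name, sequence, type)` with `type` either
#'   `"satellite"` (circular monomer consensus) or `"te"`.
#' @param min_identity minimum alignment identity (default 0.8).
#' @param min_span minimum span length in bp (default 50).
#' @param mode `"align"` (default) or `"seed"`.
#' @return Span tibble `(seq_id, start, end, label, strand, identity, type)`
#'   in 0-based half-open read coordinates.
#' @export
annotate_sequences <- function(seqs, library, min_identity = 0.8,
                               min_span = 50L, mode = c("align", "seed")) {
  mode <- match.arg(mode)
  if (nrow(library) == 0) abort("library must be non-empty")
  if (!all(c("name", "sequence", "type") %in% names(library))) {
    abort("library needs columns name, sequence, type")
  }
  if (nrow(seqs) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  label = character(), strand = character(),
                  identity = double(), type = character()))
  }
  idx <- concat_index(seqs)
  long <- idx$lens > 3000L
  all_spans <- list()
  for (e in seq_len(nrow(library))) {
    elem <- library$sequence[e]
    circ <- library$type[e] == "satellite"
    period <- nchar(elem)
    for (strand in c("+", "-")) {
      eseq <- if (strand == "+") elem else revcomp(elem)
      seeds <- element_seeds(eseq, circ)
      sp <- seed_positions(idx, seeds)
      if (nrow(sp) == 0) next
      if (mode == "seed") {
        # vectorized run merging over all sequences at once
        o <- order(sp$seq_i, sp$pos)
        si <- sp$seq_i[o]; po <- sp$pos[o]
        gap <- max(30L, period %/% 8L)
        brk <- c(TRUE, diff(si) != 0 | diff(po) > gap + SEED_K)
        run_start <- po[brk]
        end_idx <- c(which(brk)[-1] - 1L, length(po))
        run_end <- po[end_idx] + SEED_K
        spans <- tibble(seq_id = idx$ids[si[brk]],
                        start = run_start, end = run_end)
        spans <- spans[spans$end - spans$start >= min_span, , drop = FALSE]
        if (nrow(spans) > 0) {
          spans$identity <- NA_real_
          spans$score <- (spans$end - spans$start) * 1.0
          spans$label <- library$name[e]
          spans$strand <- strand
          spans$type <- library$type[e]
          all_spans[[length(all_spans) + 1]] <- spans
        }
        next
      }
      slack <- if (circ) period else min(200L, period)
      segs <- list()
      # short sequences: align the whole sequence; long ones: align seed
      # regions only
      short_i <- unique(sp$seq_i[!long[sp$seq_i]])
      if (length(short_i) > 0) {
        segs[[1]] <- tibble(seq_id = idx$ids[short_i], off = 0L,
                            s = seqs$seq[short_i])
      }
      for (i in unique(sp$seq_i[long[sp$seq_i]])) {
        pos <- sort(sp$pos[sp$seq_i == i])
        runs <- merge_runs(pos, SEED_K, gap = max(2L * period, 500L))
        runs$start <- pmax(0L, runs$start - slack)
        runs$end <- pmin(idx$lens[i], runs$end + slack)
        segs[[length(segs) + 1]] <- tibble(
          seq_id = idx$ids[i], off = runs$start,
          s = substring(seqs$seq[i], runs$start + 1L, runs$end))
      }
      segs <- bind_rows(segs)
      subject <- if (circ) concatemer(eseq, max(nchar(segs$s))) else eseq
      hits <- align_segments(segs, subject, min_identity, min_span)
      if (nrow(hits) > 0) {
        hits$label <- library$name[e]
        hits$strand <- strand
        hits$type <- library$type[e]
        all_spans[[length(all_spans) + 1]] <- hits
      }
    }
  }
  if (length(all_spans) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  label = character(), strand = character(),
                  identity = double(), type = character()))
  }
  spans <- bind_rows(all_spans)
  out <- resolve_spans(spans, min_span) |>
    select("seq_id", "start", "end", "label", "strand", "identity", "type") |>
    arrange(.data$seq_id, .data$start)
  censat_log(sprintf("annotated %d sequences: %d spans", nrow(seqs), nrow(out)))
  out
}

merge_runs <- function(pos, width, gap) {
  pos <- sort(unique(pos))
  brk <- c(TRUE, diff(pos) > gap + width)
  grp <- cumsum(brk)
  tibble(start = tapply(pos, grp, min)[unique(grp)],
         end = tapply(pos, grp, max)[unique(grp)] + width) |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

# highest-identity-first overlap resolution; lower spans are trimmed to the
# uncovered remainder and dropped below min_span
resolve_spans <- function(spans, min_span) {
  spans$identity_key <- ifelse(is.na(spans$identity), 1, spans$identity)
  # fast path: sequences whose spans never overlap need no resolution
  o <- order(spans$seq_id, spans$start)
  spans <- spans[o, , drop = FALSE]
  n <- nrow(spans)
  run_max <- spans$end
  has_ov <- rep(FALSE, n)
  if (n > 1) {
    same <- spans$seq_id[-1] == spans$seq_id[-n]
    for (j in 2:n) {
      if (same[j - 1]) {
        has_ov[j] <- spans$start[j] < run_max[j - 1]
        run_max[j] <- max(run_max[j - 1], spans$end[j])
      }
    }
  }
  ov_ids <- unique(spans$seq_id[has_ov])
  singles <- spans[!spans$seq_id %in% ov_ids, , drop = FALSE]
  spans <- spans[spans$seq_id %in% ov_ids, , drop = FALSE]
  if (nrow(spans) == 0) {
    singles$identity_key <- NULL
    return(singles)
  }
  out <- lapply(split(spans, spans$seq_id), function(df) {
    df <- df[order(-df$identity_key, -(df$end - df$start), df$label), ,
             drop = FALSE]
    L <- max(df$end)
    covered <- logical(L)
    keep <- list()
    for (j in seq_len(nrow(df))) {
      sl <- (df$start[j] + 1L):df$end[j]
      free <- sl[!covered[sl]]
      if (length(free) == 0) next
      brk <- c(TRUE, diff(free) != 1L)
      st <- free[brk]
      en <- free[c(which(brk)[-1] - 1L, length(free))]
      ok <- (en - st + 1L) >= min_span
      if (!any(ok)) next
      st <- st[ok]; en <- en[ok]
      covered[unlist(Map(seq.int, st, en))] <- TRUE
      piece <- df[rep(j, length(st)), , drop = FALSE]
      piece$start <- st - 1L
      piece$end <- en
      keep[[length(keep) + 1]] <- piece
    }
    bind_rows(keep)
  })
  res <- bind_rows(c(list(singles), out))
  res$identity_key <- NULL
  res
}
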
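#' Sequence tables
#'
#' Reads and contigs travel through the pipeline as tibbles with columns
#' `id` (unique), `seq` (uppercase over A/C/G/T/N) and, for FASTQ input, a
#' `qual` string of Phred+33 scores the same length as `seq`.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of sequences.
#' @param qual optional character vector of per-base Phred+33 qualities.
#' @return A tibble with columns `id`, `seq` and optionally `qual`.
#' @export
#' @examples
#' seq_tbl(c("a", "b"), c("ACGT", "GGTT"))
seq_tbl <- function(id, seq, qual = NULL) {
  seq <- chartr("u", "t", seq)
  seq <- chartr("U", "T", toupper(seq))
  tb <- tibble(id = unname(as.character(id)), seq = unname(seq))
  if (!is.null(qual)) tb$qual <- unname(as.character(qual))
  validate_seq_tbl(tb)
}

validate_seq_tbl <- function(tb) {
  if (any(is.na(tb$id) | tb$id == "")) abort("sequence ids must be non-empty")
  dup <- unique(tb$id[duplicated(tb$id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s): ", paste(dup, collapse = ", ")))
  }
  if (any(nchar(tb$seq) < 1)) abort("sequences must have length >= 1")
  bad <- grepl("[^ACGTN]", tb$seq)
  if (any(bad)) {
    abort(paste0("sequence(s) contain characters outside {A,C,G,T,N}: ",
                 paste(head(tb$id[bad], 5), collapse = ", ")))
  }
  if ("qual" %in% names(tb) && any(nchar(tb$qual) != nchar(tb$seq))) {
    abort("quality strings must match sequence lengths")
  }
  tb
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

#' Read and write FASTA
#'
#' Sequences are uppercased and U is converted to T on read.  Duplicate ids
#' are an error; an empty file yields an empty table with a warning.
#' `write_fasta()` followed by `read_fasta()` is the identity on `id`/`seq`.
#'
#' @param path file path.
#' @param records a sequence table (see [seq_tbl()]).
#' @param width line width for wrapped output.
#' @return `read_fasta()` returns a sequence tibble; `write_fasta()` returns
#'   `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) abort(paste0("bad FASTA: ", conditionMessage(e))))
  if (length(set) == 0) {
    warn(paste0("empty FASTA file: ", path))
    return(seq_tbl(character(), character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  seq_tbl(ids, as.character(set))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 70L) {
  validate_seq_tbl(records)
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read and write FASTQ (Phred+33)
#'
#' @param path,path1,path2 file paths; for paired input the two files hold
#'   mates in matching order.
#' @param records sequence tibble; a missing `qual` column writes maximum
#'   quality.
#' @return `read_fastq()` returns a sequence tibble with a `qual` column.
#'   `read_fastq_paired()` returns `list(reads, pairs)` where `pairs` is a
#'   tibble `(pair_id, left_id, right_id)`; ids identical across files are
#'   suffixed `/1` and `/2`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(set))
  seq_tbl(ids, as.character(set), as.character(S4Vectors::mcols(set)$qualities))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(records, path) {
  validate_seq_tbl(records)
  qual <- records$qual %||% strrep("I", nchar(records$seq))
  set <- Biostrings::DNAStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' @rdname read_fastq
#' @export
read_fastq_paired <- function(path1, path2) {
  left <- read_fastq(path1)
  right <- read_fastq(path2)
  if (nrow(left) != nrow(right)) {
    abort(sprintf("paired FASTQ files differ in record count (%d vs %d)",
                  nrow(left), nrow(right)))
  }
  same <- left$id == right$id
  bare <- ifelse(same, left$id, sub("/1$", "", left$id))
  left$id[same] <- paste0(left$id[same], "/1")
  right$id[same] <- paste0(right$id[same], "/2")
  reads <- validate_seq_tbl(bind_rows(left, right))
  pairs <- tibble(pair_id = bare, left_id = left$id, right_id = right$id)
  if (any(pairs$left_id == pairs$right_id)) {
    abort("mate ids must differ within a pair")
  }
  censat_log(sprintf("read %d pairs (%d records)", nrow(pairs), nrow(reads)))
  list(reads = reads, pairs = pairs)
}

#' Annotation span tables and BED6 round-trip
#'
#' Spans are tibbles with columns `seq_id`, `start` (0-based), `end`
#' (half-open), `label`, `strand` (`+`/`-`) and `identity` in `[0, 1]`.
#' On disk the BED6 score column carries `round(identity * 1000)`.
#'
#' @param spans a span tibble.
#' @param path file path.
#' @return `write_bed()` returns `path` invisibly; `read_bed()` returns a
#'   span tibble.
#' @export
write_bed <- function(spans, path) {
  spans <- validate_spans(spans)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   spans$seq_id, spans$start, spans$end, spans$label,
                   round(spans$identity * 1000), spans$strand)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  label = character(), strand = character(),
                  identity = double()))
  }
  df <- readr::read_tsv(path,
                        col_names = c("seq_id", "start", "end", "label",
                                      "score", "strand"),
                        col_types = "ciicic", progress = FALSE)
  validate_spans(tibble(seq_id = df$seq_id, start = df$start, end = df$end,
                        label = df$label, strand = df$strand,
                        identity = df$score / 1000))
}

validate_spans <- function(spans, seq_len = NULL) {
  need <- c("seq_id", "start", "end", "label", "strand", "identity")
  miss <- setdiff(need, names(spans))
  if (length(miss) > 0) {
    abort(paste0("span table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(spans$start < 0)) abort("span start must be >= 0")
  if (any(spans$start >= spans$end)) abort("span start must be < end")
  if (any(!spans$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(spans$identity < 0 | spans$identity > 1, na.rm = TRUE)) {
    abort("identity must lie in [0, 1]")
  }
  as_tibble(spans)
}

#' Read and write BEDGraph tracks
#'
#' Tracks are tibbles `(seq_id, start, end, value)` with 0-based half-open
#' coordinates; zero-valued runs are omitted on write.
#'
#' @param track a track tibble.
#' @param path file path.
#' @return `read_bedgraph()` returns a track tibble.
#' @export
write_bedgraph <- function(track, path) {
  track <- track[track$value != 0, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%g", track$seq_id, track$start,
                     track$end, track$value), path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  if (file.size(path) == 0) {
    return(tibble(seq_id = character(), start = integer(),
                  end = integer(), value = double()))
  }
  readr::read_tsv(path, col_names = c("seq_id", "start", "end", "value"),
                  col_types = "ciid", progress = FALSE)
}

#' Read and write network edge lists
#'
#' Edge lists are TSV files `node_a<TAB>node_b<TAB>count`.
#'
#' @param edges tibble `(a, b, count)`.
#' @param path file path.
#' @return `read_network_tsv()` returns the edge tibble.
#' @export
write_network_tsv <- function(edges, path) {
  readr::write_tsv(edges[, c("a", "b", "count")], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  readr::read_tsv(path, col_names = c("a", "b", "count"),
                  col_types = "cci", progress = FALSE)
}

#' Convert span coordinates between 0-based half-open and 1-based closed
#'
#' All on-disk and in-memory coordinates are 0-based half-open; these
#' converters serve 1-based closed reports.
#'
#' @param spans a span tibble.
#' @return The span tibble with shifted `start` (and identical `end`).
#' @export
spans_to_1based <- function(spans) {
  spans$start <- spans$start + 1L
  spans
}

#' @rdname spans_to_1based
#' @export
spans_to_0based <- function(spans) {
  spans$start <- spans$start - 1L
  spans
}
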
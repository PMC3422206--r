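# Synthetic centromeric genomes with planted truth: tandem satellite arrays
# built from diverged monomer subfamilies, embedded transposable elements,
# an assembly in which arrays are replaced by centromere gaps plus unplaced
# contigs, paired shotgun reads, and CENP-A ChIP reads enriched over
# designated domains.

with_seed_opt <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(as.integer(seed), fn())
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitution-only by default; an indel rate is accepted but defaults to 0
mutate_sequence <- function(seq, sub_rate, indel_rate = 0) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  len <- length(s)
  nmut <- rbinom(1, len, sub_rate)
  if (nmut > 0) {
    pos <- sample.int(len, nmut)
    shift <- sample.int(3, nmut, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    idx <- match(s[pos], bases)
    s[pos] <- bases[((idx - 1 + shift) %% 4) + 1]
  }
  if (indel_rate > 0) {
    nind <- rbinom(1, len, indel_rate)
    if (nind > 0) {
      for (p in sample.int(length(s), min(nind, length(s)))) {
        if (runif(1) < 0.5) {
          s <- append(s, sample(c("A", "C", "G", "T"), 1), after = p)
        } else if (length(s) > 1) {
          s <- s[-p]
        }
      }
    }
  }
  paste(s, collapse = "")
}

#' Generate monomer subfamily templates
#'
#' Draws a random ancestral monomer consensus and derives `n_subfamilies`
#' templates by independent substitution at rate `between_divergence`, so
#' the expected pairwise difference between two templates is about
#' `2 * between_divergence` per site (minus back-substitution overlap).
#' `within_divergence` is carried along as the per-monomer noise rate used
#' when arrays are built from the templates.
#'
#' @param monomer_len monomer length in bp (738 matches the CarSat1 repeat
#'   unit; 1466 the CarSat2 unit).
#' @param n_subfamilies number of templates to derive.
#' @param between_divergence substitution fraction from the ancestor, in
#'   `[0, 0.3]`.
#' @param within_divergence substitution fraction within a subfamily, in
#'   `[0, between_divergence]` (recorded, not applied here).
#' @param seed optional integer seed.
#' @return A tibble `(subfamily, role, sequence)` whose first row is the
#'   ancestral consensus (`role = "ancestral"`).
#' @export
#' @examples
#' generate_subfamilies(200, 2, between_divergence = 0.05, seed = 1)
generate_subfamilies <- function(monomer_len, n_subfamilies,
                                 between_divergence,
                                 within_divergence = 0, seed = NULL) {
  if (between_divergence < 0 || between_divergence > 0.3 ||
      within_divergence < 0 || within_divergence > 0.3) {
    abort("divergences must lie in [0, 0.3]")
  }
  if (within_divergence > between_divergence) {
    abort("within_divergence must not exceed between_divergence")
  }
  if (monomer_len < 100) abort("monomer_len must be >= 100")
  with_seed_opt(seed, function() {
    anc <- rand_dna(monomer_len)
    tmpl <- vapply(seq_len(n_subfamilies),
                   function(i) mutate_sequence(anc, between_divergence),
                   character(1))
    tibble(
      subfamily = c("ancestral", paste0("S", seq_len(n_subfamilies))),
      role = c("ancestral", rep("template", n_subfamilies)),
      sequence = c(anc, tmpl)
    )
  })
}

#' Build a tandem satellite array from subfamily templates
#'
#' Concatenates monomers block by block; each monomer is its block's
#' template with independent substitutions at `within_divergence`.
#' Transposable elements are inserted inside designated monomers.  Every
#' monomer and TE is recorded as a truth span.
#'
#' @param templates named character vector (or a tibble with `subfamily` and
#'   `sequence`) of monomer templates.
#' @param block_layout tibble `(subfamily, n_monomers)` in array order.
#' @param te_insertions optional tibble `(name, sequence, monomer_index,
#'   offset)`; `monomer_index` counts monomers across the whole array
#'   (1-based) and `offset` is the 0-based position inside that monomer
#'   after which the TE is inserted.
#' @param within_divergence per-monomer substitution rate.
#' @param seed optional integer seed.
#' @return `list(sequence, spans)` where `spans` is a tibble
#'   `(start, end, label, type, monomer_index)` in 0-based half-open array
#'   coordinates; `type` is `"satellite"` or `"te"`.
#' @export
build_satellite_array <- function(templates, block_layout,
                                  te_insertions = NULL,
                                  within_divergence = 0, seed = NULL) {
  if (is.data.frame(templates)) {
    templates <- setNames(templates$sequence, templates$subfamily)
  }
  if (nrow(block_layout) == 0 || any(block_layout$n_monomers < 1)) {
    abort("blocks must be non-empty")
  }
  miss <- setdiff(block_layout$subfamily, names(templates))
  if (length(miss) > 0) {
    abort(paste0("unknown subfamily template(s): ", paste(miss, collapse = ", ")))
  }
  with_seed_opt(seed, function() {
    subfam_per_monomer <- rep(block_layout$subfamily, block_layout$n_monomers)
    n_mono <- length(subfam_per_monomer)
    if (!is.null(te_insertions)) {
      if (any(te_insertions$monomer_index < 1 |
              te_insertions$monomer_index > n_mono)) {
        abort("TE monomer_index out of range")
      }
      if (any(te_insertions$offset < 0 |
              te_insertions$offset >
                nchar(templates[subfam_per_monomer[te_insertions$monomer_index]]))) {
        abort("TE offset outside monomer")
      }
    }
    pieces <- character(0)
    spans <- list()
    pos <- 0L
    add_span <- function(len, label, type, idx) {
      spans[[length(spans) + 1]] <<- tibble(
        start = pos, end = pos + len, label = label, type = type,
        monomer_index = idx)
      pos <<- pos + len
    }
    for (i in seq_len(n_mono)) {
      sf <- subfam_per_monomer[i]
      mono <- mutate_sequence(templates[[sf]], within_divergence)
      tes <- if (is.null(te_insertions)) NULL else
        te_insertions[te_insertions$monomer_index == i, , drop = FALSE]
      if (is.null(tes) || nrow(tes) == 0) {
        pieces <- c(pieces, mono)
        add_span(nchar(mono), sf, "satellite", i)
      } else {
        tes <- tes[order(tes$offset), , drop = FALSE]
        cut <- 0L
        for (j in seq_len(nrow(tes))) {
          left <- substr(mono, cut + 1, tes$offset[j])
          if (nchar(left) > 0) {
            pieces <- c(pieces, left)
            add_span(nchar(left), sf, "satellite", i)
          }
          pieces <- c(pieces, tes$sequence[j])
          add_span(nchar(tes$sequence[j]), tes$name[j], "te", i)
          cut <- tes$offset[j]
        }
        rest <- substr(mono, cut + 1, nchar(mono))
        if (nchar(rest) > 0) {
          pieces <- c(pieces, rest)
          add_span(nchar(rest), sf, "satellite", i)
        }
      }
    }
    list(sequence = paste(pieces, collapse = ""), spans = bind_rows(spans))
  })
}

#' Assemble a synthetic genome and its gapped assembly
#'
#' Each chromosome is a unique flank followed by one satellite array at the
#' chromosome end (the acrocentric organization in which centromere gaps
#' sit at assembly ends).  The "assembly" retains the flanks, replaces every
#' array by a gap recorded in a BED-style table (a 1 bp marker at the
#' assembly coordinate adjacent to the omitted array), and emits a
#' configurable fraction of array sequence as unplaced 1-5 kb contigs
#' (chrUn analog).  One flank interval is designated the single-copy
#' calibration locus.
#'
#' @param arrays list with one element per chromosome:
#'   `list(sequence, spans, family)` as returned by
#'   [build_satellite_array()] plus a `family` name.
#' @param flank_len unique flank length per chromosome (bp).
#' @param background_len if positive, adds one array-free background
#'   chromosome of this length.
#' @param unplaced_frac fraction of each array's bp re-emitted as unplaced
#'   contigs.
#' @param contig_len_range length range for unplaced contigs (bp).
#' @param gap_edge_retain bp of the proximal array edge retained in the
#'   assembly next to the gap (real assemblies capture some satellite
#'   adjacent to centromere gaps — the signal pericentric enrichment
#'   measures; default 0 omits the whole array).
#' @param locus_len length of the single-copy calibration locus (bp).
#' @param seed optional integer seed.
#' @return A list with sequence tibbles `genome`, `assembly`, `chrun`;
#'   `gaps` (span tibble on assembly coordinates); `layout` (genome-wide
#'   segment truth: chrom, start, end, kind, label); and `monomers`
#'   (per-monomer truth spans in genome coordinates, with `family`,
#'   `subfamily`, `type`, `monomer_index`).
#' @export
assemble_genome <- function(arrays, flank_len, background_len = 0,
                            unplaced_frac = 0, contig_len_range = c(1000, 5000),
                            gap_edge_retain = 0L, locus_len = 10000,
                            seed = NULL) {
  if (flank_len <= 0) abort("flank_len must be positive")
  with_seed_opt(seed, function() {
    n_chr <- length(arrays)
    genome <- list(); assembly <- list(); chrun <- list()
    gaps <- list(); layout <- list(); monomers <- list()
    un_i <- 0L
    for (i in seq_len(n_chr)) {
      chrom <- paste0("chr", i)
      arr <- arrays[[i]]
      if (nchar(arr$sequence) <= 0) abort("array must be non-empty")
      flank <- rand_dna(flank_len)
      genome[[chrom]] <- paste0(flank, arr$sequence)
      retain <- min(gap_edge_retain, nchar(arr$sequence))
      assembly[[chrom]] <- paste0(flank, substr(arr$sequence, 1L, retain))
      asm_len <- flank_len + retain
      gaps[[chrom]] <- tibble(seq_id = chrom, start = asm_len - 1L,
                              end = asm_len, label = "centromere_gap",
                              strand = "+", identity = 1)
      flank_label <- paste0(chrom, "_flank")
      has_span_fam <- "family" %in% names(arr$spans)
      arr_label <- paste(unique(if (has_span_fam) arr$spans$family
                                else arr$family), collapse = "+")
      layout[[chrom]] <- tibble(
        chrom = chrom,
        start = c(0L, flank_len),
        end = c(flank_len, flank_len + nchar(arr$sequence)),
        kind = c("unique", "satellite_array"),
        label = c(flank_label, arr_label)
      )
      mono <- arr$spans
      fam <- if (has_span_fam) mono$family else rep(arr$family, nrow(mono))
      monomers[[chrom]] <- tibble(
        chrom = chrom, start = mono$start + flank_len,
        end = mono$end + flank_len, family = fam,
        subfamily = ifelse(mono$type == "satellite",
                           paste0(fam, ".", mono$label), mono$label),
        label = mono$label, type = mono$type,
        monomer_index = mono$monomer_index
      )
      te <- monomers[[chrom]][monomers[[chrom]]$type == "te", , drop = FALSE]
      if (nrow(te) > 0) {
        layout[[paste0(chrom, "_te")]] <- tibble(
          chrom = chrom, start = te$start, end = te$end,
          kind = "te_insert", label = te$label)
      }
      if (unplaced_frac > 0) {
        target <- unplaced_frac * nchar(arr$sequence)
        got <- 0
        while (got < target) {
          len <- round(runif(1, contig_len_range[1], contig_len_range[2]))
          len <- min(len, nchar(arr$sequence))
          s0 <- sample.int(nchar(arr$sequence) - len + 1, 1) - 1L
          un_i <- un_i + 1L
          nm <- paste0("chrUn_", un_i)
          chrun[[nm]] <- substr(arr$sequence, s0 + 1, s0 + len)
          got <- got + len
        }
      }
    }
    if (background_len > 0) {
      genome[["chrBg"]] <- rand_dna(background_len)
      assembly[["chrBg"]] <- genome[["chrBg"]]
      layout[["chrBg"]] <- tibble(chrom = "chrBg", start = 0L,
                                  end = background_len, kind = "unique",
                                  label = "chrBg_flank")
    }
    # single-copy calibration locus inside the chr1 flank
    locus_start <- min(10000L, max(0L, flank_len - locus_len))
    layout[["locus"]] <- tibble(chrom = "chr1", start = locus_start,
                                end = locus_start + locus_len,
                                kind = "single_copy_locus", label = "sc_locus")
    res <- list(
      genome = seq_tbl(names(genome), unlist(genome)),
      assembly = seq_tbl(names(assembly), unlist(assembly)),
      chrun = if (length(chrun) > 0) seq_tbl(names(chrun), unlist(chrun))
              else seq_tbl(character(), character()),
      gaps = bind_rows(gaps),
      layout = bind_rows(layout),
      monomers = bind_rows(monomers)
    )
    censat_log(sprintf("genome: %d chromosomes, %d bp; assembly %d bp; %d chrUn contigs",
                       n_chr, sum(nchar(res$genome$seq)),
                       sum(nchar(res$assembly$seq)), nrow(res$chrun)))
    res
  })
}

#' Union of monomer spans for designated CENP-A subfamilies
#'
#' @param monomers monomer truth tibble from [assemble_genome()].
#' @param subfamilies character vector of `subfamily` labels whose blocks
#'   form CENP-A domains.
#' @return Tibble `(chrom, start, end)` of merged domain spans.
#' @export
cenpa_domains_from_monomers <- function(monomers, subfamilies) {
  hit <- monomers[monomers$subfamily %in% subfamilies, , drop = FALSE]
  if (nrow(hit) == 0) return(tibble(chrom = character(), start = integer(),
                                    end = integer()))
  out <- lapply(split(hit, hit$chrom), function(df) {
    ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end),
                          min.gapwidth = 2L)
    tibble(chrom = df$chrom[1], start = IRanges::start(ir) - 1L,
           end = IRanges::end(ir))
  })
  bind_rows(out)
}

#' Simulate paired whole-genome shotgun reads
#'
#' Draws `round(coverage * G / (2 * read_len))` fragments uniformly over the
#' genome; the left mate is the fragment start on the plus strand and the
#' right mate the reverse complement of the fragment end.  Substitution
#' errors are i.i.d. per base.
#'
#' @param genome sequence tibble of chromosomes.
#' @param coverage fold read coverage (default 7.5).
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd fragment size model; `insert_mean` must
#'   exceed `2 * read_len`.
#' @param sub_error_rate per-base substitution error rate.
#' @param seed optional integer seed.
#' @return `list(reads, pairs, origin)`: a sequence tibble with qualities, a
#'   mate-pair tibble `(pair_id, left_id, right_id)`, and per-read truth
#'   origins `(read_id, chrom, start, end, strand)`.
#' @export
simulate_paired_reads <- function(genome, coverage = 7.5, read_len = 500L,
                                  insert_mean = 2000, insert_sd = 200,
                                  sub_error_rate = 0, seed = NULL) {
  if (coverage <= 0) abort("coverage must be positive")
  if (insert_mean <= 2 * read_len) abort("insert_mean must exceed 2 * read_len")
  lens <- nchar(genome$seq)
  if (any(lens < insert_mean + 4 * insert_sd)) {
    abort("chromosomes must be longer than the largest insert")
  }
  G <- sum(lens)
  n_pairs <- round(coverage * G / (2 * read_len))
  with_seed_opt(seed, function() {
    chr_i <- sample.int(nrow(genome), n_pairs, replace = TRUE,
                        prob = lens / G)
    ins <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)),
                     2L * read_len + 1L), lens[chr_i])
    start <- vapply(seq_len(n_pairs), function(j) {
      sample.int(lens[chr_i[j]] - ins[j] + 1L, 1L) - 1L
    }, integer(1))
    left <- substring(genome$seq[chr_i], start + 1L, start + read_len)
    right <- revcomp(substring(genome$seq[chr_i], start + ins - read_len + 1L,
                               start + ins))
    pair_id <- sprintf("r%06d", seq_len(n_pairs))
    lid <- paste0(pair_id, "/1"); rid <- paste0(pair_id, "/2")
    seqs <- apply_read_errors(c(left, right), sub_error_rate)
    reads <- seq_tbl(c(lid, rid), seqs,
                     strrep("I", rep(read_len, 2 * n_pairs)))
    o_start <- c(start, start + ins - read_len)
    o_end <- c(start + read_len, start + ins)
    origin <- tibble(
      read_id = c(lid, rid),
      chrom = genome$id[c(chr_i, chr_i)],
      start = o_start, end = o_end,
      strand = rep(c("+", "-"), each = n_pairs)
    )
    censat_log(sprintf("simulated %d read pairs (%.2fx of %d bp)",
                       n_pairs, 2 * n_pairs * read_len / G, G))
    list(reads = reads,
         pairs = tibble(pair_id = pair_id, left_id = lid, right_id = rid),
         origin = origin)
  })
}

apply_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  nmut <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(nmut > 0)
  for (j in idx) {
    seqs[j] <- local({
      s <- strsplit(seqs[j], "", fixed = TRUE)[[1]]
      pos <- sample.int(length(s), nmut[j])
      bases <- c("A", "C", "G", "T")
      shift <- sample.int(3, nmut[j], replace = TRUE)
      k <- match(s[pos], bases)
      ok <- !is.na(k)
      s[pos[ok]] <- bases[((k[ok] - 1 + shift[ok]) %% 4) + 1]
      paste(s, collapse = "")
    })
  }
  seqs
}

#' Simulate single-end CENP-A ChIP reads
#'
#' Read origins follow a mixture: a read starts inside a CENP-A domain with
#' probability `fold * D / (fold * D + (G - D))` where `D` is the total
#' domain length, and uniformly over the rest of the genome otherwise.
#' Reads are 72 bp single-end by default and strand is random.
#'
#' @param genome sequence tibble of chromosomes.
#' @param cenpa_domains tibble `(chrom, start, end)` of CENP-A domains.
#' @param fold enrichment of per-bp read density inside domains (>= 1).
#' @param n_reads number of reads.
#' @param read_len read length (default 72).
#' @param sub_error_rate per-base substitution error rate.
#' @param seed optional integer seed.
#' @return `list(reads, labels, origin)` where `labels` is
#'   `(read_id, in_domain)` truth.
#' @export
simulate_chip_reads <- function(genome, cenpa_domains, fold = 1,
                                n_reads, read_len = 72L,
                                sub_error_rate = 0, seed = NULL) {
  if (n_reads <= 0) abort("n_reads must be positive")
  if (fold < 1) abort("fold must be >= 1")
  if (nrow(cenpa_domains) == 0) abort("cenpa_domains must be non-empty")
  lens <- setNames(nchar(genome$seq), genome$id)
  G <- sum(lens)
  dom <- cenpa_domains
  dom_len <- dom$end - dom$start
  D <- sum(dom_len)
  p_in <- fold * D / (fold * D + (G - D))
  with_seed_opt(seed, function() {
    in_dom <- runif(n_reads) < p_in
    n_in <- sum(in_dom)
    start <- integer(n_reads); chrom <- character(n_reads)
    if (n_in > 0) {
      di <- sample.int(nrow(dom), n_in, replace = TRUE, prob = dom_len / D)
      off <- floor(runif(n_in) * dom_len[di])
      chrom[in_dom] <- dom$chrom[di]
      start[in_dom] <- dom$start[di] + off
    }
    n_out <- n_reads - n_in
    if (n_out > 0) {
      ci <- sample.int(nrow(genome), 2L * n_out + 50L, replace = TRUE,
                       prob = lens / G)
      po <- floor(runif(length(ci)) * lens[ci])
      cand_chr <- genome$id[ci]
      keep <- rep(TRUE, length(ci))
      for (r in seq_len(nrow(dom))) {
        keep <- keep & !(cand_chr == dom$chrom[r] & po >= dom$start[r] &
                           po < dom$end[r])
      }
      while (sum(keep) < n_out) {  # top up on the rare shortfall
        ci2 <- sample.int(nrow(genome), n_out, replace = TRUE, prob = lens / G)
        po2 <- floor(runif(n_out) * lens[ci2])
        ci <- c(ci, ci2); po <- c(po, po2)
        cand_chr <- genome$id[ci]
        keep <- rep(TRUE, length(ci))
        for (r in seq_len(nrow(dom))) {
          keep <- keep & !(cand_chr == dom$chrom[r] & po >= dom$start[r] &
                             po < dom$end[r])
        }
      }
      pick <- which(keep)[seq_len(n_out)]
      chrom[!in_dom] <- cand_chr[pick]
      start[!in_dom] <- po[pick]
    }
    start <- pmin(start, lens[chrom] - read_len)
    seqs <- substring(genome$seq[match(chrom, genome$id)], start + 1L,
                      start + read_len)
    strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    seqs <- apply_read_errors(seqs, sub_error_rate)
    ids <- sprintf("chip%07d", seq_len(n_reads))
    censat_log(sprintf("simulated %d ChIP reads (%.1f%% in-domain)",
                       n_reads, 100 * mean(in_dom)))
    list(reads = seq_tbl(ids, seqs, strrep("I", rep(read_len, n_reads))),
         labels = tibble(read_id = ids, in_domain = in_dom),
         origin = tibble(read_id = ids, chrom = chrom, start = start,
                         end = start + read_len, strand = strand))
  })
}

#' Label simulated reads against the planted layout
#'
#' For each read origin, reports the majority satellite family/subfamily at
#' the origin (requiring at least half the read), the fraction of the read
#' over satellite sequence, and the fraction inside CENP-A domains.
#'
#' @param origin read origin tibble from the simulators.
#' @param monomers monomer truth tibble from [assemble_genome()].
#' @param cenpa_domains domain tibble (may be empty).
#' @return Tibble `(read_id, family, subfamily, sat_frac, te_frac,
#'   domain_frac)`; `family`/`subfamily` are `NA` for reads mostly outside
#'   arrays.
#' @export
label_reads_truth <- function(origin, monomers,
                              cenpa_domains = NULL) {
  read_len <- origin$end - origin$start
  res <- tibble(read_id = origin$read_id, family = NA_character_,
                subfamily = NA_character_, sat_frac = 0, te_frac = 0,
                domain_frac = 0)
  sat <- monomers[monomers$type == "satellite", , drop = FALSE]
  te <- monomers[monomers$type == "te", , drop = FALSE]
  ov_frac <- function(spans, values = NULL) {
    out <- numeric(nrow(origin))
    best <- character(nrow(origin))
    for (ch in unique(origin$chrom)) {
      oi <- which(origin$chrom == ch)
      si <- which(spans$chrom == ch)
      if (length(si) == 0 || length(oi) == 0) next
      qr <- IRanges::IRanges(origin$start[oi] + 1L, origin$end[oi])
      sr <- IRanges::IRanges(spans$start[si] + 1L, spans$end[si])
      hits <- IRanges::findOverlaps(qr, sr)
      if (length(hits) == 0) next
      w <- IRanges::width(IRanges::pintersect(
        qr[S4Vectors::queryHits(hits)], sr[S4Vectors::subjectHits(hits)]))
      df <- tibble(q = oi[S4Vectors::queryHits(hits)],
                   lab = if (is.null(values)) "x"
                         else values[si][S4Vectors::subjectHits(hits)],
                   w = w)
      agg <- df |> group_by(.data$q, .data$lab) |>
        summarise(w = sum(.data$w), .groups = "drop_last") |>
        arrange(desc(.data$w)) |>
        summarise(total = sum(.data$w), top = first(.data$lab),
                  topw = first(.data$w), .groups = "drop")
      out[agg$q] <- agg$total
      best[agg$q] <- agg$top
    }
    list(bp = out, best = best)
  }
  s <- ov_frac(sat, sat$subfamily)
  res$sat_frac <- s$bp / read_len
  half <- s$bp >= read_len / 2
  res$subfamily[half] <- s$best[half]
  res$family[half] <- sub("\\..*$", "", s$best[half])
  if (nrow(te) > 0) res$te_frac <- ov_frac(te)$bp / read_len
  if (!is.null(cenpa_domains) && nrow(cenpa_domains) > 0) {
    dm <- tibble(chrom = cenpa_domains$chrom, start = cenpa_domains$start,
                 end = cenpa_domains$end, type = "dom")
    res$domain_frac <- ov_frac(dm)$bp / read_len
  }
  res
}
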
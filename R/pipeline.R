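#' Run the full three-phase pipeline
#'
#' Phase I: satellite family discovery on unplaced contigs, read annotation
#' and classification, pericentric enrichment of families next to assembly
#' gaps, mate-pair family networking and seed expansion into the
#' centromeric read database, TE co-occurrence and array-size estimation.
#' Phase II: canonical k-mer library from the centromeric reads, assembly
#' subtraction, single-copy calibration and copy-number classes, junction
#' k-mers.  Phase III: ChIP enrichment scores against sampled background
#' replicates, enriched k-mer calls, CENP-A read classification, contig
#' enrichment tracks, and per-family monomer subtype clustering with
#' subtype mate-pair networks.
#'
#' @param sim input bundle as produced by [simulate_scenario()] (or
#'   assembled from files): sequence tibbles `wgs`, `chip`, `assembly`,
#'   `chrun`, `te_library`, plus `wgs_pairs` and `gaps`.
#' @param config a [censat_config()]; `sim$config` is used when present.
#' @param locus optional `(chrom, start, end)` list locating a known
#'   single-copy locus in the assembly for observed-mode calibration
#'   (defaults to simulated-mode calibration).
#' @param subtype_max_rows row cap per clustered window.
#' @param max_anchor_reads cap on reads anchored per family group
#'   (deterministic subsample; bounds alignment cost).
#' @param k_range k-means search range for subtype clustering.
#' @return A nested list with elements `discovery`, `library`,
#'   `annotations`, `classes`, `density`, `pericentric`, `network`,
#'   `expansion`, `array_sizes`, `te_enrichment`, `kmers` (library table
#'   with copy classes), `calibration`, `junctions`, `enrichment`
#'   (records with calls), `enriched_kmers`, `family_enrichment`,
#'   `cenpa_reads`, `contig_track` and `subtypes` (one entry per group of
#'   homologous discovered families).
#' @export
run_censat <- function(sim, config = NULL, locus = NULL,
                       subtype_max_rows = 400L, max_anchor_reads = 1200L,
                       k_range = c(2L, 8L)) {
  cfg <- config %||% sim$config %||% censat_config()
  seed <- cfg$seed
  ## ---- Phase I ----
  disc <- discover_families(sim$chrun)
  if (nrow(disc$families) == 0) abort("no satellite families discovered")
  lib <- bind_rows(disc$families,
                   if (nrow(sim$te_library) > 0)
                     tibble(name = sim$te_library$id,
                            sequence = sim$te_library$seq, type = "te"))
  annotations <- annotate_sequences(sim$wgs, lib,
                                    min_identity = cfg$min_identity,
                                    min_span = cfg$min_span)
  classes <- classify_reads(sim$wgs, annotations)
  asm_spans <- annotate_sequences(sim$assembly, lib,
                                  min_identity = cfg$min_identity,
                                  min_span = cfg$min_span)
  density <- windowed_family_density(
    asm_spans[asm_spans$type == "satellite", , drop = FALSE],
    sim$gaps, sim$assembly, window_len = cfg$pericentric_window)
  pericentric <- pericentric_enrichment(density,
                                        n_permutations = cfg$n_permutations,
                                        seed = seed + 101L)
  network <- mate_pair_matrix(classes, sim$wgs_pairs)
  seeds <- pericentric$family[pericentric$p_value < 0.05 &
                                pericentric$fold >= 2 &
                                pericentric$family %in% network$nodes$label]
  if (length(seeds) == 0) abort("no pericentrically enriched seed family")
  expansion <- seed_network_expansion(network, seeds,
                                      min_pair_edge = cfg$min_pair_edge,
                                      read_classes = classes,
                                      pairs = sim$wgs_pairs)
  array_sizes <- family_array_sizes(annotations, cfg$coverage)
  te_enrichment <- te_cooccurrence(classes, annotations)
  ## ---- Phase II ----
  cent_ids <- expansion$reads$read_id
  cent_reads <- sim$wgs[sim$wgs$id %in% cent_ids, , drop = FALSE]
  cent_kt <- extract_kmers(cent_reads, cfg$k)
  lib_kt <- subtract_assembly_kmers(cent_kt, sim$assembly, sim$chrun,
                                    exclude_chrun = TRUE)
  read_len <- max(nchar(sim$wgs$seq))
  calibration <- if (!is.null(locus)) {
    # pooled: simulated closed-form draws averaged with the observed counts
    # of the known single-copy locus
    asm_seq <- sim$assembly$seq[sim$assembly$id == locus$chrom]
    single_copy_calibration("pooled", k = cfg$k, coverage = cfg$coverage,
                            read_len = read_len,
                            table = extract_kmers(sim$wgs, cfg$k),
                            locus_seq = substr(asm_seq, locus$start + 1,
                                               locus$end),
                            seed = seed + 202L)
  } else {
    single_copy_calibration("simulated", k = cfg$k, coverage = cfg$coverage,
                            read_len = read_len, seed = seed + 202L)
  }
  kmers <- classify_kmer_copy(lib_kt, calibration,
                              copy_sd_mult = cfg$copy_sd_mult)
  junctions <- junction_kmers(cent_reads,
                              annotations[annotations$seq_id %in% cent_ids, ,
                                          drop = FALSE], cfg$k)
  junctions <- junctions[junctions$kmer %in% lib_kt$kmer, , drop = FALSE]
  ## ---- Phase III ----
  chip_kt <- extract_kmers(sim$chip, cfg$k)
  # depth-matched background: each replicate carries slightly less than the
  # ChIP library's k-mer total, so equal pseudocounted counts can never
  # clear the fold threshold through normalization alone and isolated
  # single-read coincidences stay below it
  n_bg <- min(nrow(sim$wgs) - 1L,
              floor(0.9 * kmer_total(chip_kt) / (read_len - cfg$k + 1)))
  bg_sets <- draw_background(sim$wgs, n_reads = n_bg,
                             n_reps = cfg$n_background_reps,
                             seed = seed + 303L)
  wgs_inst <- kmer_instances(sim$wgs, cfg$k)
  bg_kts <- lapply(bg_sets, function(s) {
    kmer_table_from_instances(wgs_inst, s$id)
  })
  enrichment <- kmer_chip_score(lib_kt, chip_kt, bg_kts,
                                pseudocount = cfg$pseudocount) |>
    call_enriched(threshold_log2 = cfg$enrich_log2_threshold,
                  n_calling_reps = cfg$n_calling_reps)
  enriched_kmers <- enrichment$kmer[enrichment$enriched]
  fam_enr <- family_enrichment(sim$chip, bg_sets, lib, min_span = 20L)
  sat_read_ids <- classes$read_id[classes$class %in% expansion$anchored]
  sat_reads <- sim$wgs[sim$wgs$id %in% sat_read_ids, , drop = FALSE]
  cenpa_reads <- classify_reads_cenpa(sat_reads, enriched_kmers, k = cfg$k,
                                      min_continuous_bp =
                                        cfg$min_continuous_enriched_bp)
  contig_track <- map_enrichment_to_contigs(sim$chrun, enriched_kmers,
                                            k = cfg$k)
  ## ---- subtypes per homologous family group ----
  # discovered families are subfamily-resolution (>95% rule); monomer
  # subtype analysis pools homologous families (linked at 75% identity)
  sat_lib <- lib[lib$type == "satellite" & lib$name %in% expansion$anchored, ,
                 drop = FALSE]
  comps <- if (nrow(sat_lib) > 1) {
    grp <- cluster_consensi(setNames(sat_lib$sequence, sat_lib$name),
                            min_identity = 0.75, min_overlap = 100L)
    grp$members
  } else list(sat_lib$name)
  status_by_read <- setNames(cenpa_reads$status, cenpa_reads$read_id)
  subtypes <- list()
  for (ci in seq_along(comps)) {
    fams <- comps[[ci]]
    # group consensus: the member family with the most classified reads
    depth <- vapply(fams, function(f) sum(classes$class == f), integer(1))
    cons_fam <- fams[which.max(depth)]
    consensus <- lib$sequence[match(cons_fam, lib$name)]
    rid <- classes$read_id[classes$class %in% fams]
    reads_c <- sim$wgs[sim$wgs$id %in% rid, , drop = FALSE]
    if (nrow(reads_c) > max_anchor_reads) {
      pick <- withr::with_seed(seed + 505L + ci,
                               sort(sample.int(nrow(reads_c),
                                               max_anchor_reads)))
      reads_c <- reads_c[pick, , drop = FALSE]
    }
    anchored <- anchor_reads(reads_c, consensus)
    if (nrow(anchored) < 10) next
    windows <- extract_windows(anchored, window_len = cfg$window_len,
                               window_slide = cfg$window_slide)
    clus <- cluster_windows(windows, k_range = k_range,
                            n_restarts = cfg$n_restarts,
                            seed = seed + 404L + ci,
                            max_rows = subtype_max_rows)
    subtype_tbl <- label_read_subtype(clus)
    subtype_tbl$status <- unname(status_by_read[subtype_tbl$read_id])
    info <- subtype_tbl |> filter(!is.na(.data$status)) |>
      mutate(label = paste0(cons_fam, ":", .data$subtype)) |>
      select("read_id", "label", "status")
    net <- subtype_pair_network(info, sim$wgs_pairs,
                                min_edge = max(2L, cfg$min_pair_edge %/% 5L))
    subtypes[[paste0("component", ci)]] <- list(
      families = fams, consensus_family = cons_fam,
      anchored = anchored, windows = windows, clusterings = clus,
      subtype_table = subtype_tbl, network = net$network,
      transitional = net$transitional)
  }
  list(discovery = disc, library = lib, annotations = annotations,
       classes = classes, density = density, pericentric = pericentric,
       network = network, expansion = expansion, array_sizes = array_sizes,
       te_enrichment = te_enrichment, kmers = kmers,
       calibration = calibration, junctions = junctions,
       enrichment = enrichment, enriched_kmers = enriched_kmers,
       family_enrichment = fam_enr, cenpa_reads = cenpa_reads,
       contig_track = contig_track, subtypes = subtypes, config = cfg)
}
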
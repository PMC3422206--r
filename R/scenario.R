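#' Simulate the standard desk-scale study scenario
#'
#' Builds a small genome whose chromosomes each end in a centromeric region
#' of two satellite arrays (families `CenSatB` proximal and `CenSatA`
#' distal, sharing monomer templates across chromosomes, as centromeric
#' satellite families recur across chromosomes).  Every array is organized
#' in three blocks of two monomer subfamilies — a small central `S1` block
#' flanked by larger `S2` blocks — with between-subfamily divergence 5%
#' from a common ancestor and within-subfamily divergence 0.5%.  The `S1`
#' blocks of both families are the CENP-A domains, and one transposable
#' element is inserted into the chr1 `CenSatA` array outside the domain.
#' Paired shotgun reads are drawn at 7.5x with 500 bp reads and 2 kb
#' inserts, and 50,000 72-bp single-end ChIP reads at 10-fold domain
#' enrichment.  The assembly retains the flanks plus two monomers of the
#' proximal array edge next to each centromere gap, and re-emits a quarter
#' of array bp as unplaced contigs.  All truth (layout, monomer spans, read
#' origins and labels, planted templates, TE library, CENP-A domains) is
#' returned.
#'
#' These defaults are the package's reference study conditions; tests and
#' the acceptance script run against them.
#'
#' @param seed integer seed driving every random draw.
#' @param n_chromosomes number of array-bearing chromosomes.
#' @param n_families number of satellite families per centromere (1 or 2).
#' @param chrom_len chromosome length (bp).
#' @param monomer_len monomer repeat unit (bp; 738 is the CarSat1 unit).
#' @param blocks monomer counts for the (flanking, central, flanking)
#'   blocks; the central block uses subfamily `S1` (the CENP-A subfamily)
#'   and the flanking blocks subfamily `S2`.
#' @param between_divergence,within_divergence subfamily divergence rates.
#' @param n_te number of TE insertions (0 or 1; inserted in the chr1
#'   distal array outside the CENP-A domain).
#' @param te_len TE length (bp).
#' @param coverage,read_len,insert_mean,insert_sd,wgs_error WGS model.
#' @param chip_n,chip_fold,chip_read_len,chip_error ChIP model.
#' @param unplaced_frac fraction of array bp re-emitted as chrUn contigs.
#' @param pericentric_window scaled pericentric window (bp).
#' @return A list with the simulation pieces (`genome`, `assembly`, `chrun`,
#'   `gaps`, `wgs`, `wgs_pairs`, `chip`, `te_library`, `config`) and a
#'   `truth` list (`layout`, `monomers`, `templates`, `cenpa_domains`,
#'   `cenpa_subfamilies`, `wgs_origin`, `wgs_labels`, `chip_labels`,
#'   `chip_origin`, `families`).
#' @export
simulate_scenario <- function(seed = 1L,
                              n_chromosomes = 2L,
                              n_families = 2L,
                              chrom_len = 200000L,
                              monomer_len = 738L,
                              blocks = c(25L, 8L, 25L),
                              between_divergence = 0.05,
                              within_divergence = 0.005,
                              n_te = 1L,
                              te_len = 400L,
                              coverage = 7.5,
                              read_len = 500L,
                              insert_mean = 2000,
                              insert_sd = 200,
                              wgs_error = 0.005,
                              chip_n = 50000L,
                              chip_fold = 10,
                              chip_read_len = 72L,
                              chip_error = 0.005,
                              unplaced_frac = 0.25,
                              pericentric_window = 20000L) {
  seed <- as.integer(seed)
  if (!n_families %in% c(1L, 2L)) abort("n_families must be 1 or 2")
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                 20L))
  # proximal-to-distal family order at each centromere: B then A
  fam_names <- if (n_families == 2L) c("CenSatB", "CenSatA") else "CenSatA"
  layout_blocks <- tibble(
    subfamily = c("S2", "S1", "S2"),
    n_monomers = as.integer(blocks)
  )
  te_library <- if (n_te > 0) {
    withr::with_seed(sub_seeds[1], seq_tbl("TE1", rand_dna(te_len)))
  } else seq_tbl(character(), character())
  # one template set per family, shared by all chromosomes
  templates <- list()
  for (f in seq_along(fam_names)) {
    templates[[fam_names[f]]] <-
      generate_subfamilies(monomer_len, 2, between_divergence,
                           within_divergence, seed = sub_seeds[2] + f)
  }
  arrays <- list()
  for (i in seq_len(n_chromosomes)) {
    pieces <- list()
    for (f in seq_along(fam_names)) {
      fam <- fam_names[f]
      tmpl <- templates[[fam]]
      te_ins <- NULL
      if (i == 1 && fam == "CenSatA" && n_te > 0) {
        # inside the first flanking S2 block, away from the CENP-A domain
        te_ins <- tibble(name = "TE1", sequence = te_library$seq[1],
                         monomer_index = 12L,
                         offset = as.integer(monomer_len / 2))
      }
      a <- build_satellite_array(
        setNames(tmpl$sequence[tmpl$role == "template"],
                 tmpl$subfamily[tmpl$role == "template"]),
        layout_blocks, te_insertions = te_ins,
        within_divergence = within_divergence,
        seed = sub_seeds[4] + 10L * i + f)
      a$spans$family <- fam
      pieces[[fam]] <- a
    }
    seqs <- vapply(pieces, function(p) p$sequence, character(1))
    offs <- cumsum(c(0L, head(nchar(seqs), -1)))
    spans <- bind_rows(lapply(seq_along(pieces), function(f) {
      sp <- pieces[[f]]$spans
      sp$start <- sp$start + offs[f]
      sp$end <- sp$end + offs[f]
      sp
    }))
    arrays[[i]] <- list(sequence = paste(seqs, collapse = ""),
                        spans = spans, family = fam_names[1])
  }
  array_lens <- vapply(arrays, function(a) nchar(a$sequence), numeric(1))
  asm <- assemble_genome(arrays, flank_len = chrom_len - max(array_lens),
                         unplaced_frac = unplaced_frac,
                         gap_edge_retain = 2L * monomer_len,
                         seed = sub_seeds[8])
  cenpa_subfams <- paste0(fam_names, ".S1")
  domains <- cenpa_domains_from_monomers(asm$monomers, cenpa_subfams)
  wgs <- simulate_paired_reads(asm$genome, coverage = coverage,
                               read_len = read_len,
                               insert_mean = insert_mean,
                               insert_sd = insert_sd,
                               sub_error_rate = wgs_error,
                               seed = sub_seeds[9])
  chip <- simulate_chip_reads(asm$genome, domains, fold = chip_fold,
                              n_reads = chip_n, read_len = chip_read_len,
                              sub_error_rate = chip_error,
                              seed = sub_seeds[10])
  wgs_labels <- label_reads_truth(wgs$origin, asm$monomers, domains)
  cfg <- censat_config(coverage = coverage, read_len = read_len,
                       pericentric_window = pericentric_window,
                       seed = seed)
  template_tbl <- bind_rows(lapply(fam_names, function(f) {
    t <- templates[[f]]
    tibble(family = f,
           subfamily = ifelse(t$role == "ancestral", paste0(f, ".ancestral"),
                              paste0(f, ".", t$subfamily)),
           role = t$role, sequence = t$sequence)
  }))
  list(
    genome = asm$genome, assembly = asm$assembly, chrun = asm$chrun,
    gaps = asm$gaps, wgs = wgs$reads, wgs_pairs = wgs$pairs,
    chip = chip$reads, te_library = te_library, config = cfg,
    truth = list(
      layout = asm$layout, monomers = asm$monomers,
      templates = template_tbl, cenpa_domains = domains,
      cenpa_subfamilies = cenpa_subfams,
      wgs_origin = wgs$origin, wgs_labels = wgs_labels,
      chip_labels = chip$labels, chip_origin = chip$origin,
      families = fam_names
    )
  )
}
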
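#' Pipeline configuration
#'
#' Returns the full set of tunable constants used across the pipeline, with
#' defaults at the scale of a mammalian whole-genome shotgun study: 50 bp
#' k-mer windows with a 1 bp slide, 7.5x read coverage, 2 Mb pericentric
#' windows adjacent to centromere assembly gaps, a minimum of 10 mate pairs
#' per network edge, a multi-copy call at more than 2 standard deviations
#' above the single-copy k-mer mean, a 2-fold (log2 = 1) ChIP enrichment
#' threshold called in two background comparisons, 200 bp consensus windows
#' with 100 bp slide clustered over k = 2..20, 100 bootstrap replicates and
#' ten genomic background replicates.
#'
#' All values can be overridden by name; [read_config()] loads the same
#' document from YAML.  Synthetic test genomes are run with
#' `pericentric_window` scaled down (see [simulate_scenario()]); the
#' constants here keep study-scale values expressible.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list of class `censat_config`.
#' @export
#' @examples
#' cfg <- censat_config(pericentric_window = 20000)
#' cfg$k
censat_config <- function(...) {
  cfg <- list(
    k = 50L,                      # k-mer length (bp)
    coverage = 7.5,               # WGS fold coverage
    read_len = 500L,              # WGS read length (bp)
    pericentric_window = 2e6,     # window adjacent to centromere gap (bp)
    min_pair_edge = 10L,          # mate pairs required to keep a network edge
    copy_sd_mult = 2,             # multi-copy if count > mu + mult * sd
    enrich_log2_threshold = 1,    # log2 ratio for an enriched k-mer (2-fold)
    n_calling_reps = 2L,          # background replicates a call must pass
    min_continuous_enriched_bp = 100L, # CENP-A[+] requires a run this long
                                  # (two full k-mer lengths; one isolated
                                  # enriched k-mer is too weak a signal)
    min_identity = 0.8,           # annotation identity floor
    min_span = 50L,               # annotation span floor (bp)
    family_min_identity = 0.95,   # consensus clustering: >95% identity
    family_min_overlap = 100L,    # ... over at least 100 aligned bp
    window_len = 200L,            # consensus window length (bp)
    window_slide = 100L,          # consensus window slide (bp)
    k_range = c(2L, 20L),         # k-means model search range
    n_restarts = 10L,             # k-means restarts per k
    n_bootstrap = 100L,           # phylogeny bootstrap replicates
    n_background_reps = 10L,      # genomic background replicates
    n_permutations = 1000L,       # pericentric enrichment permutations
    pseudocount = 2,              # smoothing for count ratios; damps
                                  # shot noise on singleton k-mers
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = c("censat_config", "list"))
}

validate_config <- function(cfg) {
  if (cfg$k < 8) abort("k must be >= 8")
  if (cfg$window_slide > cfg$window_len) {
    abort("window_slide must not exceed window_len")
  }
  if (cfg$k_range[1] < 2) abort("k_range lower bound must be >= 2")
  counts <- c(
    cfg$coverage, cfg$read_len, cfg$pericentric_window, cfg$min_pair_edge,
    cfg$min_continuous_enriched_bp, cfg$window_len, cfg$window_slide,
    cfg$n_bootstrap, cfg$n_background_reps, cfg$n_permutations,
    cfg$n_restarts, cfg$n_calling_reps
  )
  if (any(counts <= 0)) abort("all counts in the config must be positive")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' The file is a flat mapping whose keys mirror [censat_config()]; missing
#' keys take the defaults.  The effective configuration is logged.
#'
#' @param path path to a YAML file.
#' @param ... further overrides applied after the file (highest precedence).
#' @return A `censat_config` list.
#' @export
read_config <- function(path, ...) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$k_range)) doc$k_range <- as.integer(doc$k_range)
  cfg <- do.call(censat_config, utils::modifyList(doc, list(...)))
  censat_log(paste0(
    "effective config: ",
    paste(names(cfg), vapply(cfg, function(x) paste(x, collapse = ".."),
                             character(1)),
          sep = "=", collapse = " ")
  ))
  cfg
}

#' @export
print.censat_config <- function(x, ...) {
  cat("<censat_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(x[[nm]], collapse = "..")))
  }
  invisible(x)
}

# Leveled, timestamped logging to stderr.  Stage functions report their
# input/output record counts through this; the default level keeps test
# output quiet.
censat_log <- function(msg, level = c("info", "warn", "debug")) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warn = 3L, off = 4L)
  floor_lvl <- getOption("censatr.log_level", "warn")
  if (ranks[[level]] >= ranks[[floor_lvl]]) {
    message(sprintf("[%s] %s %s", toupper(level),
                    format(Sys.time(), "%H:%M:%S"), msg))
  }
  invisible(NULL)
}
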
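## Pipeline configuration: every numeric threshold used anywhere in the
## pipeline lives here, so each constant has a single greppable source.

config_defaults <- function() {
  list(
    min_read_length = 35L,       # bp; shorter reads discarded
    dust_threshold = 1,          # DUST score; reads scoring > threshold discarded
    lca_min_score = 35,          # bits
    lca_max_evalue = 1.0e-5,
    lca_min_identity = 95,       # percent
    lca_top_percent = 10,        # percent of best bitscore
    lca_min_support = 0.01,      # percent of assigned reads
    lca_min_cover = 95,          # percent of query covered
    var_min_qual = 30,           # Phred
    var_cov_fraction = 0.5,      # fraction of mean depth
    rare_allele_floor = 0.1,     # proportion; alleles < floor dropped
    damage_score_threshold = 3,  # PMD score
    dmg_var_min_qual = 3,        # Phred, damage-restricted re-call
    dmg_var_min_cov = 3L,        # depth, damage-restricted re-call
    window_span = 35L,           # bp, linked-variant window
    hap_min_reads = 3L,          # spanning reads per allele combination
    hap_min_fraction = 0.15,     # fraction of spanning reads per combination
    n_dedup_replicates = 5L,     # independent dedup/variant-call replicates
    profile_length_cap = 160L,   # bp, damage-profile hard cap
    max_mismatch_rate = 0.1,     # mapper: reject above this mismatch fraction
    frag_mean_length = 65,       # bp, simulator log-normal location
    frag_spread = 0.25,          # simulator log-normal sdlog
    pmd_d = 0.3,                 # PMD prior: terminal deamination probability
    pmd_decay = 0.5,             # PMD prior: per-base geometric decay
    rng_seed = 1L
  )
}

config_fraction_keys <- function() {
  c("var_cov_fraction", "rare_allele_floor", "hap_min_fraction",
    "max_mismatch_rate", "frag_spread", "pmd_d", "pmd_decay")
}

#' Construct a validated pipeline configuration
#'
#' Every threshold of the sedaDNA pipeline, with defaults matching the
#' published analysis settings (35 bp minimum read length, DUST > 1 removal,
#' naive-LCA parameters, Phred 30 variant quality, half-mean-coverage depth
#' cutoff, 0.1 rare-allele floor, PMD score threshold 3, 35 bp linkage
#' windows, the "<3 reads or <15%" phased-haplotype filter, and five dedup
#' replicates).
#'
#' @param ... named overrides of the defaults; unknown names are an error.
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$window_span
#' pipeline_config(window_span = 50)$window_span
#' @export
pipeline_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all configuration overrides must be named")
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  int_keys <- c("min_read_length", "window_span", "hap_min_reads",
                "n_dedup_replicates", "profile_length_cap",
                "dmg_var_min_cov", "rng_seed")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  num_keys <- setdiff(names(cfg), c(int_keys, "rng_seed"))
  for (k in num_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop("configuration key '", k, "' must be a single number")
  }
  pos_keys <- setdiff(names(cfg), "rng_seed")
  for (k in pos_keys) {
    if (cfg[[k]] <= 0) stop("configuration key '", k, "' must be strictly positive")
  }
  for (k in config_fraction_keys()) {
    if (cfg[[k]] > 1) stop("configuration key '", k, "' must lie in (0, 1]")
  }
  if (cfg$window_span < 2L) stop("configuration key 'window_span' must be >= 2")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a flat key:value file
#'
#' The config dialect is one `key: value` pair per line; blank lines and
#' lines starting with `#` are ignored. Unset keys take the package
#' defaults; unknown keys are an error naming the key.
#'
#' @param path path to the config file.
#' @return A validated [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  over <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE))
      stop("malformed config line (expected 'key: value'): ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) stop("malformed value for config key '", key, "': ", val)
    over[[key]] <- num
  }
  do.call(pipeline_config, over)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("sedaDNA pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
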
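#' Pipeline configuration
#'
#' Collects every numeric threshold used across the pipeline into a single
#' validated object. Defaults reproduce the published analysis settings:
#' 23-nt flanks, the two matched-fraction filter steps (>0.90, then >0.80 with
#' a same-genus co-hit), the 27-nt minimum spacer length, the array-hit test
#' (global alignment at gap open/extend -3 with >13 identities), 90% repeat
#' clustering identity, 74% subtype-reference identity, the >=10 unique
#' protospacer gate, the orientation thresholds (0.3 bits and 5x the median)
#' and the PAM thresholds (0.5 bits and 10x the median, minimum size 2),
#' 25 kb cas-cluster proximity, and alpha 0.01 for the strand-bias test.
#'
#' @param flank_len flank length extracted either side of a protospacer (nt).
#' @param step1_frac matched-fraction threshold of filter step 1 (exclusive).
#' @param step2_frac matched-fraction threshold of filter step 2 (exclusive);
#'   must be below `step1_frac`.
#' @param min_spacer_len spacers shorter than this are removed (nt).
#' @param array_gap_open,array_gap_extend gap scores of the repeat-vs-flank
#'   global alignment used to detect hits inside CRISPR arrays.
#' @param array_identity_min a flank with strictly more identities than this
#'   to the repeat (either orientation) marks the hit as inside an array.
#' @param repeat_cluster_identity repeat clustering identity threshold.
#' @param subtype_identity minimum identity to a subtype reference repeat.
#' @param min_protospacers minimum unique protospacers for orientation/PAM calls.
#' @param orient_bits_min,orient_median_factor information-content thresholds
#'   for a flank side to qualify during orientation prediction.
#' @param pam_bits_min,pam_median_factor information-content thresholds for a
#'   position to be flagged as part of the PAM.
#' @param pam_min_size minimum number of flagged positions for a PAM call.
#' @param proximity_bp maximum array-to-cas-cluster distance for linking (bp).
#' @param alpha significance level of the strand-bias binomial test.
#' @param seed_word exact-match word size of the internal matcher (nt).
#' @param rng_seed integer seed recorded with the run (used by simulation).
#' @return object of class `spacerscope_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$flank_len
#' @export
pipeline_config <- function(flank_len = 23L,
                            step1_frac = 0.90,
                            step2_frac = 0.80,
                            min_spacer_len = 27L,
                            array_gap_open = -3,
                            array_gap_extend = -3,
                            array_identity_min = 13L,
                            repeat_cluster_identity = 0.90,
                            subtype_identity = 0.74,
                            min_protospacers = 10L,
                            orient_bits_min = 0.3,
                            orient_median_factor = 5,
                            pam_bits_min = 0.5,
                            pam_median_factor = 10,
                            pam_min_size = 2L,
                            proximity_bp = 25000L,
                            alpha = 0.01,
                            seed_word = 10L,
                            rng_seed = 1L) {
  cfg <- list(
    flank_len = as.integer(flank_len),
    step1_frac = step1_frac,
    step2_frac = step2_frac,
    min_spacer_len = as.integer(min_spacer_len),
    array_gap_open = array_gap_open,
    array_gap_extend = array_gap_extend,
    array_identity_min = as.integer(array_identity_min),
    repeat_cluster_identity = repeat_cluster_identity,
    subtype_identity = subtype_identity,
    min_protospacers = as.integer(min_protospacers),
    orient_bits_min = orient_bits_min,
    orient_median_factor = orient_median_factor,
    pam_bits_min = pam_bits_min,
    pam_median_factor = pam_median_factor,
    pam_min_size = as.integer(pam_min_size),
    proximity_bp = as.integer(proximity_bp),
    alpha = alpha,
    seed_word = as.integer(seed_word),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "spacerscope_config"
  cfg
}

validate_config <- function(cfg) {
  fracs <- c("step1_frac", "step2_frac", "repeat_cluster_identity",
             "subtype_identity", "alpha")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("config field '%s' must be a fraction in [0, 1]", f),
           call. = FALSE)
    }
  }
  if (cfg$step2_frac >= cfg$step1_frac) {
    stop("step2_frac must be strictly smaller than step1_frac", call. = FALSE)
  }
  if (cfg$flank_len < 1L) stop("flank_len must be >= 1", call. = FALSE)
  if (cfg$pam_min_size < 1L) stop("pam_min_size must be >= 1", call. = FALSE)
  if (cfg$seed_word < 1L) stop("seed_word must be >= 1", call. = FALSE)
  if (cfg$min_spacer_len < 1L) stop("min_spacer_len must be >= 1", call. = FALSE)
  if (cfg$proximity_bp < 0L) stop("proximity_bp must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.spacerscope_config <- function(x, ...) {
  cat("spacerscope pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a pipeline configuration as YAML
#'
#' Serialisation round-trips exactly: reading a written config yields
#' identical values.
#'
#' @param cfg a [pipeline_config()] object.
#' @param path file path of the YAML document.
#' @return `read_config()` returns a `spacerscope_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "spacerscope_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Short hash of a configuration, for run logging
#'
#' @param cfg a [pipeline_config()] object.
#' @return an 8-hex-digit string stable under serialisation round trips.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "spacerscope_config"))
  s <- paste(names(cfg), vapply(cfg, function(v) format(v, digits = 15), ""),
             sep = "=", collapse = ";")
  # 31-ary polynomial rolling hash over the canonical string
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
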
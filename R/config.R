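# Pipeline configuration: YAML round-trip, defaults and hashing.

#' Default pipeline configuration
#'
#' Stage parameters with their defaults: synteny (`min_anchors = 3`,
#' `max_gap` = 1/20 of chromosome length when unset), breakpoints
#' (`flank_width` 5 kb, `min_dup_len` 50 bp, `min_identity` 0.9,
#' reciprocity `tol` 1 kb), stats (`window` 500 kb, `step` 250 kb,
#' `B = 1000` envelope replicates), and the species-tree branch durations
#' in Myr (1.72 to the subgroup ancestor, 0.92 to the madeirensis split).
#' Simulation sizes default to a 1/100-scale karyotype so a full run stays
#' desk-sized.
#'
#' @param ... Name-value overrides of any default.
#' @return A named list (class `pipeline_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = "paracentric_out",
    simulate = list(
      chrom_names = c("A", "J", "U", "E", "O", "dot"),
      chrom_lengths = c(228000L, 236000L, 258000L, 208000L, 304000L, 14000L),
      markers_per_chrom = c(140L, 145L, 158L, 128L, 186L, 8L),
      marker_length = 400L,
      gc = 0.45),
    synteny = list(min_anchors = 3L, max_gap = NA_real_),
    breakpoints = list(flank_width = 1500L, min_dup_len = 50L,
                       min_identity = 0.9, tol = 1000L, min_score = 30),
    stats = list(window = 25000, step = 12500, B = 1000L),
    tree = list(age_subgroup = 1.72, age_ms_split = 0.92)
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline configuration
#'
#' YAML on disk; `read_config(write_config(cfg))` round-trips identically.
#'
#' @param path File path.
#' @return `read_config`: a `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Hash of a configuration (for output provenance)
#'
#' @param cfg A `pipeline_config`.
#' @return Character md5 hash of the canonical YAML serialization.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}
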
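# Shared fixture builders, constructed in code at test time.

# A genome with explicitly placed markers (and optional random sequence).
toy_genome <- function(taxon, chrom = "chr1", length = 10000L,
                       starts = integer(0), marker_len = 100L,
                       strands = NULL, ids = NULL, seed = NULL,
                       with_sequence = FALSE, gc = 0.45) {
  k <- length(starts)
  if (is.null(strands)) strands <- rep("+", k)
  if (is.null(ids)) ids <- sprintf("m%02d", seq_len(k))
  seqc <- NULL
  if (with_sequence) {
    if (!is.null(seed)) set.seed(seed)
    seqc <- random_dna(length, gc)
  }
  m <- data.frame(id = ids, start = as.integer(starts),
                  end = as.integer(starts + marker_len),
                  strand = strands, stringsAsFactors = FALSE)
  marker_genome(taxon, setNames(list(list(name = chrom,
                                          length = as.integer(length),
                                          markers = m, sequence = seqc)),
                                chrom))
}

# Random signed permutation of size n.
random_signed_perm <- function(n) {
  p <- sample.int(n)
  p * sample(c(-1L, 1L), n, replace = TRUE)
}

# All 2^n * n! signed permutations of size n (exhaustive, small n only).
all_signed_perms <- function(n) {
  pm <- function(v) {
    if (!length(v)) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v)) for (r in pm(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], r)
    out
  }
  out <- list()
  for (p in pm(seq_len(n))) for (s in 0:(2^n - 1L)) {
    e <- p
    neg <- which(bitwAnd(s, 2^(seq_len(n) - 1L)) > 0)
    e[neg] <- -e[neg]
    out[[length(out) + 1L]] <- e
  }
  out
}

# The 3 markers on each side of a position, in chromosomal order.
window_at <- function(genome, chrom, pos, k = 3L) {
  m <- marker_table(genome)
  m <- m[m$chrom == chrom, , drop = FALSE]
  c(tail(m$id[m$end <= pos], k), head(m$id[m$start >= pos], k))
}

# One shared template-pipeline run, computed on first use and cached for
# the whole test session (several files assert different facets of it).
.template_cache <- new.env(parent = emptyenv())
template_run <- function() {
  if (is.null(.template_cache$res)) {
    cfg <- default_config(outdir = file.path(tempdir(),
                                             "paracentric_template"))
    .template_cache$cfg <- cfg
    .template_cache$res <- run_pipeline(cfg, stages = "all")
  }
  .template_cache$res
}
template_cfg <- function() {
  template_run()
  .template_cache$cfg
}

# Single-inversion genome pair for breakpoint tests: an ancestor with
# evenly spaced markers and a derived copy carrying one event.  Returns
# the pair plus the realized derived-frame breakpoints.
single_inversion_pair <- function(seed, L = 80000L, n_markers = 50L,
                                  mechanism = "straight",
                                  offset = 0L, f_left = 0.25,
                                  f_right = 0.75, with_sequence = TRUE) {
  anc <- make_ancestral_genome(1L, L, n_markers, seed = seed,
                               chrom_names = "c1",
                               marker_length = 300L,
                               with_sequence = with_sequence,
                               taxon_id = "ancestor")
  clear <- offset + 60L
  l <- snap_intergenic(anc, "c1", round(f_left * L), clearance = clear)
  r <- snap_intergenic(anc, "c1", round(f_right * L), clearance = clear)
  ev <- inversion_event("inv1", "c1", l, r, mechanism = mechanism,
                        offset_left = offset, offset_right = offset)
  der <- apply_inversion(anc, ev)
  der$taxon_id <- "derived"
  list(ancestor = anc, derived = der, event = ev,
       realized = attr(der, "realized"))
}
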
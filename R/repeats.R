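# Repeat-landscape simulation: per-class counts with pericentromeric
# enrichment and telomere-ward density gradients.  Chromosomes are oriented
# centromere (0) -> telomere (length).

#' Define a repeat landscape model
#'
#' Each row of `classes` describes one repeat class:
#' `name` (one of LTR, nonLTR, DNA_transposon, satellite, microsatellite),
#' `count`, `unit_length` (bp), `pericentromeric_enrichment` (fold factor,
#' `>= 1` concentrates density toward the centromere end) and
#' `telomeric_gradient_slope` (relative density change per Mb toward the
#' telomere; 0 for none).  The default emulates a landscape where
#' transposable elements and satellites concentrate pericentromerically
#' while microsatellites increase nearly monotonically toward the
#' telomeres.
#'
#' @param classes Optional data.frame overriding the defaults.
#' @return A `repeat_model`.
#' @export
repeat_model <- function(classes = NULL) {
  if (is.null(classes))
    classes <- data.frame(
      name = c("LTR", "nonLTR", "DNA_transposon", "satellite",
               "microsatellite"),
      count = c(60L, 120L, 80L, 40L, 200L),
      unit_length = c(400L, 300L, 200L, 290L, 40L),
      pericentromeric_enrichment = c(4, 4, 6, 8, 1),
      telomeric_gradient_slope = c(0, 0, 0, 0, 2),
      stringsAsFactors = FALSE)
  stopifnot(all(classes$count >= 0L),
            all(classes$pericentromeric_enrichment >= 1),
            all(classes$unit_length > 0L))
  structure(list(classes = classes), class = "repeat_model")
}

# Relative placement density along one chromosome, on a fine grid.
# Uniform component, plus an exponentially decaying pericentromeric bump
# (scale 10% of chromosome length), plus a linear telomere-ward gradient.
repeat_weight_profile <- function(x_mid, L, enrichment, slope_per_mb) {
  w <- rep(1, length(x_mid))
  if (enrichment > 1)
    w <- w + (enrichment - 1) * exp(-x_mid / (0.1 * L))
  if (slope_per_mb != 0)
    w <- w * pmax(0, 1 + slope_per_mb * (x_mid - L / 2) / 1e6)
  w
}

#' Place repeats on a genome
#'
#' Samples `count` repeat midpoints per class and chromosome from the
#' class's spatial density (uniform times enrichment/gradient factors) and
#' returns BED-style records (0-based half-open).  With enrichment 1 and
#' slope 0 the placement is exactly uniform.  Counts are interpreted per
#' chromosome.
#'
#' @param genome A `marker_genome`.
#' @param model A [repeat_model()].
#' @param seed Integer seed.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`
#'   (repeat class) and `id`, sorted by chromosome and start.
#' @export
place_repeats <- function(genome, model, seed) {
  stopifnot(inherits(model, "repeat_model"))
  out <- list()
  for (ci in seq_along(genome$chromosomes)) {
    ch <- genome$chromosomes[[ci]]
    L <- ch$length
    grid <- 1000L
    cell <- L / grid
    x_mid <- (seq_len(grid) - 0.5) * cell
    for (ri in seq_len(nrow(model$classes))) {
      cl <- model$classes[ri, ]
      if (cl$count == 0L) next
      set.seed(split_seed(seed, ci * 131L + ri))
      w <- repeat_weight_profile(x_mid, L, cl$pericentromeric_enrichment,
                                 cl$telomeric_gradient_slope)
      cells <- sample.int(grid, cl$count, replace = TRUE, prob = w)
      mids <- (cells - 1L) * cell + runif(cl$count) * cell
      half <- cl$unit_length / 2
      start <- pmax(0L, as.integer(round(mids - half)))
      end <- pmin(L, start + cl$unit_length)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch$name, start = start, end = as.integer(end),
        name = cl$name,
        id = sprintf("%s_%s_%04d", ch$name, cl$name, seq_len(cl$count)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), id = character(),
                      stringsAsFactors = FALSE))
  bed <- do.call(rbind, out)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  rownames(bed) <- NULL
  bed
}
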
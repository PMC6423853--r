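# Distributional and arithmetic genome statistics: G-tests against
# chromosome-length expectations, windowed repeat-density profiles with
# Monte-Carlo random-placement envelopes, regressions, coverage and
# assembly summary metrics.

#' G-test of counts against a length-proportional expectation
#'
#' Tests whether per-chromosome feature counts depart from the expectation
#' proportional to chromosome length: `E_i = sum(O) * L_i / sum(L)`,
#' `G = 2 * sum(O_i * ln(O_i / E_i))` (zero observed cells contribute 0),
#' with a chi-square upper tail on `k - 1` degrees of freedom.
#'
#' @param observed Integer counts per category (>= 0, sum > 0).
#' @param lengths Exposures (chromosome lengths in bp, > 0).
#' @param categories Optional category labels.
#' @return A `g_test` result: list with `G`, `df`, `p`, `observed`,
#'   `expected` and `deviations` (observed - expected).
#' @examples
#' genes <- c(dot = 91, A = 2322, J = 2452, U = 2496, E = 2591, O = 3229)
#' bp <- c(1375632, 22857882, 23583473, 25800175, 20818511, 30426146)
#' g_test(genes, bp)   # G = 113.61, df = 5, p < 1e-6
#' @export
g_test <- function(observed, lengths, categories = names(observed)) {
  if (any(lengths <= 0)) stop("all lengths must be > 0")
  if (any(observed < 0)) stop("counts must be >= 0")
  if (sum(observed) <= 0) stop("total count must be > 0")
  if (length(observed) != length(lengths))
    stop("observed and lengths must have equal length")
  if (is.null(categories)) categories <- as.character(seq_along(observed))
  expected <- sum(observed) * lengths / sum(lengths)
  terms <- ifelse(observed == 0, 0, observed * log(observed / expected))
  G <- 2 * sum(terms)
  df <- length(observed) - 1L
  structure(list(G = G, df = df, p = pchisq(G, df, lower.tail = FALSE),
                 observed = setNames(observed, categories),
                 expected = setNames(expected, categories),
                 deviations = setNames(observed - expected, categories)),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("<g_test> G = %.2f, d.f. = %d, P = %.3g\n", x$G, x$df, x$p))
  d <- data.frame(observed = x$observed, expected = round(x$expected, 1),
                  deviation = round(x$deviations))
  print(d)
  invisible(x)
}

#' Windowed repeat-density profile along a chromosome
#'
#' Counts repeat midpoints in sliding windows tiled from the centromere
#' (position 0) toward the telomere.
#'
#' @param repeats BED-style data.frame (`start`, `end`; optionally
#'   restricted to one chromosome beforehand) or a numeric vector of
#'   midpoints.
#' @param chrom_length Chromosome length in bp.
#' @param window Window size in bp (default 500 kb at full scale).
#' @param step Step between window starts in bp (`window >= step > 0`).
#' @return A `window_profile`: list with `windows` (data.frame `start`,
#'   `end`, `mid`) and `density` (counts per window).
#' @export
window_density <- function(repeats, chrom_length, window = 5e5,
                           step = 2.5e5) {
  if (!(window >= step && step > 0)) stop("need window >= step > 0")
  mids <- if (is.data.frame(repeats)) (repeats$start + repeats$end) / 2
  else as.numeric(repeats)
  starts <- seq(0, max(0, chrom_length - 1), by = step)
  ends <- pmin(starts + window, chrom_length)
  counts <- vapply(seq_along(starts), function(i)
    sum(mids >= starts[i] & mids < starts[i] + window), 0)
  structure(list(windows = data.frame(start = starts, end = ends,
                                      mid = (starts + ends) / 2),
                 density = counts,
                 window = window, step = step,
                 chrom_length = chrom_length),
            class = "window_profile")
}

#' Monte-Carlo envelope for repeat density under random placement
#'
#' Places `n_repeats` midpoints uniformly on the chromosome `B` times and
#' returns the per-window 2.5% and 97.5% count percentiles: the 95%
#' confidence envelope around the expectation if repeats were distributed
#' at random.
#'
#' @param n_repeats Number of repeats.
#' @param chrom_length Chromosome length in bp.
#' @param window,step Window geometry as in [window_density()].
#' @param B Number of Monte-Carlo replicates (>= 100; default 1000).
#' @param seed Integer seed.
#' @return data.frame with `start`, `end`, `env_low`, `env_high`, `mean`.
#' @export
random_placement_envelope <- function(n_repeats, chrom_length, window = 5e5,
                                      step = 2.5e5, B = 1000L, seed = 1L) {
  if (B < 100L) stop("B must be >= 100")
  set.seed(seed)
  starts <- seq(0, max(0, chrom_length - 1), by = step)
  nw <- length(starts)
  if (n_repeats == 0L) {
    counts <- matrix(0, nrow = B, ncol = nw)
  } else {
    counts <- matrix(0, nrow = B, ncol = nw)
    for (b in seq_len(B)) {
      mids <- runif(n_repeats, 0, chrom_length)
      counts[b, ] <- vapply(starts, function(s)
        sum(mids >= s & mids < s + window), 0)
    }
  }
  data.frame(start = starts, end = pmin(starts + window, chrom_length),
             env_low = apply(counts, 2L, quantile, probs = 0.025),
             env_high = apply(counts, 2L, quantile, probs = 0.975),
             mean = colMeans(counts))
}

#' Simple linear regression of density on position
#'
#' Ordinary least squares with a two-sided t-test on the slope; used for
#' telomere-ward density gradients.
#'
#' @param positions Window midpoints (>= 3 points, non-constant).
#' @param densities Densities per window.
#' @return List with `slope`, `intercept`, `r2`, `p`.
#' @export
linreg_density <- function(positions, densities) {
  if (length(positions) < 3L) stop("need at least 3 points")
  if (var(positions) == 0) stop("zero variance in positions")
  fit <- lm(densities ~ positions)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r2 = sm$r.squared, p = unname(sm$coefficients[2L, 4L]))
}

#' Pearson correlation with a two-sided test
#'
#' @param x,y Numeric vectors.
#' @return List with `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Sequencing coverage in genome folds
#'
#' @param total_bp Total sequenced bases.
#' @param genome_size Genome size in bp (> 0).
#' @return Raw fold coverage (display rounded to the nearest integer).
#' @examples
#' round(coverage_fold(10025366103, 150e6))  # ~67-fold
#' @export
coverage_fold <- function(total_bp, genome_size) {
  if (genome_size <= 0) stop("genome_size must be > 0")
  total_bp / genome_size
}

#' Gene density in kb of assembly per gene
#'
#' @param assembly_length Assembly length in bp.
#' @param n_genes Number of genes (> 0).
#' @return kb per gene (raw; display to 2 decimals).
#' @examples
#' round(gene_density(129237000, 13317), 2)  # 9.70
#' @export
gene_density <- function(assembly_length, n_genes) {
  if (n_genes <= 0) stop("n_genes must be > 0")
  (assembly_length / n_genes) / 1000
}

#' Percentage helper
#'
#' @param num,den Numerator and denominator.
#' @return `100 * num / den` (raw; display to 1 decimal).
#' @export
percent_of <- function(num, den) {
  if (den == 0) stop("denominator must be non-zero")
  100 * num / den
}

#' Assembly summary statistics
#'
#' N50 is the length of the scaffold for which 50% of the total assembly
#' length is contained in scaffolds of that size or larger; L50 is the
#' ranking order of the scaffold that defines the N50 length.  GC content
#' is computed over `sequences` when provided.
#'
#' @param scaffold_lengths Scaffold lengths in bp (> 0, non-empty).
#' @param sequences Optional character vector of scaffold sequences.
#' @return An `assembly_stats` list: `n_scaffolds`, `total_length`, `N50`,
#'   `L50`, `GC` (or `NA`).
#' @examples
#' assembly_stats(c(5, 4, 3, 2, 1))  # N50 = 4, L50 = 2
#' @export
assembly_stats <- function(scaffold_lengths, sequences = NULL) {
  if (!length(scaffold_lengths)) stop("empty scaffold list")
  if (any(scaffold_lengths <= 0)) stop("scaffold lengths must be > 0")
  len <- sort(scaffold_lengths, decreasing = TRUE)
  csum <- cumsum(len)
  i <- which(csum >= sum(len) / 2)[1L]
  gc <- NA_real_
  if (!is.null(sequences)) {
    s <- paste(toupper(sequences), collapse = "")
    bases <- strsplit(s, "")[[1L]]
    gc <- mean(bases %in% c("G", "C"))
  }
  structure(list(n_scaffolds = length(scaffold_lengths),
                 total_length = sum(scaffold_lengths),
                 N50 = len[i], L50 = i, GC = gc),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("<assembly_stats> %d scaffolds, %.0f bp; N50 = %.0f, L50 = %d%s\n",
              x$n_scaffolds, x$total_length, x$N50, x$L50,
              if (is.na(x$GC)) "" else sprintf(", GC = %.1f%%", 100 * x$GC)))
  invisible(x)
}

#' Genome size from propidium-iodide flow cytometry
#'
#' `GS_target = GS_standard * fluor_ratio`, with the fluorescence ratio
#' `PI-fluor(target) / PI-fluor(standard)`.
#'
#' @param gs_standard Standard genome size in Mb (e.g. 328.0).
#' @param fluor_ratio Fluorescence ratio (> 0).
#' @return Target genome size in Mb (raw; display to 3 decimals).
#' @export
flow_cytometry_size <- function(gs_standard, fluor_ratio) {
  if (fluor_ratio <= 0) stop("fluorescence ratio must be > 0")
  gs_standard * fluor_ratio
}
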
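# Core container: a taxon's genome as ordered, oriented gene markers over an
# (optional) nucleotide sequence.  All coordinates are 0-based half-open;
# conversion to/from 1-based closed GFF3 happens only in the readers/writers.

#' Construct a marker genome
#'
#' A `marker_genome` holds one taxon's chromosomes, each an ordered set of
#' non-overlapping oriented gene markers over an optional nucleotide
#' sequence.  It is the substrate of every pipeline stage.
#'
#' @param taxon_id Character label for the taxon.
#' @param chromosomes Named list; each element a list with fields `name`,
#'   `length` (bp), `markers` (data.frame with columns `id`, `start`, `end`,
#'   `strand`; 0-based half-open) and optionally `sequence` (single
#'   character string of A/C/G/T).
#' @return An object of class `marker_genome`.
#' @export
marker_genome <- function(taxon_id, chromosomes) {
  g <- structure(list(taxon_id = taxon_id, chromosomes = chromosomes),
                 class = "marker_genome")
  validate_marker_genome(g)
  g
}

#' @export
print.marker_genome <- function(x, ...) {
  cat(sprintf("<marker_genome> taxon '%s': %d chromosome(s)\n",
              x$taxon_id, length(x$chromosomes)))
  for (ch in x$chromosomes) {
    cat(sprintf("  %-6s %9d bp  %4d markers%s\n", ch$name, ch$length,
                nrow(ch$markers),
                if (is.null(ch$sequence)) "" else "  [sequence]"))
  }
  invisible(x)
}

#' Validate the marker-genome invariants
#'
#' Checks that marker intervals are sorted, non-overlapping and within
#' bounds, strands are `+`/`-`, and marker ids are unique within the taxon.
#' Called by every constructor; exported for use after manual edits.
#'
#' @param g A `marker_genome`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_marker_genome <- function(g) {
  stopifnot(is.character(g$taxon_id), length(g$taxon_id) == 1L)
  all_ids <- character(0)
  for (ch in g$chromosomes) {
    m <- ch$markers
    stopifnot(is.data.frame(m),
              all(c("id", "start", "end", "strand") %in% names(m)))
    if (nrow(m)) {
      if (any(m$start < 0L) || any(m$end > ch$length) || any(m$start >= m$end))
        stop("chromosome ", ch$name, ": marker interval out of bounds")
      if (is.unsorted(m$start, strictly = FALSE))
        stop("chromosome ", ch$name, ": markers not sorted by start")
      if (nrow(m) > 1L && any(m$start[-1L] < m$end[-nrow(m)]))
        stop("chromosome ", ch$name, ": overlapping markers")
      if (!all(m$strand %in% c("+", "-")))
        stop("chromosome ", ch$name, ": strand must be '+' or '-'")
      all_ids <- c(all_ids, m$id)
    }
    if (!is.null(ch$sequence) && nchar(ch$sequence) != ch$length)
      stop("chromosome ", ch$name, ": sequence length != declared length")
  }
  if (anyDuplicated(all_ids))
    stop("duplicate marker id(s) within taxon: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  invisible(TRUE)
}

#' @export
summary.marker_genome <- function(object, ...) {
  d <- do.call(rbind, lapply(object$chromosomes, function(ch)
    data.frame(chrom = ch$name, length = ch$length,
               n_markers = nrow(ch$markers))))
  rownames(d) <- NULL
  d
}

chrom_names <- function(g) vapply(g$chromosomes, `[[`, "", "name")

get_chrom <- function(g, chrom) {
  i <- match(chrom, chrom_names(g))
  if (is.na(i)) stop("no chromosome '", chrom, "' in taxon ", g$taxon_id)
  g$chromosomes[[i]]
}

set_chrom <- function(g, chrom, value) {
  i <- match(chrom, chrom_names(g))
  if (is.na(i)) stop("no chromosome '", chrom, "' in taxon ", g$taxon_id)
  g$chromosomes[[i]] <- value
  g
}

#' All markers of a genome as one table
#'
#' @param g A `marker_genome`.
#' @return data.frame with columns `chrom`, `id`, `start`, `end`, `strand`.
#' @export
marker_table <- function(g) {
  out <- do.call(rbind, lapply(g$chromosomes, function(ch) {
    if (!nrow(ch$markers)) return(NULL)
    cbind(data.frame(chrom = ch$name, stringsAsFactors = FALSE), ch$markers)
  }))
  if (is.null(out))
    out <- data.frame(chrom = character(), id = character(),
                      start = integer(), end = integer(),
                      strand = character())
  rownames(out) <- NULL
  out
}

#' Reverse complement of a nucleotide string
#'
#' @param s Single character string (A/C/G/T/N, either case).
#' @return Reverse complement, uppercase.
#' @export
revcomp <- function(s) {
  if (!nchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Random DNA sequence at a given GC content
#'
#' Bases are drawn i.i.d.; GC fraction defaults to 0.45, the composition
#' used for simulated intergenic sequence.
#'
#' @param n Length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @return Character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.45) {
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

subseq_chr <- function(ch, start, end) {
  # 0-based half-open extraction from a chromosome's sequence
  if (is.null(ch$sequence)) stop("chromosome ", ch$name, " has no sequence")
  start <- max(0L, start); end <- min(ch$length, end)
  if (end <= start) return("")
  substr(ch$sequence, start + 1L, end)
}

# Hierarchical RNG splitting: one top-level seed, deterministic sub-seeds per
# chromosome/event index.  Kept below 2^31 - 1.
split_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483587)
}
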
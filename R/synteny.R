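# Synteny stage: ortholog anchors from shared marker ids, greedy collinear
# chaining into signed blocks, and per-chromosome signed permutations.

#' Find ortholog anchors between two marker genomes
#'
#' Markers are matched by id (one anchor per id shared by both genomes;
#' ids private to one genome are ignored).  The relative strand of an
#' anchor is the product of the two marker strands.  Duplicated ids within
#' one genome are an error: paralogy is unsupported.
#'
#' @param g1,g2 `marker_genome` objects.
#' @return data.frame of anchors sorted by genome-1 position, with columns
#'   `marker_id`, `chrom1`, `start1`, `end1`, `strand1`, `chrom2`,
#'   `start2`, `end2`, `strand2`, `rel_strand` (`+1`/`-1`).
#' @export
find_anchors <- function(g1, g2) {
  m1 <- marker_table(g1); m2 <- marker_table(g2)
  if (anyDuplicated(m1$id)) stop("duplicate marker ids in genome 1 (",
                                 g1$taxon_id, "): paralogy unsupported")
  if (anyDuplicated(m2$id)) stop("duplicate marker ids in genome 2 (",
                                 g2$taxon_id, "): paralogy unsupported")
  shared <- intersect(m1$id, m2$id)
  i1 <- match(shared, m1$id); i2 <- match(shared, m2$id)
  a <- data.frame(marker_id = shared,
                  chrom1 = m1$chrom[i1], start1 = m1$start[i1],
                  end1 = m1$end[i1], strand1 = m1$strand[i1],
                  chrom2 = m2$chrom[i2], start2 = m2$start[i2],
                  end2 = m2$end[i2], strand2 = m2$strand[i2],
                  stringsAsFactors = FALSE)
  a$rel_strand <- ifelse(a$strand1 == a$strand2, 1L, -1L)
  a <- a[order(a$chrom1, a$start1), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Chain anchors into signed synteny blocks
#'
#' Builds maximal runs of anchors that are collinear in both genomes: all
#' anchors of a run share a relative strand, genome-2 positions are
#' monotone (increasing for `+`, decreasing for `-`), and the gap between
#' consecutive anchors is at most `max_gap` in both genomes.  Runs with
#' fewer than `min_anchors` anchors are discarded (their anchors dropped
#' as micro-rearrangements, not merged into neighbouring blocks).  Block
#' spans are the hulls of their anchors.
#'
#' @param anchors Anchor table from [find_anchors()].
#' @param min_anchors Minimum anchors per block (default 3).
#' @param max_gap Maximum inter-anchor gap in bp in either genome
#'   (default 1e6).
#' @return A `synteny_blocks` data.frame with columns `block_id`, `chrom1`,
#'   `start1`, `end1`, `chrom2`, `start2`, `end2`, `orientation`
#'   (`+1`/`-1`) and `n_anchors`, ordered and numbered by genome-1
#'   position.
#' @export
chain_blocks <- function(anchors, min_anchors = 3L, max_gap = 1e6) {
  empty <- structure(
    data.frame(block_id = integer(), chrom1 = character(),
               start1 = integer(), end1 = integer(), chrom2 = character(),
               start2 = integer(), end2 = integer(), orientation = integer(),
               n_anchors = integer(), stringsAsFactors = FALSE),
    class = c("synteny_blocks", "data.frame"))
  if (!nrow(anchors)) return(empty)
  a <- anchors[order(anchors$chrom1, anchors$start1), , drop = FALSE]
  build_runs <- function(a) {
    runs <- list()
    run <- 1L
    for (i in seq_len(nrow(a))[-1L]) {
      p <- run[length(run)]
      ok <- a$chrom1[i] == a$chrom1[p] && a$chrom2[i] == a$chrom2[p] &&
        a$rel_strand[i] == a$rel_strand[p] &&
        (a$start1[i] - a$end1[p]) <= max_gap
      if (ok) {
        want <- a$rel_strand[i]
        dir_ok <- sign(a$start2[i] - a$start2[p]) == want
        gap2 <- if (want == 1L) a$start2[i] - a$end2[p]
                else a$start2[p] - a$end2[i]
        ok <- dir_ok && gap2 <= max_gap
      }
      if (ok) run <- c(run, i)
      else { runs[[length(runs) + 1L]] <- run; run <- i }
    }
    runs[[length(runs) + 1L]] <- run
    runs
  }
  # drop runs shorter than min_anchors (micro-rearrangements) and re-chain
  # the survivors, so collinear runs merge across the hole if the gap
  # constraint still holds; iterate to a fixed point
  repeat {
    runs <- build_runs(a)
    short <- runs[lengths(runs) < min_anchors]
    if (!length(short)) break
    a <- a[-unlist(short), , drop = FALSE]
    if (!nrow(a)) return(empty)
  }
  blocks <- do.call(rbind, lapply(runs, function(r) {
    s <- a[r, , drop = FALSE]
    data.frame(chrom1 = s$chrom1[1L], start1 = min(s$start1),
               end1 = max(s$end1), chrom2 = s$chrom2[1L],
               start2 = min(s$start2), end2 = max(s$end2),
               orientation = s$rel_strand[1L], n_anchors = nrow(s),
               stringsAsFactors = FALSE)
  }))
  blocks <- blocks[order(blocks$chrom1, blocks$start1), , drop = FALSE]
  blocks <- cbind(block_id = seq_len(nrow(blocks)), blocks)
  rownames(blocks) <- NULL
  structure(blocks, class = c("synteny_blocks", "data.frame"))
}

#' Summary statistics for a set of synteny blocks
#'
#' @param blocks A `synteny_blocks` table.
#' @return List with `n_blocks`, `mean_size_mb` (mean genome-1 span in Mb)
#'   and `n_inverted` (orientation `-1`).  All zero for an empty set.
#' @export
block_stats <- function(blocks) {
  if (!nrow(blocks))
    return(list(n_blocks = 0L, mean_size_mb = 0, n_inverted = 0L))
  list(n_blocks = nrow(blocks),
       mean_size_mb = mean(blocks$end1 - blocks$start1) / 1e6,
       n_inverted = sum(blocks$orientation == -1L))
}

#' Signed permutation of the blocks on one chromosome
#'
#' Blocks are numbered by their genome-2 order (ties broken by genome-2
#' start coordinate) and listed in genome-1 order, each signed by its
#' orientation.  The identity permutation `(+1, ..., +n)` means no
#' rearrangement.
#'
#' @param blocks A `synteny_blocks` table.
#' @param chrom Genome-1 chromosome to extract.
#' @return A [signed_permutation()].
#' @export
to_signed_permutation <- function(blocks, chrom) {
  b <- blocks[blocks$chrom1 == chrom, , drop = FALSE]
  if (!nrow(b)) return(signed_permutation(integer(0), chrom = chrom))
  if (length(unique(b$chrom2)) > 1L)
    stop("blocks on ", chrom, " map to multiple genome-2 chromosomes (",
         paste(unique(b$chrom2), collapse = ", "),
         "): translocation unsupported")
  b <- b[order(b$start1), , drop = FALSE]
  number <- rank(b$start2, ties.method = "first")
  signed_permutation(as.integer(b$orientation * number), chrom = chrom)
}
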
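# Breakpoint isolation: intervals between contiguous synteny blocks, flank
# mapping across genomes with overhangs, reciprocal-consistency checks,
# flanking inverted-duplication detection and mechanism classification.

default_scoring <- function() list(match = 1, mismatch = -2,
                                   gap_open = 4, gap_ext = 1)

#' Breakpoint intervals between contiguous synteny blocks
#'
#' A synteny breakpoint is the nucleotide interval between two adjacent
#' blocks on the reference genome; abutting blocks yield a zero-length
#' interval at the shared coordinate.  Labels run proximal (centromere,
#' position 0) to distal.
#'
#' @param blocks A `synteny_blocks` table (one or more chromosomes).
#' @return data.frame with columns `chrom`, `start`, `end`, `left_block`,
#'   `right_block`, `label`; empty for fewer than two blocks per
#'   chromosome.
#' @export
breakpoint_intervals <- function(blocks) {
  out <- list()
  for (chr in unique(blocks$chrom1)) {
    b <- blocks[blocks$chrom1 == chr, , drop = FALSE]
    b <- b[order(b$start1), , drop = FALSE]
    if (nrow(b) < 2L) next
    for (i in seq_len(nrow(b) - 1L)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = b$end1[i], end = b$start1[i + 1L],
        left_block = b$block_id[i], right_block = b$block_id[i + 1L],
        label = sprintf("%s_bk%d", chr, i), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), left_block = integer(),
                      right_block = integer(), label = character(),
                      stringsAsFactors = FALSE))
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

# Best local alignment of a query string against one target string,
# affine gaps, fixed scoring.  Returns NULL below min_score.
local_hit <- function(query, target, scoring, min_score) {
  if (!nchar(query) || !nchar(target)) return(NULL)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(target),
    type = "local", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  if (Biostrings::score(aln) < min_score) return(NULL)
  pr <- aln@pattern@range; sr <- aln@subject@range
  list(qstart = BiocGenerics::start(pr) - 1L, qend = BiocGenerics::end(pr),
       tstart = BiocGenerics::start(sr) - 1L, tend = BiocGenerics::end(sr),
       score = Biostrings::score(aln),
       identity = Biostrings::pid(aln) / 100,
       aligned_length = BiocGenerics::width(pr))
}

#' Map a breakpoint flank region onto another genome
#'
#' Extracts the breakpoint interval plus `flank_width` bp into each
#' flanking block and aligns it locally (affine gaps; match +1, mismatch
#' -2, gap open 4, extend 1) against the target genome on both strands.
#' For a true inversion breakpoint the query splits into two hits on
#' opposite relative strands, each with an overhang where homology ends.
#' After the best hit is found, the unaligned query remainder is realigned
#' to recover the second hit.
#'
#' @param genome Query `marker_genome` (with sequence).
#' @param chrom Query chromosome.
#' @param bp_start,bp_end Breakpoint interval (0-based half-open; equal for
#'   a point breakpoint).
#' @param target Target `marker_genome` (with sequence).
#' @param flank_width Flank extension in bp (default 5000).
#' @param target_window Optional list `(chrom, start, end)` — or a list of
#'   such lists — restricting the target search space (e.g. neighbourhoods
#'   of the matching breakpoint gaps; keeps the alignment problem small).
#' @param min_score Minimum alignment score to report a hit (default 30).
#' @param max_hits Maximum hits to report (default 2).
#' @param scoring Scoring list; see [default_scoring()].
#' @return A `flank_alignment_report`: list with `query` (taxon, chrom,
#'   region, breakpoint) and `hits` (data.frame sorted by score with
#'   target coordinates, strand, aligned length, overhangs and identity).
#' @export
map_flank <- function(genome, chrom, bp_start, bp_end, target,
                      flank_width = 5000L, target_window = NULL,
                      min_score = 30, max_hits = 2L,
                      scoring = default_scoring()) {
  ch <- get_chrom(genome, chrom)
  q_start <- max(0L, bp_start - flank_width)
  q_end <- min(ch$length, bp_end + flank_width)
  query <- subseq_chr(ch, q_start, q_end)
  qlen <- nchar(query)
  targets <- if (is.null(target_window)) {
    lapply(target$chromosomes, function(tc)
      list(chrom = tc$name, offset = 0L, seq = tc$sequence,
           tlen = tc$length))
  } else {
    wins <- if (!is.null(target_window$chrom)) list(target_window)
    else target_window
    lapply(wins, function(w) {
      tc <- get_chrom(target, w$chrom)
      s <- max(0L, w$start); e <- min(tc$length, w$end)
      list(chrom = tc$name, offset = s, seq = subseq_chr(tc, s, e),
           tlen = tc$length)
    })
  }
  hits <- list()
  segments <- list(c(0L, qlen))   # unexplained query segments (0-based)
  for (h in seq_len(max_hits)) {
    best <- NULL
    done <- FALSE
    # longest unexplained segment first; once a hit explains >= 90% of a
    # segment's achievable score, the remaining target/strand combinations
    # cannot matter and are skipped
    segments <- segments[order(-vapply(segments, diff, 0L))]
    for (seg in segments) {
      if (done) break
      if (seg[2L] - seg[1L] < 20L) next
      qs <- substr(query, seg[1L] + 1L, seg[2L])
      for (tg in targets) {
        if (done) break
        for (strand in c("+", "-")) {
          tseq <- if (strand == "+") tg$seq else revcomp(tg$seq)
          hit <- local_hit(qs, tseq, scoring, min_score)
          if (is.null(hit)) next
          hit$strand <- strand
          hit$chrom <- tg$chrom
          hit$qstart <- hit$qstart + seg[1L]
          hit$qend <- hit$qend + seg[1L]
          # convert target coords to forward-strand full-genome space
          if (strand == "+") {
            hit$target_start <- tg$offset + hit$tstart
            hit$target_end <- tg$offset + hit$tend
          } else {
            w <- nchar(tg$seq)
            hit$target_start <- tg$offset + w - hit$tend
            hit$target_end <- tg$offset + w - hit$tstart
          }
          hit$segment <- seg
          if (is.null(best) || hit$score > best$score) best <- hit
          if (!is.null(best) &&
              best$score >= 0.9 * scoring$match * (seg[2L] - seg[1L])) {
            done <- TRUE
            break
          }
        }
      }
    }
    if (is.null(best)) break
    hits[[h]] <- best
    # split the segment the hit came from
    segments <- Filter(function(s) !identical(s, best$segment), segments)
    segments <- c(segments, list(c(best$segment[1L], best$qstart),
                                 c(best$qend, best$segment[2L])))
  }
  hitdf <- if (length(hits)) do.call(rbind, lapply(hits, function(h)
    data.frame(target_chrom = h$chrom, target_start = h$target_start,
               target_end = h$target_end, strand = h$strand,
               qstart = h$qstart, qend = h$qend,
               aligned_length = h$aligned_length,
               overhang_left = h$qstart,
               overhang_right = qlen - h$qend,
               identity = h$identity, score = h$score,
               stringsAsFactors = FALSE)))
  else data.frame(target_chrom = character(), target_start = integer(),
                  target_end = integer(), strand = character(),
                  qstart = integer(), qend = integer(),
                  aligned_length = integer(), overhang_left = integer(),
                  overhang_right = integer(), identity = numeric(),
                  score = numeric(), stringsAsFactors = FALSE)
  hitdf <- hitdf[order(-hitdf$score), , drop = FALSE]
  rownames(hitdf) <- NULL
  structure(list(query = list(taxon = genome$taxon_id, chrom = chrom,
                              start = q_start, end = q_end,
                              breakpoint = c(bp_start, bp_end)),
                 hits = hitdf),
            class = "flank_alignment_report")
}

#' @export
print.flank_alignment_report <- function(x, ...) {
  cat(sprintf("<flank_alignment_report> %s:%s [%d,%d) bp interval [%d,%d): %d hit(s)\n",
              x$query$taxon, x$query$chrom, x$query$start, x$query$end,
              x$query$breakpoint[1L], x$query$breakpoint[2L], nrow(x$hits)))
  if (nrow(x$hits)) print(x$hits)
  invisible(x)
}

#' Reciprocal consistency of two flank-alignment reports
#'
#' The two reports must describe the same breakpoint queried from opposite
#' taxa.  The check is true iff each direction's hit endpoints land within
#' `tol` bp of the other direction's query breakpoint.
#'
#' @param report_1to2 Report for the genome-1 query against genome 2.
#' @param report_2to1 Report for the genome-2 query against genome 1.
#' @param tol Tolerance in bp (default 1000).
#' @return Logical.
#' @export
reciprocal_consistency <- function(report_1to2, report_2to1, tol = 1000L) {
  one_way <- function(rep_fwd, rep_rev) {
    if (!nrow(rep_fwd$hits)) return(FALSE)
    bp <- rep_rev$query$breakpoint     # interval [bp1, bp2] on the target
    ends <- c(rep_fwd$hits$target_start, rep_fwd$hits$target_end)
    chroms <- rep(rep_fwd$hits$target_chrom, 2L)
    dist_to_interval <- pmax(0, bp[1L] - ends, ends - bp[2L])
    any(chroms == rep_rev$query$chrom & dist_to_interval <= tol)
  }
  one_way(report_1to2, report_2to1) && one_way(report_2to1, report_1to2)
}

#' Detect an inverted duplication between the two flanks of an inversion
#'
#' Aligns `flank_left` locally against the reverse complement of
#' `flank_right`; an aligned stretch at least `min_dup_len` long with
#' identity at least `min_identity` is reported as a duplication call (the
#' staggered-break footprint on a derived arrangement, or the repeat-pair
#' footprint of ectopic recombination on either arrangement).
#'
#' @param flank_left,flank_right Nucleotide strings extracted around the
#'   two breakpoints of one inversion in one arrangement.
#' @param min_dup_len Minimum duplication length in bp (default 50).
#' @param min_identity Minimum identity fraction (default 0.9).
#' @param scoring Scoring list; see [default_scoring()].
#' @return A `duplication_call` (list with `length`, `identity`,
#'   `orientation = "inverted"`) or `NULL` if none.
#' @export
detect_inverted_duplication <- function(flank_left, flank_right,
                                        min_dup_len = 50L,
                                        min_identity = 0.9,
                                        scoring = default_scoring()) {
  hit <- local_hit(flank_left, revcomp(flank_right), scoring,
                   min_score = min_dup_len * scoring$match * 0.5)
  if (is.null(hit)) return(NULL)
  if (hit$aligned_length < min_dup_len || hit$identity < min_identity)
    return(NULL)
  structure(list(length = hit$aligned_length, identity = hit$identity,
                 orientation = "inverted", score = hit$score),
            class = "duplication_call")
}

#' Classify the origin mechanism of an inversion
#'
#' Decision table over the presence of flanking inverted duplications in
#' the derived and the ancestral arrangement:
#' derived only -> `staggered`; both -> `ectopic_recombination`;
#' neither -> `straight_or_nearly_straight` (clean cuts, or staggered cuts
#' whose duplications are too short to leave long-lasting traces);
#' ancestral only -> `undetermined` (flagged, inconsistent with either
#' mechanism under known polarity).
#'
#' @param dup_derived,dup_ancestral [detect_inverted_duplication()] results
#'   (or `NULL`) for the derived and ancestral arrangements.
#' @return A `mechanism_call`: list with `mechanism` and `evidence`.
#' @export
classify_mechanism <- function(dup_derived, dup_ancestral) {
  mech <- if (!is.null(dup_derived) && is.null(dup_ancestral)) "staggered"
  else if (!is.null(dup_derived) && !is.null(dup_ancestral))
    "ectopic_recombination"
  else if (is.null(dup_derived) && is.null(dup_ancestral))
    "straight_or_nearly_straight"
  else "undetermined"
  structure(list(mechanism = mech,
                 evidence = list(derived = dup_derived,
                                 ancestral = dup_ancestral)),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("<mechanism_call>", x$mechanism, "\n")
  for (side in c("derived", "ancestral")) {
    d <- x$evidence[[side]]
    cat(sprintf("  %s: %s\n", side,
                if (is.null(d)) "no duplication"
                else sprintf("inverted duplication %d bp (%.1f%% id)",
                             d$length, 100 * d$identity)))
  }
  invisible(x)
}

#' Test whether a breakpoint interval disrupts a gene
#'
#' Genes whose body overlaps the interval (half-open intersection) are
#' listed; zero-length intervals are tested as a point, disrupting only
#' markers they cut strictly inside.
#'
#' @param interval One-row data.frame (or list) with `start` and `end`;
#'   a row of [breakpoint_intervals()].
#' @param markers Marker annotation data.frame (`id`, `start`, `end`) on
#'   the same chromosome and coordinate system.
#' @return List with `disrupted` (logical) and `genes` (character ids).
#' @export
check_gene_disruption <- function(interval, markers) {
  s <- interval$start; e <- interval$end
  hit <- if (s == e) markers$start < s & markers$end > s
  else markers$start < e & markers$end > s
  genes <- markers$id[hit]
  list(disrupted = length(genes) > 0L, genes = genes)
}

#' Fraction of a breakpoint flank covered by repeat annotation
#'
#' Used for the mutational-bias screen (whether breakpoints of
#' sex-chromosome inversions sit in more repeat-dense sequence than
#' autosomal ones).
#'
#' @param chrom Chromosome name.
#' @param start,end Flank interval (0-based half-open).
#' @param repeats Repeat annotation BED data.frame
#'   (`chrom`, `start`, `end`).
#' @return Fraction of the interval covered in `[0, 1]`.
#' @export
flank_repeat_content <- function(chrom, start, end, repeats) {
  if (end <= start) return(0)
  r <- repeats[repeats$chrom == chrom & repeats$end > start &
                 repeats$start < end, , drop = FALSE]
  if (!nrow(r)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(pmax(r$start, start) + 1L,
                                         pmin(r$end, end)))
  sum(BiocGenerics::width(ir)) / (end - start)
}
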
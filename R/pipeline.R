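# Pipeline: the template rearrangement scenario, the end-to-end two-taxon
# inversion analysis, stage runners and the collated report.

#' Snap a position to the nearest sufficiently wide intergenic gap
#'
#' Returns the midpoint of the marker-free gap nearest `pos` that is at
#' least `2 * clearance` wide, so inversion breakpoints (and stagger
#' fragments of up to `clearance` bp) never cut a marker.
#'
#' @param genome A `marker_genome`.
#' @param chrom Chromosome name.
#' @param pos Nominal position (bp).
#' @param clearance Required marker-free room either side of the returned
#'   point (bp).
#' @return Integer position.
#' @export
snap_intergenic <- function(genome, chrom, pos, clearance = 0L) {
  ch <- get_chrom(genome, chrom)
  m <- ch$markers
  bounds <- c(0L, as.vector(rbind(m$start, m$end)), ch$length)
  gs <- bounds[seq(1L, length(bounds), by = 2L)]
  ge <- bounds[seq(2L, length(bounds), by = 2L)]
  wide <- (ge - gs) >= 2L * clearance + 2L
  if (!any(wide)) stop("no intergenic gap of width >= ", 2L * clearance,
                       " on ", chrom)
  mid <- (gs + ge) / 2
  i <- which(wide)[which.min(abs(mid[wide] - pos))]
  as.integer(round(mid[i]))
}

# One nominal event: positions as fractions of the chromosome length,
# snapped to intergenic gaps in the current genome frame.
snap_event <- function(genome, spec) {
  ch <- get_chrom(genome, spec$chrom)
  clear <- max(spec$offset_left, spec$offset_right, 0L) + 50L
  l <- snap_intergenic(genome, spec$chrom, round(spec$f_left * ch$length),
                       clearance = clear)
  r <- snap_intergenic(genome, spec$chrom, round(spec$f_right * ch$length),
                       clearance = clear)
  inversion_event(spec$event_id, spec$chrom, min(l, r), max(l, r),
                  mechanism = spec$mechanism,
                  offset_left = spec$offset_left,
                  offset_right = spec$offset_right,
                  branch = spec$branch, state = spec$state)
}

#' The template rearrangement scenario of the species subgroup
#'
#' Twelve inversions emulating the subgroup's reconstructed history:
#' six on the sex chromosome A (four overlapping proximal ones plus two
#' distal singles), three fixed autosomal inversions (one of them, on O,
#' on the internal branch above the subobscura+madeirensis ancestor),
#' two polymorphic inversions on U, and one fixed on the guanche branch.
#' The four staggered events carry duplication offsets of 689, 1007, 513
#' and 538 bp (U, U, E and O respectively); the rest are straight breaks.
#' Breakpoints are snapped to intergenic gaps in the genome frame current
#' at the time each event applies.
#'
#' @param ancestral A `marker_genome` (see [make_ancestral_genome()]).
#' @param tree Species tree from [subgroup_tree()].
#' @return List of [inversion_event()]s with realized coordinates.
#' @export
template_events <- function(ancestral, tree) {
  specs <- list(
    list(event_id = "A_h1", chrom = "A", f_left = 0.05, f_right = 0.26,
         mechanism = "straight", branch = "subobscura"),
    list(event_id = "A_h2", chrom = "A", f_left = 0.13, f_right = 0.35,
         mechanism = "straight", branch = "subobscura"),
    list(event_id = "A_h3", chrom = "A", f_left = 0.09, f_right = 0.44,
         mechanism = "straight", branch = "subobscura"),
    list(event_id = "A_h4", chrom = "A", f_left = 0.03, f_right = 0.39,
         mechanism = "straight", branch = "subobscura"),
    list(event_id = "A_5", chrom = "A", f_left = 0.57, f_right = 0.70,
         mechanism = "straight", branch = "subobscura"),
    list(event_id = "A_6", chrom = "A", f_left = 0.88, f_right = 0.985,
         mechanism = "straight", branch = "subobscura"),
    list(event_id = "J_ST", chrom = "J", f_left = 0.25, f_right = 0.60,
         mechanism = "straight", branch = "subobscura"),
    list(event_id = "E_ST", chrom = "E", f_left = 0.24, f_right = 0.58,
         mechanism = "staggered", offset_left = 513L, offset_right = 513L,
         branch = "subobscura"),
    list(event_id = "O_ms", chrom = "O", f_left = 0.26, f_right = 0.59,
         mechanism = "staggered", offset_left = 538L, offset_right = 538L,
         branch = "ms"),
    list(event_id = "U_1", chrom = "U", f_left = 0.155, f_right = 0.35,
         mechanism = "staggered", offset_left = 689L, offset_right = 689L,
         branch = "subobscura", state = "polymorphic"),
    list(event_id = "U_2", chrom = "U", f_left = 0.38, f_right = 0.58,
         mechanism = "staggered", offset_left = 1007L, offset_right = 1007L,
         branch = "subobscura", state = "polymorphic"),
    list(event_id = "E_g1", chrom = "E", f_left = 0.68, f_right = 0.91,
         mechanism = "straight", branch = "guanche")
  )
  specs <- lapply(specs, function(s) {
    s$offset_left <- s$offset_left %||% 0L
    s$offset_right <- s$offset_right %||% 0L
    s$state <- s$state %||% "fixed"
    s
  })
  # snap coordinates in the frame current on each branch, walking the tree
  # root-to-tip; polymorphic events are listed after fixed ones per branch
  branch_order <- c("ms", "subobscura", "madeirensis", "guanche")
  states <- list(root = ancestral)
  parent_of <- c(ms = "root", subobscura = "ms", madeirensis = "ms",
                 guanche = "root")
  events <- list()
  for (br in branch_order) {
    g <- states[[parent_of[[br]]]]
    on_branch <- Filter(function(s) identical(s$branch, br), specs)
    ord <- order(vapply(on_branch, function(s) s$state == "polymorphic", TRUE))
    for (s in on_branch[ord]) {
      ev <- snap_event(g, s)
      g <- apply_inversion(g, ev)
      events[[length(events) + 1L]] <- ev
    }
    states[[br]] <- g
  }
  # restore the original listing order
  ids <- vapply(specs, `[[`, "", "event_id")
  events[order(match(vapply(events, `[[`, "", "event_id"), ids))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the template subgroup data set
#'
#' Ancestral genome, template events, tip genomes (including the
#' unrearranged outgroup) and repeat landscape, all from one seed.
#'
#' @param config A [default_config()].
#' @return List with `ancestral`, `tree`, `events`, `genomes`,
#'   `haplotypes`, `truth`, `repeats`.
#' @export
simulate_template <- function(config = default_config()) {
  sc <- config$simulate
  anc <- make_ancestral_genome(length(sc$chrom_names), sc$chrom_lengths,
                               sc$markers_per_chrom, seed = config$seed,
                               chrom_names = sc$chrom_names,
                               marker_length = sc$marker_length,
                               gc = sc$gc)
  tree <- subgroup_tree(config$tree$age_subgroup, config$tree$age_ms_split,
                        outgroup = TRUE)
  events <- template_events(anc, tree)
  evo <- evolve_subgroup(anc, tree, events, seed = config$seed)
  repeats <- place_repeats(evo$genomes$subobscura, repeat_model(),
                           seed = config$seed)
  list(ancestral = anc, tree = tree, events = events,
       genomes = evo$genomes, haplotypes = evo$haplotypes,
       truth = evo$truth, repeats = repeats)
}

# g2-side gap between two blocks (by block ids), from the g2-sorted order;
# NULL when the two blocks are not adjacent on genome 2.
gap2_between <- function(blocks_c, id_a, id_b) {
  o2 <- blocks_c[order(blocks_c$start2), , drop = FALSE]
  ia <- match(id_a, o2$block_id); ib <- match(id_b, o2$block_id)
  if (is.na(ia) || is.na(ib) || abs(ia - ib) != 1L) return(NULL)
  i <- min(ia, ib)
  c(start = o2$end2[i], end = o2$start2[i + 1L])
}

#' End-to-end inversion analysis between two taxa
#'
#' Runs the full detection chain for one genome pair: anchors, signed
#' synteny blocks, per-chromosome signed permutations, breakpoint
#' intervals, reciprocal flank mapping, flanking inverted-duplication
#' detection, mechanism classification, polarity against an outgroup and
#' gene-disruption checks.  Isolated inverted blocks become individual
#' inversion calls; scrambled multi-block segments (overlapping
#' inversions) are reported as regions with an optimal reversal scenario.
#'
#' @param ref,alt `marker_genome`s with sequence (reference = genome 1).
#' @param outgroup Optional outgroup `marker_genome` for polarity.
#' @param min_anchors,max_gap Synteny parameters ([chain_blocks()]);
#'   `max_gap = NA` uses 1/20 of the longest chromosome.
#' @param flank_width,min_dup_len,min_identity,tol,min_score Breakpoint
#'   parameters (see [map_flank()], [detect_inverted_duplication()],
#'   [reciprocal_consistency()]).
#' @return An `inversion_analysis`: list with `blocks`, `stats`, `perms`,
#'   `calls` (data.frame, one row per isolated inversion), `regions`
#'   (complex segments with reversal scenarios) and `params`.
#' @export
analyze_pair <- function(ref, alt, outgroup = NULL,
                         min_anchors = 3L, max_gap = NA,
                         flank_width = 1500L, min_dup_len = 50L,
                         min_identity = 0.9, tol = 1000L, min_score = 30) {
  if (is.na(max_gap))
    max_gap <- max(vapply(ref$chromosomes, `[[`, 0, "length")) / 20
  anchors <- find_anchors(ref, alt)
  blocks <- chain_blocks(anchors, min_anchors = min_anchors,
                         max_gap = max_gap)
  perms <- list(); calls <- list(); regions <- list()
  for (chr in unique(blocks$chrom1)) {
    bc <- blocks[blocks$chrom1 == chr, , drop = FALSE]
    bc <- bc[order(bc$start1), , drop = FALSE]
    perm <- to_signed_permutation(bc, chr)
    perms[[chr]] <- perm
    e <- perm$elements
    n <- length(e)
    if (!n) next
    # decompose into in-place blocks, isolated inverted blocks (simple
    # calls) and minimal scrambled segments whose value set equals their
    # position set (overlapping-inversion regions)
    simple <- integer(0)
    i0 <- 1L
    while (i0 <= n) {
      if (e[i0] == i0) { i0 <- i0 + 1L; next }
      if (e[i0] == -i0) { simple <- c(simple, i0); i0 <- i0 + 1L; next }
      s <- i0; hi <- abs(e[i0])
      while (i0 < hi) { i0 <- i0 + 1L; hi <- max(hi, abs(e[i0])) }
      sub <- e[s:hi]
      subperm <- signed_permutation(sign(sub) * (abs(sub) - s + 1L),
                                    chrom = chr)
      sc <- sort_by_reversals(subperm)
      regions[[length(regions) + 1L]] <- list(
        chrom = chr, block_ids = bc$block_id[s:hi],
        start1 = bc$start1[s], end1 = bc$end1[hi],
        permutation = subperm, scenario = sc, distance = sc$distance)
      i0 <- hi + 1L
    }
    for (i in simple) {
      calls[[length(calls) + 1L]] <- analyze_simple_inversion(
        ref, alt, outgroup, bc, i, chr, flank_width, min_dup_len,
        min_identity, tol, min_score)
    }
  }
  calls_df <- if (length(calls)) do.call(rbind, calls)
  else data.frame()
  structure(list(anchors = anchors, blocks = blocks,
                 stats = block_stats(blocks), perms = perms,
                 calls = calls_df, regions = regions,
                 params = list(min_anchors = min_anchors, max_gap = max_gap,
                               flank_width = flank_width,
                               min_dup_len = min_dup_len,
                               min_identity = min_identity, tol = tol,
                               min_score = min_score),
                 taxa = c(ref = ref$taxon_id, alt = alt$taxon_id)),
            class = "inversion_analysis")
}

# One isolated inverted block: breakpoints on both genomes, reciprocity,
# duplications, mechanism, polarity, gene disruption.
analyze_simple_inversion <- function(ref, alt, outgroup, bc, i, chr,
                                     flank_width, min_dup_len,
                                     min_identity, tol, min_score) {
  n <- nrow(bc)
  chr2 <- bc$chrom2[1L]
  ref_ch <- get_chrom(ref, chr); alt_ch <- get_chrom(alt, chr2)
  # at a chromosome edge (no further block) the junction is known only to
  # lie beyond the anchor hull, so the interval extends to the sequence end
  gapL <- if (i > 1L) c(start = bc$end1[i - 1L], end = bc$start1[i])
  else c(start = 0L, end = bc$start1[i])
  gapR <- if (i < n) c(start = bc$end1[i], end = bc$start1[i + 1L])
  else c(start = bc$end1[i], end = ref_ch$length)
  agapL <- if (i > 1L) gap2_between(bc, bc$block_id[i - 1L], bc$block_id[i])
  else c(start = 0L, end = bc$start2[i])
  agapR <- if (i < n) gap2_between(bc, bc$block_id[i], bc$block_id[i + 1L])
  else c(start = bc$end2[i], end = alt_ch$length)
  # flanking blocks not adjacent on genome 2 (complex neighbourhood):
  # fall back to the block's own span boundary
  if (is.null(agapL)) agapL <- c(start = bc$start2[i], end = bc$start2[i])
  if (is.null(agapR)) agapR <- c(start = bc$end2[i], end = bc$end2[i])
  # reciprocal flank mapping at both breakpoints; the query's two hits
  # land near the two breakpoint gaps of the target, so small windows
  # around those keep the alignments cheap
  margin <- flank_width + 1000L
  win_of <- function(chrom, gap) list(chrom = chrom,
                                      start = gap[["start"]] - margin,
                                      end = gap[["end"]] + margin)
  alt_wins <- list(win_of(chr2, agapL), win_of(chr2, agapR))
  ref_wins <- list(win_of(chr, gapL), win_of(chr, gapR))
  fmap <- function(g, c0, gap, tgt, wins)
    map_flank(g, c0, gap[["start"]], gap[["end"]], tgt,
              flank_width = flank_width, target_window = wins,
              min_score = min_score)
  rep12 <- fmap(ref, chr, gapL, alt, alt_wins)
  rep21 <- fmap(alt, chr2, agapL, ref, ref_wins)
  rep12d <- fmap(ref, chr, gapR, alt, alt_wins)
  rep21d <- fmap(alt, chr2, agapR, ref, ref_wins)
  recip <- reciprocal_consistency(rep12, rep21, tol = tol) &&
    reciprocal_consistency(rep12d, rep21d, tol = tol)
  # refine the reference breakpoint intervals with the precise homology
  # ends of the reverse-direction hits: for every hit lying on one side of
  # the query's breakpoint, the junction-facing target endpoint marks
  # where homology breaks
  refine <- function(gap, rev_reps, fwd_reps) {
    # reverse direction: junction-facing target endpoints of hits lying on
    # one side of the query's breakpoint (target space = reference space)
    ends_rev <- unlist(lapply(rev_reps, function(r) {
      if (!nrow(r$hits)) return(numeric(0))
      # side classification is meaningless for wide (edge) breakpoint
      # intervals; the forward query's split points cover those
      if (r$query$breakpoint[2L] - r$query$breakpoint[1L] > 2L * tol)
        return(numeric(0))
      qlo <- r$query$breakpoint[1L] - r$query$start
      qhi <- r$query$breakpoint[2L] - r$query$start
      e <- numeric(0)
      for (hi in seq_len(nrow(r$hits))) {
        h <- r$hits[hi, ]
        if (h$qend <= qhi + 50L) {          # hit left of the junction
          e <- c(e, if (h$strand == "+") h$target_end else h$target_start)
        } else if (h$qstart >= qlo - 50L) { # hit right of the junction
          e <- c(e, if (h$strand == "+") h$target_start else h$target_end)
        }
      }
      e
    }))
    # forward direction: interior alignment ends of the reference query
    # mark where homology breaks, directly in reference coordinates
    ends_fwd <- unlist(lapply(fwd_reps, function(r) {
      if (!nrow(r$hits)) return(numeric(0))
      qlen <- r$query$end - r$query$start
      e <- c(r$hits$qstart[r$hits$qstart > 25L],
             r$hits$qend[r$hits$qend < qlen - 25L])
      r$query$start + e
    }))
    ends <- c(ends_rev, ends_fwd)
    ends <- ends[ends >= gap[["start"]] - tol & ends <= gap[["end"]] + tol]
    if (!length(ends)) return(gap)
    out <- c(start = max(gap[["start"]], min(ends)),
             end = min(gap[["end"]], max(ends)))
    if (out[["start"]] > out[["end"]]) gap else out
  }
  rgapL <- refine(gapL, list(rep21, rep21d), list(rep12, rep12d))
  rgapR <- refine(gapR, list(rep21, rep21d), list(rep12, rep12d))
  # flanking inverted duplications in each taxon's arrangement
  flank_pair <- function(ch, a, b) {
    list(left = subseq_chr(ch, a[["start"]] - flank_width,
                           a[["end"]] + flank_width),
         right = subseq_chr(ch, b[["start"]] - flank_width,
                            b[["end"]] + flank_width))
  }
  fr <- flank_pair(ref_ch, gapL, gapR)
  fa <- flank_pair(alt_ch, agapL, agapR)
  dup_ref <- detect_inverted_duplication(fr$left, fr$right,
                                         min_dup_len, min_identity)
  dup_alt <- detect_inverted_duplication(fa$left, fa$right,
                                         min_dup_len, min_identity)
  # polarity: each taxon's window around its own proximal breakpoint is
  # tested for contiguity in the outgroup's gene arrangement
  pol <- NULL
  if (!is.null(outgroup)) {
    out_ch <- get_chrom(outgroup, chr)
    pol <- infer_polarity(window_around(ref_ch, gapL),
                          window_around(alt_ch, agapL),
                          out_ch$markers$id,
                          taxon_a = ref$taxon_id, taxon_b = alt$taxon_id,
                          inversion_id = sprintf("%s_inv%d", chr, i))
  }
  derived <- if (!is.null(pol) && pol$status == "resolved")
    pol$derived_taxon else NA_character_
  mech <- if (!is.na(derived)) {
    if (derived == ref$taxon_id) classify_mechanism(dup_ref, dup_alt)
    else classify_mechanism(dup_alt, dup_ref)
  } else classify_mechanism(dup_ref, dup_alt)  # unpolarized: ref as derived
  disL <- check_gene_disruption(list(start = rgapL[["start"]],
                                     end = rgapL[["end"]]), ref_ch$markers)
  disR <- check_gene_disruption(list(start = rgapR[["start"]],
                                     end = rgapR[["end"]]), ref_ch$markers)
  dis <- list(disrupted = disL$disrupted || disR$disrupted,
              genes = union(disL$genes, disR$genes))
  dup_len <- function(d) if (is.null(d)) NA_integer_ else d$length
  data.frame(
    inversion_id = sprintf("%s_inv%d", chr, i), chrom = chr,
    block_id = bc$block_id[i],
    ref_prox_start = rgapL[["start"]], ref_prox_end = rgapL[["end"]],
    ref_dist_start = rgapR[["start"]], ref_dist_end = rgapR[["end"]],
    alt_chrom = chr2,
    alt_prox_start = agapL[["start"]], alt_prox_end = agapL[["end"]],
    alt_dist_start = agapR[["start"]], alt_dist_end = agapR[["end"]],
    reciprocal_ok = recip,
    dup_len_ref = dup_len(dup_ref), dup_len_alt = dup_len(dup_alt),
    mechanism = mech$mechanism,
    polarity = if (is.null(pol)) NA_character_ else pol$status,
    derived_taxon = derived,
    gene_disrupted = dis$disrupted,
    disrupted_genes = paste(dis$genes, collapse = ","),
    stringsAsFactors = FALSE)
}

# the k markers nearest each side of a breakpoint gap, in chromosomal order
window_around <- function(ch, gap, k = 3L) {
  m <- ch$markers
  left <- m$id[m$end <= gap[["start"]]]
  right <- m$id[m$start >= gap[["end"]]]
  c(tail(left, k), head(right, k))
}

order_in <- function(ch, ids) {
  m <- ch$markers[ch$markers$id %in% ids, , drop = FALSE]
  m$id[order(m$start)]
}

#' @export
print.inversion_analysis <- function(x, ...) {
  cat(sprintf("<inversion_analysis> %s vs %s: %d blocks (%d inverted), mean %.3f Mb\n",
              x$taxa[["ref"]], x$taxa[["alt"]], x$stats$n_blocks,
              x$stats$n_inverted, x$stats$mean_size_mb))
  cat(sprintf("  %d isolated inversion call(s); %d complex region(s)\n",
              if (is.null(x$calls) || !nrow(x$calls)) 0L else nrow(x$calls),
              length(x$regions)))
  for (r in x$regions)
    cat(sprintf("  region %s [%d..%d]: %d blocks, reversal distance %d\n",
                r$chrom, r$start1, r$end1, length(r$block_ids), r$distance))
  invisible(x)
}
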
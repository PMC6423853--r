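# Genome-rearrangement simulator: ancestral genome construction, single
# inversion events (straight / staggered / ectopic), and whole-subgroup
# evolution along a species tree with a ground-truth table.

#' Generate an ancestral marker genome
#'
#' Markers are placed uniformly at random without overlap, with random
#' strands; intergenic sequence is random DNA at the stated GC content.
#' The default layout emulates a Drosophila-like karyotype of five
#' acrocentric chromosomes plus a small dot, scaled down for tractability.
#' Chromosomes are oriented centromere (position 0) to telomere.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_lengths Integer vector of chromosome lengths (bp), recycled
#'   to `n_chrom`.
#' @param n_markers Markers per chromosome (scalar or vector).
#' @param seed Integer seed fixing all randomness.
#' @param chrom_names Optional chromosome names (default `chr1`, ...).
#' @param marker_length Length of each marker in bp (default 500).
#' @param gc GC fraction of the generated sequence (default 0.45).
#' @param with_sequence Generate nucleotide sequence? (default TRUE; marker
#'   coordinates alone suffice for the synteny stage).
#' @param taxon_id Taxon label (default `"ancestor"`).
#' @return A [marker_genome()].
#' @examples
#' g <- make_ancestral_genome(2, c(50000, 30000), 10, seed = 1)
#' summary(g)
#' @export
make_ancestral_genome <- function(n_chrom, chrom_lengths, n_markers, seed,
                                  chrom_names = NULL, marker_length = 500L,
                                  gc = 0.45, with_sequence = TRUE,
                                  taxon_id = "ancestor") {
  chrom_lengths <- as.integer(rep_len(chrom_lengths, n_chrom))
  n_markers <- as.integer(rep_len(n_markers, n_chrom))
  if (any(chrom_lengths <= 0L)) stop("chromosome lengths must be > 0")
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_len(n_chrom))
  chroms <- vector("list", n_chrom)
  for (i in seq_len(n_chrom)) {
    L <- chrom_lengths[i]; k <- n_markers[i]
    if (k * marker_length > L)
      stop("cannot fit ", k, " markers of ", marker_length,
           " bp on a ", L, " bp chromosome '", chrom_names[i], "'")
    set.seed(split_seed(seed, i))
    if (k > 0L) {
      # non-overlap by sampling in the 'compressed' coordinate space
      slack <- L - k * marker_length
      starts <- sort(sample.int(slack + 1L, k, replace = FALSE)) - 1L +
        (seq_len(k) - 1L) * marker_length
      m <- data.frame(
        id = sprintf("%s_g%04d", chrom_names[i], seq_len(k)),
        start = as.integer(starts),
        end = as.integer(starts + marker_length),
        strand = sample(c("+", "-"), k, replace = TRUE),
        stringsAsFactors = FALSE)
    } else {
      m <- data.frame(id = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
    }
    chroms[[i]] <- list(name = chrom_names[i], length = L, markers = m,
                        sequence = if (with_sequence) random_dna(L, gc))
  }
  names(chroms) <- chrom_names
  marker_genome(taxon_id, chroms)
}

#' Define an inversion event
#'
#' Breakpoints are on the pre-event coordinate system, 0-based half-open:
#' the segment `[left_bp, right_bp)` is inverted.  Mechanisms:
#' * `straight` — two clean cuts; length unchanged, no duplication.
#' * `staggered` — offset cuts; the two stagger fragments (`offset_left`,
#'   `offset_right` bp) end up duplicated in inverted orientation on the
#'   flanks of the derived arrangement and the genome grows by their sum.
#' * `ectopic` — recombination between a pre-placed inverted repeat pair
#'   (see [place_inverted_repeat_pair()]); repeat copies flank the inverted
#'   segment in both the ancestral and the derived arrangement.
#'
#' @param event_id Label.
#' @param chrom Chromosome name.
#' @param left_bp,right_bp Breakpoints, `left_bp < right_bp`.
#' @param mechanism `"straight"`, `"staggered"` or `"ectopic"`.
#' @param offset_left,offset_right Stagger offsets in bp (staggered only).
#' @param repeat_id Repeat-pair label (ectopic only).
#' @param branch Tree-branch label the event occurs on.
#' @param state `"fixed"` or `"polymorphic"` at the carrying tip.
#' @return An `inversion_event`.
#' @export
inversion_event <- function(event_id, chrom, left_bp, right_bp,
                            mechanism = c("straight", "staggered", "ectopic"),
                            offset_left = 0L, offset_right = 0L,
                            repeat_id = NULL, branch = NA_character_,
                            state = c("fixed", "polymorphic")) {
  mechanism <- match.arg(mechanism)
  state <- match.arg(state)
  if (left_bp >= right_bp) stop("left_bp must be < right_bp")
  if (offset_left < 0L || offset_right < 0L) stop("offsets must be >= 0")
  if (mechanism == "staggered" && offset_left == 0L && offset_right == 0L)
    mechanism <- "straight"  # zero offsets are equivalent to straight
  if (mechanism == "ectopic" && is.null(repeat_id))
    stop("ectopic events require a repeat_id")
  structure(list(event_id = event_id, chrom = chrom,
                 left_bp = as.integer(left_bp), right_bp = as.integer(right_bp),
                 mechanism = mechanism,
                 offset_left = as.integer(offset_left),
                 offset_right = as.integer(offset_right),
                 repeat_id = repeat_id, branch = branch, state = state),
            class = "inversion_event")
}

#' Place an inverted repeat pair (substrate for ectopic recombination)
#'
#' Writes the same random repeat unit in forward orientation at `pos_left`
#' and reverse-complemented at `pos_right` on one chromosome, and records
#' the pair so that an `ectopic` [inversion_event()] can reference it.
#'
#' @param genome A `marker_genome` with sequence.
#' @param chrom Chromosome name.
#' @param pos_left,pos_right Start positions (0-based) of the two copies.
#' @param length Repeat unit length in bp.
#' @param repeat_id Label for the pair.
#' @param seed Integer seed for the repeat unit sequence.
#' @return The modified genome.
#' @export
place_inverted_repeat_pair <- function(genome, chrom, pos_left, pos_right,
                                       length, repeat_id, seed) {
  ch <- get_chrom(genome, chrom)
  if (is.null(ch$sequence)) stop("genome has no sequence")
  if (pos_left + length > pos_right || pos_right + length > ch$length)
    stop("repeat pair does not fit")
  set.seed(seed)
  unit <- random_dna(length, gc = 0.45)
  s <- ch$sequence
  substr(s, pos_left + 1L, pos_left + length) <- unit
  substr(s, pos_right + 1L, pos_right + length) <- revcomp(unit)
  ch$sequence <- s
  rp <- data.frame(repeat_id = repeat_id, start_left = as.integer(pos_left),
                   start_right = as.integer(pos_right),
                   length = as.integer(length), stringsAsFactors = FALSE)
  ch$repeat_pairs <- rbind(ch$repeat_pairs, rp)
  set_chrom(genome, chrom, ch)
}

#' Apply one inversion event to a genome
#'
#' The inverted segment is reverse-complemented; contained markers are
#' reversed in order with strands flipped.  Staggered events additionally
#' duplicate the two stagger fragments in inverted orientation on the
#' derived flanks (see Details); ectopic events invert between the two
#' copies of the named repeat pair, leaving repeat copies on both flanks.
#'
#' @details
#' Staggered cut geometry (a documented convention — with fragments
#' `A = [left_bp, left_bp+offset_left)`, `M` the interior and
#' `B = [right_bp-offset_right, right_bp)`, the derived sequence is
#' `prefix + A + rc(B) + rc(M) + rc(A) + B + suffix`: each flank of the
#' derived inversion carries an inverted duplicate of the opposite flank's
#' stagger fragment, and the genome grows by `offset_left + offset_right`.
#' Breakpoints may not fall inside a marker, and stagger fragments must be
#' marker-free.
#'
#' @param genome A `marker_genome`.
#' @param event An [inversion_event()].
#' @return The derived genome, with attribute `"realized"` giving the
#'   derived-coordinate span `c(left, right)` of the rearranged region.
#' @export
apply_inversion <- function(genome, event) {
  ch <- get_chrom(genome, event$chrom)
  l <- event$left_bp; r <- event$right_bp
  a <- event$offset_left; b <- event$offset_right
  if (event$mechanism == "ectopic") {
    rp <- ch$repeat_pairs
    rp <- rp[!is.na(match(rp$repeat_id, event$repeat_id)), , drop = FALSE]
    if (is.null(ch$repeat_pairs) || !nrow(rp))
      stop("ectopic event '", event$event_id, "': no repeat pair '",
           event$repeat_id, "' on chromosome ", event$chrom)
    # recombination between the inverted copies: invert from the start of
    # the left copy to the end of the right copy; the segment then still
    # begins with the forward copy and ends with the inverted one, so both
    # arrangements carry the pair on their flanks
    l <- rp$start_left[1L]; r <- rp$start_right[1L] + rp$length[1L]
    a <- b <- 0L
  }
  if (l < 0L || r > ch$length) stop("breakpoints outside chromosome")
  if (event$mechanism == "staggered" && a + b > r - l)
    stop("stagger offsets exceed segment length")
  m <- ch$markers
  cuts <- c(l, l + a, r - b, r)
  if (nrow(m)) {
    for (cc in unique(cuts))
      if (any(m$start < cc & m$end > cc))
        stop("breakpoint at ", cc, " falls inside a marker (chromosome ",
             ch$name, "); use simulate_gene_disruption() if intended")
    if (a > 0L && any(m$start < l + a & m$end > l))
      stop("left stagger fragment overlaps a marker")
    if (b > 0L && any(m$start < r & m$end > r - b))
      stop("right stagger fragment overlaps a marker")
  }
  genome <- apply_inversion_raw(genome, event$chrom, l, r, a, b)
  attr(genome, "realized") <- c(left = l, right = r + a + b)
  genome
}

# The coordinate/sequence arithmetic, shared with the gene-disruption mode.
apply_inversion_raw <- function(genome, chrom, l, r, a = 0L, b = 0L) {
  ch <- get_chrom(genome, chrom)
  m <- ch$markers
  grow <- a + b
  # sequence
  if (!is.null(ch$sequence)) {
    A <- subseq_chr(ch, l, l + a)
    M <- subseq_chr(ch, l + a, r - b)
    B <- subseq_chr(ch, r - b, r)
    ch$sequence <- paste0(subseq_chr(ch, 0L, l),
                          A, revcomp(B), revcomp(M), revcomp(A), B,
                          subseq_chr(ch, r, ch$length))
  }
  # markers: interior of [l+a, r-b) reflects; downstream shifts by grow
  if (nrow(m)) {
    inside <- m$start >= l + a & m$end <= r - b
    after <- m$start >= r
    ns <- m$start; ne <- m$end
    ns[inside] <- l + a + grow + ((r - b) - m$end[inside])
    ne[inside] <- l + a + grow + ((r - b) - m$start[inside])
    ns[after] <- m$start[after] + grow
    ne[after] <- m$end[after] + grow
    m$strand[inside] <- ifelse(m$strand[inside] == "+", "-", "+")
    m$start <- as.integer(ns); m$end <- as.integer(ne)
    m <- m[order(m$start), , drop = FALSE]
    rownames(m) <- NULL
  }
  ch$markers <- m
  ch$length <- ch$length + grow
  set_chrom(genome, chrom, ch)
}

#' Apply an inversion whose breakpoint disrupts a gene
#'
#' Variant of [apply_inversion()] that permits breakpoints inside markers
#' (straight breaks only): the cut marker is split at the breakpoint into
#' `<id>.5p` and `<id>.3p` halves so downstream gene-disruption calls can
#' be exercised against a known truth.
#'
#' @inheritParams apply_inversion
#' @return The derived genome.
#' @export
simulate_gene_disruption <- function(genome, event) {
  stopifnot(event$mechanism == "straight")
  ch <- get_chrom(genome, event$chrom)
  m <- ch$markers
  for (cc in c(event$left_bp, event$right_bp)) {
    hit <- which(m$start < cc & m$end > cc)
    for (i in hit) {
      top <- data.frame(id = paste0(m$id[i], ".5p"), start = m$start[i],
                        end = cc, strand = m$strand[i])
      bot <- data.frame(id = paste0(m$id[i], ".3p"), start = cc,
                        end = m$end[i], strand = m$strand[i])
      m <- rbind(m[-i, , drop = FALSE], top, bot)
      m <- m[order(m$start), , drop = FALSE]
    }
  }
  rownames(m) <- NULL
  ch$markers <- m
  genome <- set_chrom(genome, event$chrom, ch)
  apply_inversion_raw(genome, event$chrom, event$left_bp, event$right_bp)
}

# Map an ancestral-frame position through an inversion event applied at
# derived-frame cut l..r with stagger growth: used to keep truth-table
# coordinates of earlier events current as later events are applied.
shift_position <- function(pos, l, r, a, b) {
  grow <- a + b
  ifelse(pos <= l, pos,
         ifelse(pos >= r, pos + grow,
                # interior point: reflect within the inverted segment
                l + a + grow + ((r - b) - pmin(pmax(pos, l + a), r - b))))
}

#' Evolve a species subgroup along a tree
#'
#' Applies inversion events branch by branch from the root to each tip and
#' returns the tip genomes together with a ground-truth table of realized
#' breakpoint coordinates.  Polymorphic events on a terminal branch are
#' realized as two haplotype genomes for that tip (one with, one without
#' the polymorphic inversions); the returned `$genomes` entry for such a
#' tip is the haplotype carrying all events.
#'
#' @param ancestral A `marker_genome`.
#' @param tree An [ape::read.tree()] phylogeny whose tip labels name the
#'   taxa; internal branches are referenced by the node label of their
#'   child node (e.g. `"ms"` for the branch above the
#'   subobscura+madeirensis ancestor).  Branch lengths are in Myr.
#' @param events List of [inversion_event()]s; each `branch` must name a
#'   tip or internal node label.  Events on one branch apply in list order.
#' @param seed Integer seed (reserved for event realizations that draw
#'   randomness; coordinates here are deterministic).
#' @return List with `genomes` (named list of `marker_genome`),
#'   `haplotypes` (per polymorphic tip, the event-free haplotype), and
#'   `truth` (a `truth_table`: `$events`, `$realized`, `$duplications`).
#' @export
evolve_subgroup <- function(ancestral, tree, events, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  labels <- c(tree$tip.label, tree$node.label)
  for (ev in events)
    if (!ev$branch %in% labels)
      stop("event '", ev$event_id, "': branch '", ev$branch,
           "' not in the tree")
  tips <- tree$tip.label
  genomes <- list(); haplos <- list()
  realized <- data.frame(event_id = character(), taxon = character(),
                         chrom = character(), left = integer(),
                         right = integer(), stringsAsFactors = FALSE)
  dups <- data.frame(event_id = character(), length = integer(),
                     placement = character(), stringsAsFactors = FALSE)
  for (tip in tips) {
    branch_path <- branches_to_tip(tree, tip)
    g <- ancestral
    g$taxon_id <- tip
    live <- list()   # realized coords of events applied on this lineage
    g_anc_haplo <- NULL
    for (br in branch_path) {
      for (ev in events) {
        if (!identical(ev$branch, br)) next
        if (ev$state == "polymorphic" && is.null(g_anc_haplo) && br == tip)
          g_anc_haplo <- g   # haplotype without the polymorphic event(s)
        g2 <- apply_inversion(g, ev)
        rl <- attr(g2, "realized")
        # update earlier events' coordinates through this rearrangement
        if (length(live)) {
          a <- if (ev$mechanism == "staggered") ev$offset_left else 0L
          b <- if (ev$mechanism == "staggered") ev$offset_right else 0L
          pre_r <- rl[["right"]] - a - b  # right cut in the pre-event frame
          for (i in seq_along(live)) {
            if (live[[i]]$chrom != ev$chrom) next
            lr <- c(live[[i]]$left, live[[i]]$right)
            lr2 <- sort(shift_position(lr, rl[["left"]], pre_r, a, b))
            live[[i]]$left <- lr2[1L]; live[[i]]$right <- lr2[2L]
          }
        }
        live[[length(live) + 1L]] <- list(event_id = ev$event_id,
                                          chrom = ev$chrom,
                                          left = unname(rl[["left"]]),
                                          right = unname(rl[["right"]]))
        g <- g2
      }
    }
    genomes[[tip]] <- g
    if (!is.null(g_anc_haplo)) haplos[[tip]] <- g_anc_haplo
    if (length(live))
      realized <- rbind(realized, do.call(rbind, lapply(live, function(x)
        data.frame(event_id = x$event_id, taxon = tip, chrom = x$chrom,
                   left = x$left, right = x$right,
                   stringsAsFactors = FALSE))))
  }
  ev_df <- do.call(rbind, lapply(events, function(ev)
    data.frame(event_id = ev$event_id, chrom = ev$chrom,
               left_bp = ev$left_bp, right_bp = ev$right_bp,
               mechanism = ev$mechanism, offset_left = ev$offset_left,
               offset_right = ev$offset_right, branch = ev$branch,
               state = ev$state, stringsAsFactors = FALSE)))
  if (is.null(ev_df))
    ev_df <- data.frame(event_id = character(), chrom = character(),
                        left_bp = integer(), right_bp = integer(),
                        mechanism = character(), offset_left = integer(),
                        offset_right = integer(), branch = character(),
                        state = character(), stringsAsFactors = FALSE)
  for (ev in events) {
    if (ev$mechanism == "staggered") {
      dups <- rbind(dups,
        data.frame(event_id = ev$event_id,
                   length = c(ev$offset_left, ev$offset_right),
                   placement = c("left_flank", "right_flank"),
                   stringsAsFactors = FALSE))
    }
  }
  truth <- structure(list(events = ev_df, realized = realized,
                          duplications = dups, seed = seed),
                     class = "truth_table")
  list(genomes = genomes, haplotypes = haplos, truth = truth)
}

# Ordered branch labels (root -> tip) for one tip: internal-node labels of
# the nodes on the path (the branch above each node), then the tip label.
branches_to_tip <- function(tree, tip) {
  it <- match(tip, tree$tip.label)
  ntip <- length(tree$tip.label)
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]
  path <- integer(0); node <- it
  while (TRUE) {
    e <- match(node, child)
    if (is.na(e)) break
    path <- c(parent[e], path)
    node <- parent[e]
  }
  labs <- character(0)
  for (nd in path) {
    if (nd > ntip && !is.null(tree$node.label)) {
      lb <- tree$node.label[nd - ntip]
      if (!is.na(lb) && nzchar(lb)) labs <- c(labs, lb)
    }
  }
  c(labs, tip)
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("<truth_table> %d event(s), %d realized record(s), %d duplication(s)\n",
              nrow(x$events), nrow(x$realized), nrow(x$duplications)))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}
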
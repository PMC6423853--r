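# History stage: polarity against an outgroup, parsimony mapping of
# inversions onto the species tree, and lineage fixation-rate statistics.

#' Infer inversion polarity from marker orders around a breakpoint
#'
#' Each taxon's breakpoint-flanking marker window is compared with the
#' outgroup's gene arrangement: a taxon shows the ancestral state iff its
#' window occurs as one contiguous run (forward or reversed, allowing for
#' assembly orientation) in the outgroup order.  A derived junction joins
#' markers from two distant outgroup locations and therefore breaks
#' contiguity.  Both matching means no inversion at this site; neither
#' matching, or fewer than `min_shared` markers shared with the outgroup,
#' yields `undetermined` — never a guess.
#'
#' @param order_a,order_b Character vectors of marker ids in chromosomal
#'   order around the breakpoint of each taxon (three markers per side for
#'   a confident call).
#' @param order_outgroup Marker ids in outgroup chromosomal order; may be
#'   the full chromosome's order.
#' @param taxon_a,taxon_b Taxon labels (defaults `"A"`, `"B"`).
#' @param inversion_id Optional label.
#' @param min_shared Minimum markers shared with the outgroup (default 6,
#'   i.e. three per side).
#' @return A `polarity_call`: list with `inversion_id`, `status`
#'   (`"resolved"`, `"no_inversion"`, `"undetermined"`),
#'   `ancestral_taxon`, `derived_taxon` and the compared orders.
#' @examples
#' infer_polarity(c("m1","m2","m3","m4","m5","m6"),
#'                c("m1","m2","m3","m6","m5","m4"),
#'                c("m1","m2","m3","m4","m5","m6"))
#' @export
infer_polarity <- function(order_a, order_b, order_outgroup,
                           taxon_a = "A", taxon_b = "B",
                           inversion_id = NA_character_, min_shared = 6L) {
  res <- function(status, anc = NA_character_, der = NA_character_)
    structure(list(inversion_id = inversion_id, status = status,
                   ancestral_taxon = anc, derived_taxon = der,
                   orders = list(a = order_a, b = order_b,
                                 outgroup = order_outgroup)),
              class = "polarity_call")
  # contiguous-run test: positions of the taxon's window in the outgroup
  # order must be consecutive and monotone
  matches <- function(x) {
    y <- x[x %in% order_outgroup]
    if (length(y) < min_shared) return(NA)
    pos <- match(y, order_outgroup)
    d <- diff(pos)
    all(d == 1L) || all(d == -1L)
  }
  ma <- matches(order_a); mb <- matches(order_b)
  if (is.na(ma) || is.na(mb)) return(res("undetermined"))
  if (ma && mb) return(res("no_inversion"))
  if (!ma && !mb) return(res("undetermined"))
  if (ma) res("resolved", anc = taxon_a, der = taxon_b)
  else res("resolved", anc = taxon_b, der = taxon_a)
}

#' @export
print.polarity_call <- function(x, ...) {
  cat(sprintf("<polarity_call>%s %s",
              if (is.na(x$inversion_id)) "" else paste0(" ", x$inversion_id),
              x$status))
  if (identical(x$status, "resolved"))
    cat(sprintf(": ancestral = %s, derived = %s",
                x$ancestral_taxon, x$derived_taxon))
  cat("\n")
  invisible(x)
}

#' Map inversions onto the species tree by single-origin parsimony
#'
#' Each inversion is placed on the earliest branch consistent with all
#' tips carrying its derived state (Dollo-like single origin, no loss
#' except through replacement by nested derivatives, recorded as the state
#' `extinct_ancestral`).  A derived state present in taxa that do not form
#' a clade is an error naming the conflicting taxa.
#'
#' @param tip_states data.frame with columns `inversion_id`, `taxon`,
#'   `state` in `fixed`, `polymorphic`, `absent`, `extinct_ancestral`
#'   (absent rows default to `absent`).
#' @param tree An [ape::read.tree()] phylogeny; internal branches are
#'   named by node labels (e.g. `"ms"`).
#' @return data.frame with one row per inversion: `inversion_id`, `branch`
#'   and one `state_<taxon>` column per tip.
#' @export
assign_to_branches <- function(tip_states, tree) {
  stopifnot(inherits(tree, "phylo"),
            all(c("inversion_id", "taxon", "state") %in% names(tip_states)))
  bad <- setdiff(tip_states$taxon, tree$tip.label)
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  ntip <- length(tree$tip.label)
  out <- list()
  for (inv in unique(tip_states$inversion_id)) {
    st <- setNames(rep("absent", ntip), tree$tip.label)
    rows <- tip_states[tip_states$inversion_id == inv, , drop = FALSE]
    st[rows$taxon] <- rows$state
    carriers <- names(st)[st != "absent"]
    if (!length(carriers))
      stop("inversion ", inv, ": no taxon carries the derived state")
    if (length(carriers) == 1L) {
      branch <- carriers
    } else {
      mrca <- ape::getMRCA(tree, carriers)
      desc <- tree$tip.label[descendant_tips(tree, mrca)]
      non_carrier <- setdiff(desc, carriers)
      if (length(non_carrier))
        stop("inversion ", inv, ": derived state pattern impossible under ",
             "a single origin; carriers {",
             paste(carriers, collapse = ", "), "} conflict with {",
             paste(non_carrier, collapse = ", "), "}")
      branch <- node_branch_label(tree, mrca)
    }
    row <- data.frame(inversion_id = inv, branch = branch,
                      stringsAsFactors = FALSE)
    for (tp in tree$tip.label) row[[paste0("state_", tp)]] <- st[[tp]]
    out[[length(out) + 1L]] <- row
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

node_branch_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  lb <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
  if (!is.na(lb) && nzchar(lb)) return(lb)
  paste(tree$tip.label[descendant_tips(tree, node)], collapse = "+")
}

#' Inversion fixation rate
#'
#' @param k Number of fixed inversions.
#' @param t Exposure in Myr (branch time, possibly times the number of
#'   chromosomes for per-chromosome rates).
#' @return Rate in inversions/Myr (raw value; display to two significant
#'   figures with `signif(x, 2)`).
#' @examples
#' signif(fixation_rate(6, 1.72), 2)       # 3.5, sex chromosome
#' signif(fixation_rate(3, 4 * 1.72), 2)   # 0.44, per average autosome
#' @export
fixation_rate <- function(k, t) {
  if (t <= 0) stop("exposure t must be > 0")
  if (k < 0) stop("count k must be >= 0")
  k / t
}

#' Exact conditional test comparing two Poisson rates
#'
#' Conditional on the total count `n = k1 + k2`, `k1` is binomial with
#' success probability `t1 / (t1 + t2)` under equal rates.  The one-sided
#' p-value is the upper tail `P(X >= k1)`; the two-sided p-value doubles
#' the smaller tail (capped at 1).
#'
#' @param k1,k2 Fixed-inversion counts (>= 0).
#' @param t1,t2 Exposures in Myr (> 0).
#' @return A `rate_comparison`: list with counts, exposures, rates, the
#'   rate ratio and both p-values.  `n = 0` gives p = 1.
#' @examples
#' rate_ratio_test(6, 1.72, 3, 4 * 1.72)   # two-sided p = 0.006
#' @export
rate_ratio_test <- function(k1, t1, k2, t2) {
  stopifnot(k1 >= 0, k2 >= 0, t1 > 0, t2 > 0)
  n <- k1 + k2
  p1 <- t1 / (t1 + t2)
  if (n == 0) {
    p_upper <- p_lower <- p_two <- 1
  } else {
    p_upper <- sum(dbinom(k1:n, n, p1))       # P(X >= k1)
    p_lower <- sum(dbinom(0:k1, n, p1))       # P(X <= k1)
    p_two <- min(1, 2 * min(p_upper, p_lower))
  }
  r1 <- k1 / t1; r2 <- k2 / t2
  structure(list(k1 = k1, k2 = k2, t1 = t1, t2 = t2,
                 rate1 = r1, rate2 = r2,
                 ratio = if (r2 > 0) r1 / r2 else Inf,
                 p_one_sided = p_upper, p_two_sided = p_two,
                 method = "exact conditional binomial (Poisson rates)"),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf("<rate_comparison> %d/%.3g Myr = %.2g vs %d/%.3g Myr = %.2g inversions/Myr\n",
              x$k1, x$t1, signif(x$rate1, 2), x$k2, x$t2, signif(x$rate2, 2)))
  cat(sprintf("  ratio %.2g; one-sided P = %.3g, two-sided P = %.3g (%s)\n",
              x$ratio, x$p_one_sided, x$p_two_sided, x$method))
  invisible(x)
}

#' The subobscura-subgroup species tree
#'
#' `((subobscura, madeirensis), guanche)` with branch durations in Myr:
#' 1.72 Myr to the subgroup common ancestor and 0.92 Myr to the
#' madeirensis split.  The internal node above subobscura+madeirensis is
#' labelled `ms`.  An optional unrearranged `outgroup` tip can be added
#' for polarity inference.
#'
#' @param age_subgroup Age of the subgroup common ancestor in Myr
#'   (default 1.72).
#' @param age_ms_split Age of the madeirensis split in Myr (default 0.92).
#' @param outgroup Add an outgroup tip? (default TRUE).
#' @return An [ape::phylo] tree with node labels.
#' @export
subgroup_tree <- function(age_subgroup = 1.72, age_ms_split = 0.92,
                          outgroup = TRUE) {
  inner <- sprintf("((subobscura:%g,madeirensis:%g)ms:%g,guanche:%g)root",
                   age_ms_split, age_ms_split,
                   age_subgroup - age_ms_split, age_subgroup)
  nwk <- if (outgroup)
    sprintf("(%s:1,outgroup:%g)top;", inner, age_subgroup + 1)
  else paste0(inner, ";")
  ape::read.tree(text = nwk)
}
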
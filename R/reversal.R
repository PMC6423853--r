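# Sorting signed permutations by reversals.  The main route is an exact
# Hannenhalli-Pevzner breakpoint-graph computation (cycles, hurdles,
# fortress); an independent exhaustive breadth-first-search oracle over the
# full signed-permutation space (compiled, n <= 8) is provided as a
# cross-check route for tests.

#' Construct a signed permutation
#'
#' @param elements Integer vector whose absolute values are a permutation
#'   of `1..n`; the sign encodes block orientation.
#' @param chrom Optional chromosome label.
#' @return A `signed_permutation`.
#' @export
signed_permutation <- function(elements, chrom = NA_character_) {
  elements <- as.integer(elements)
  n <- length(elements)
  if (n && !identical(sort(abs(elements)), seq_len(n)))
    stop("absolute values must be a permutation of 1..n")
  structure(list(chrom = chrom, elements = elements),
            class = "signed_permutation")
}

#' @export
print.signed_permutation <- function(x, ...) {
  e <- x$elements
  cat(sprintf("<signed_permutation>%s (%s)\n",
              if (is.na(x$chrom)) "" else paste0(" ", x$chrom),
              paste(ifelse(e > 0, paste0("+", e), e), collapse = ", ")))
  invisible(x)
}

perm_elements <- function(perm) {
  if (inherits(perm, "signed_permutation")) perm$elements
  else as.integer(perm)
}

# ---- Hannenhalli-Pevzner ---------------------------------------------------

# Breakpoint graph of a signed permutation, on the extended unsigned
# sequence 0, a1 b1, ..., an bn, 2n+1 (+x -> (2x-1, 2x); -x -> (2x, 2x-1)).
# Black edges join array positions (1,2), (3,4), ...; gray edges join the
# array positions of values 2i and 2i+1.
bp_graph <- function(e) {
  n <- length(e)
  u <- integer(2L * n + 2L)
  u[1L] <- 0L; u[2L * n + 2L] <- 2L * n + 1L
  for (i in seq_len(n)) {
    x <- e[i]
    u[2L * i] <- if (x > 0L) 2L * x - 1L else -2L * x
    u[2L * i + 1L] <- if (x > 0L) 2L * x else -2L * x - 1L
  }
  posn <- integer(2L * n + 2L)      # posn[v+1] = array index of value v
  posn[u + 1L] <- seq_along(u)
  gray <- cbind(posn[seq(1L, 2L * n + 1L, by = 2L)],
                posn[seq(2L, 2L * n + 2L, by = 2L)])
  gray <- t(apply(gray, 1L, sort))
  list(u = u, gray = gray, n = n)
}

# Cycle count of the breakpoint graph.
bp_cycles <- function(g) {
  m <- 2L * g$n + 2L
  # adjacency: black partner and gray partner of each position
  black <- integer(m); gray <- integer(m)
  for (k in seq_len(m / 2L)) {
    i <- 2L * k - 1L; j <- 2L * k
    black[i] <- j; black[j] <- i
  }
  for (r in seq_len(nrow(g$gray))) {
    i <- g$gray[r, 1L]; j <- g$gray[r, 2L]
    gray[i] <- j; gray[j] <- i
  }
  seen <- logical(m); c0 <- 0L
  for (s in seq_len(m)) {
    if (seen[s]) next
    c0 <- c0 + 1L
    v <- s; use_black <- TRUE
    repeat {
      seen[v] <- TRUE
      v <- if (use_black) black[v] else gray[v]
      use_black <- !use_black
      if (v == s && use_black) break
    }
  }
  c0
}

# Components of the interleaving graph over gray edges, with orientation.
# Two gray edges interleave iff exactly one endpoint of one lies strictly
# inside the other's span.  A gray edge (i, j) is oriented iff j - i is
# even; trivial edges (adjacencies, j == i + 1) form no component.
bp_components <- function(g) {
  ge <- g$gray
  nontrivial <- which(ge[, 2L] - ge[, 1L] > 1L)
  k <- length(nontrivial)
  if (!k) return(list())
  ge <- ge[nontrivial, , drop = FALSE]
  comp <- seq_len(k)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (p in seq_len(k)) for (q in seq_len(k)) {
    if (p >= q) next
    i1 <- ge[p, 1L]; j1 <- ge[p, 2L]; i2 <- ge[q, 1L]; j2 <- ge[q, 2L]
    inter <- (i1 < i2 && i2 < j1 && j1 < j2) || (i2 < i1 && i1 < j2 && j2 < j1)
    if (inter) { a <- find(p); b <- find(q); if (a != b) comp[a] <- b }
  }
  roots <- vapply(seq_len(k), find, 1L)
  lapply(split(seq_len(k), roots), function(idx) {
    edges <- ge[idx, , drop = FALSE]
    list(positions = sort(unique(as.vector(edges))),
         span = range(edges),
         oriented = any((edges[, 2L] - edges[, 1L]) %% 2L == 0L))
  })
}

# Hurdles among unoriented components: a component is a hurdle iff its
# positions are consecutive on the circle of breakpoint-graph positions,
# i.e. all positions of the other unoriented components fall in a single
# gap between its own consecutive positions (including the wrap-around
# arc through the frame ends).
count_hurdles <- function(comps) {
  unor <- Filter(function(cp) !cp$oriented, comps)
  if (!length(unor)) return(list(h = 0L, fortress = FALSE))
  is_hurdle_in <- function(set, i) {
    p <- set[[i]]$positions
    others <- unlist(lapply(set[-i], `[[`, "positions"))
    if (!length(others)) return(TRUE)
    # gap index for each foreign position: findInterval over own positions;
    # 0 or length(p) are both the wrap arc
    gi <- findInterval(others, p)
    gi[gi == length(p)] <- 0L
    length(unique(gi)) == 1L
  }
  k <- length(unor)
  hurdle <- vapply(seq_len(k), function(i) is_hurdle_in(unor, i), TRUE)
  h <- sum(hurdle)
  fortress <- FALSE
  if (h %% 2L == 1L) {
    # superhurdle: deleting it turns some non-hurdle unoriented component
    # into a hurdle; a fortress has an odd number of hurdles, all super
    super <- logical(k)
    for (i in which(hurdle)) {
      rest <- unor[-i]
      if (!length(rest)) { super[i] <- FALSE; next }
      old <- hurdle[-i]
      new <- vapply(seq_along(rest), function(j) is_hurdle_in(rest, j), TRUE)
      super[i] <- any(new & !old)
    }
    fortress <- all(super[hurdle])
  }
  list(h = as.integer(h), fortress = fortress)
}

#' Minimum number of reversals to sort a signed permutation
#'
#' Exact reversal distance to the positive identity, computed on the
#' breakpoint graph as `n + 1 - cycles + hurdles + fortress`
#' (Hannenhalli-Pevzner).  This reproduces the sorting-signed-permutations
#' semantics of the GRIMM program.
#'
#' @param perm A [signed_permutation()] or plain signed integer vector.
#' @return Integer distance (0 for the identity).
#' @examples
#' reversal_distance(c(1, 2, 3))   # 0
#' reversal_distance(c(-2, -1))    # 1
#' reversal_distance(c(2, 1))      # 3
#' @export
reversal_distance <- function(perm) {
  e <- perm_elements(perm)
  n <- length(e)
  if (!n) return(0L)
  g <- bp_graph(e)
  c0 <- bp_cycles(g)
  hh <- count_hurdles(bp_components(g))
  as.integer(n + 1L - c0 + hh$h + as.integer(hh$fortress))
}

#' Exhaustive BFS oracle for reversal distance
#'
#' Independent cross-check for [reversal_distance()]: breadth-first search
#' over the complete reversal graph of all `2^n * n!` signed permutations
#' (compiled; practical for `n <= 8`).  Distance tables are cached per
#' `n` within the session.
#'
#' @param perm A [signed_permutation()] or signed integer vector,
#'   `length <= 8`.
#' @return Integer distance.
#' @export
reversal_distance_bfs <- function(perm) {
  e <- perm_elements(perm)
  n <- length(e)
  if (!n) return(0L)
  if (n > 8L) stop("BFS oracle supports n <= 8")
  key <- as.character(n)
  tab <- .bfs_cache[[key]]
  if (is.null(tab)) {
    tab <- reversal_bfs_table(n)
    .bfs_cache[[key]] <- tab
  }
  tab[perm_index(e) + 1L]
}

.bfs_cache <- new.env(parent = emptyenv())

# state index = lehmer_rank(|e|) * 2^n + sign bits (bit i-1 set iff e[i] < 0);
# must match the compiled encoding.
perm_index <- function(e) {
  n <- length(e)
  p <- abs(e)
  rank <- 0
  avail <- seq_len(n)
  for (i in seq_len(n)) {
    pos <- match(p[i], avail) - 1L
    rank <- rank * (n - i + 1) + pos
    avail <- avail[-(pos + 1L)]
  }
  bits <- sum(2^(which(e < 0) - 1L))
  rank * 2^n + bits
}

#' Apply a reversal to a signed permutation
#'
#' Reverses elements `i..j` (1-based, inclusive) and flips their signs.
#'
#' @param perm Signed integer vector or [signed_permutation()].
#' @param i,j Element indices, `i <= j`.
#' @return Vector of the same length.
#' @export
apply_reversal <- function(perm, i, j) {
  e <- perm_elements(perm)
  e[i:j] <- -rev(e[i:j])
  e
}

#' One optimal sorting scenario
#'
#' Returns a minimum-length sequence of reversals transforming `perm` into
#' the positive identity.  Ties are broken deterministically: at each step
#' the lexicographically smallest `(start, end)` reversal that preserves
#' optimality is taken, so the whole scenario is the lexicographically
#' smallest optimal one.
#'
#' @param perm A [signed_permutation()] or signed integer vector.
#' @return A `reversal_scenario`: list with `permutation`, `reversals`
#'   (list of `c(start, end)` element indices) and `distance`.
#' @export
sort_by_reversals <- function(perm) {
  e0 <- perm_elements(perm)
  e <- e0
  d <- reversal_distance(e)
  revs <- list()
  while (d > 0L) {
    found <- FALSE
    for (i in seq_along(e)) {
      for (j in i:length(e)) {
        e2 <- apply_reversal(e, i, j)
        if (reversal_distance(e2) == d - 1L) {
          revs[[length(revs) + 1L]] <- c(start = i, end = j)
          e <- e2; d <- d - 1L; found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) stop("internal error: no distance-reducing reversal found")
  }
  structure(list(permutation = e0, reversals = revs,
                 distance = length(revs)),
            class = "reversal_scenario")
}

#' @export
print.reversal_scenario <- function(x, ...) {
  cat(sprintf("<reversal_scenario> distance %d\n", x$distance))
  e <- x$permutation
  cat("  ", paste(ifelse(e > 0, paste0("+", e), e), collapse = " "), "\n")
  for (r in x$reversals) {
    e <- apply_reversal(e, r[["start"]], r[["end"]])
    cat(sprintf("  rev[%d..%d] -> %s\n", r[["start"]], r[["end"]],
                paste(ifelse(e > 0, paste0("+", e), e), collapse = " ")))
  }
  invisible(x)
}
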
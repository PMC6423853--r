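test_that("anchors are the shared marker ids with relative strands", {
  g1 <- toy_genome("t1", starts = c(100, 400, 700), ids = c("a", "b", "c"))
  g2 <- toy_genome("t2", starts = c(100, 400, 700), ids = c("x", "y", "z"))
  expect_equal(nrow(find_anchors(g1, g2)), 0L)  # disjoint id sets

  g3 <- toy_genome("t3", starts = c(100, 400, 700), ids = c("a", "b", "c"))
  a <- find_anchors(g1, g3)
  expect_equal(nrow(a), 3L)
  expect_true(all(a$rel_strand == 1L))

  # a 5-marker inverted segment flips exactly those relative strands
  g4 <- make_ancestral_genome(1L, 30000L, 12L, seed = 4, chrom_names = "c1",
                              marker_length = 300L, with_sequence = FALSE)
  m <- g4$chromosomes[[1]]$markers
  l <- (m$end[3] + m$start[4]) %/% 2L   # gap midpoints around markers 4..8
  r <- (m$end[8] + m$start[9]) %/% 2L
  inv_ids <- m$id[m$start >= l & m$end <= r]
  expect_length(inv_ids, 5L)
  g5 <- apply_inversion(g4, inversion_event("e", "c1", l, r))
  a2 <- find_anchors(g4, g5)
  expect_setequal(a2$marker_id[a2$rel_strand == -1L], inv_ids)

  # paralogy is unsupported
  gdup <- toy_genome("t5", starts = c(100, 400), ids = c("a", "b"))
  gdup$chromosomes[[1]]$markers$id <- c("a", "a")
  expect_error(find_anchors(gdup, g1), "paralogy")
})

test_that("chaining produces signed collinear blocks", {
  mk_anchors <- function(pos1, pos2, strand) data.frame(
    marker_id = sprintf("m%02d", seq_along(pos1)),
    chrom1 = rep("c1", length(pos1)), start1 = pos1, end1 = pos1 + 100L,
    strand1 = rep("+", length(pos1)),
    chrom2 = rep("c2", length(pos1)), start2 = pos2, end2 = pos2 + 100L,
    strand2 = rep("+", length(pos1)),
    rel_strand = strand, stringsAsFactors = FALSE)

  # perfectly collinear anchors give one + block with all anchors
  p <- seq(0L, 1400L, by = 200L)
  b <- chain_blocks(mk_anchors(p, p, 1L), min_anchors = 3L, max_gap = 500)
  expect_equal(nrow(b), 1L)
  expect_equal(b$orientation, 1L)
  expect_equal(b$n_anchors, 8L)

  # a 15-anchor toy with an inverted interior run gives (+, -, +)
  p1 <- seq(0L, 2800L, by = 200L)
  p2 <- p1
  p2[6:10] <- rev(p1[6:10])
  str <- rep(1L, 15L); str[6:10] <- -1L
  b3 <- chain_blocks(mk_anchors(p1, p2, str), min_anchors = 3L,
                     max_gap = 500)
  expect_equal(nrow(b3), 3L)
  expect_equal(b3$orientation, c(1L, -1L, 1L))
  expect_equal(b3$n_anchors, c(5L, 5L, 5L))

  # a 1-anchor inverted run below min_anchors is dropped and the flanking
  # collinear runs re-chain into a single block
  p1 <- seq(0L, 1200L, by = 200L)
  p2 <- p1; str <- rep(1L, 7L)
  str[4] <- -1L
  b1 <- chain_blocks(mk_anchors(p1, p2, str), min_anchors = 2L,
                     max_gap = 500)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$n_anchors, 6L)

  expect_equal(nrow(chain_blocks(mk_anchors(integer(0), integer(0),
                                            integer(0)))), 0L)
})

test_that("block statistics and signed permutations are consistent", {
  st0 <- block_stats(chain_blocks(data.frame()))
  expect_equal(st0, list(n_blocks = 0L, mean_size_mb = 0, n_inverted = 0L))

  b <- data.frame(block_id = 1:2, chrom1 = "c1",
                  start1 = c(0L, 2e6), end1 = c(1e6, 5e6),
                  chrom2 = "c2", start2 = c(0L, 2e6), end2 = c(1e6, 5e6),
                  orientation = c(1L, -1L), n_anchors = c(5L, 5L))
  st <- block_stats(b)
  expect_equal(st$n_blocks, 2L)
  expect_equal(st$mean_size_mb, 2.0)
  expect_equal(st$n_inverted, 1L)

  expect_equal(to_signed_permutation(b[1, ], "c1")$elements, 1L)
  b3 <- data.frame(block_id = 1:3, chrom1 = "c1",
                   start1 = c(0, 10, 20) * 1e3, end1 = c(9, 19, 29) * 1e3,
                   chrom2 = "c2", start2 = c(0, 10, 20) * 1e3,
                   end2 = c(9, 19, 29) * 1e3,
                   orientation = c(1L, -1L, 1L), n_anchors = 3L)
  expect_equal(to_signed_permutation(b3, "c1")$elements, c(1L, -2L, 3L))

  btr <- b3; btr$chrom2 <- c("c2", "c3", "c2")
  expect_error(to_signed_permutation(btr, "c1"), "translocation")
})

test_that("swapping the genomes preserves block span pairs and signs", {
  sim <- single_inversion_pair(seed = 21, with_sequence = FALSE)
  a12 <- find_anchors(sim$ancestor, sim$derived)
  a21 <- find_anchors(sim$derived, sim$ancestor)
  b12 <- chain_blocks(a12, 3L, 8000)
  b21 <- chain_blocks(a21, 3L, 8000)
  expect_equal(nrow(b12), nrow(b21))
  key <- function(b) {
    sp <- apply(cbind(paste(b$start1, b$end1), paste(b$start2, b$end2)),
                1L, function(x) paste(sort(x), collapse = "|"))
    sort(paste(sp, b$orientation))
  }
  expect_identical(key(b12), key(b21))
})

test_that("block count equals true breakpoint count + 1 on disjoint inversions", {
  # two disjoint inversions on one chromosome: 4 breakpoints, 5 blocks
  g <- make_ancestral_genome(1L, 120000L, 60L, seed = 31, chrom_names = "c1",
                             marker_length = 300L, with_sequence = FALSE)
  l1 <- snap_intergenic(g, "c1", 20000); r1 <- snap_intergenic(g, "c1", 45000)
  l2 <- snap_intergenic(g, "c1", 70000); r2 <- snap_intergenic(g, "c1", 100000)
  g2 <- apply_inversion(g, inversion_event("e1", "c1", l1, r1))
  g2 <- apply_inversion(g2, inversion_event("e2", "c1", l2, r2))
  b <- chain_blocks(find_anchors(g, g2), min_anchors = 3L, max_gap = 6000)
  expect_equal(nrow(b), 5L)
  expect_equal(sum(b$orientation == -1L), 2L)
})
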
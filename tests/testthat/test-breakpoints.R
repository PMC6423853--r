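test_that("breakpoint intervals are the gaps between contiguous blocks", {
  b1 <- data.frame(block_id = 1L, chrom1 = "c1", start1 = 0L, end1 = 100L,
                   chrom2 = "c2", start2 = 0L, end2 = 100L,
                   orientation = 1L, n_anchors = 3L)
  expect_equal(nrow(breakpoint_intervals(b1)), 0L)

  b2 <- rbind(b1, data.frame(block_id = 2L, chrom1 = "c1", start1 = 120L,
                             end1 = 200L, chrom2 = "c2", start2 = 120L,
                             end2 = 200L, orientation = -1L,
                             n_anchors = 3L))
  iv <- breakpoint_intervals(b2)
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$start, iv$end), c(100L, 120L))
  expect_equal(c(iv$left_block, iv$right_block), c(1L, 2L))

  # abutting blocks give a zero-length interval at the shared coordinate
  b3 <- b2; b3$start1[2] <- 100L
  iv3 <- breakpoint_intervals(b3)
  expect_equal(c(iv3$start, iv3$end), c(100L, 100L))
})

test_that("breakpoint intervals bracket the true cut on clean-break simulations", {
  for (seed in c(101, 202)) {
    sim <- single_inversion_pair(seed, with_sequence = FALSE)
    b <- chain_blocks(find_anchors(sim$derived, sim$ancestor), 3L, 8000)
    iv <- breakpoint_intervals(b)
    expect_equal(nrow(iv), 2L)
    truth <- sort(unname(sim$realized))
    for (k in 1:2)
      expect_true(iv$start[k] <= truth[k] && truth[k] <= iv$end[k])
  }
})

test_that("flank mapping finds full-length hits at unrearranged loci", {
  g <- toy_genome("t1", length = 30000L, with_sequence = TRUE, seed = 51)
  g2 <- g; g2$taxon_id <- "t2"
  rep <- map_flank(g, "chr1", 15000L, 15000L, g2, flank_width = 1000L,
                   min_score = 30)
  expect_gte(nrow(rep$hits), 1L)
  top <- rep$hits[1L, ]
  expect_equal(top$strand, "+")
  expect_equal(top$overhang_left, 0L)
  expect_equal(top$overhang_right, 0L)
  expect_equal(top$target_start, 14000L)
  expect_equal(top$target_end, 16000L)

  # a query with no homology in the target yields no hits
  set.seed(1)
  alien <- toy_genome("alien", length = 6000L, with_sequence = TRUE,
                      seed = 999)
  rep0 <- map_flank(alien, "chr1", 3000L, 3000L, g2, flank_width = 1000L,
                    min_score = 200)
  expect_equal(nrow(rep0$hits), 0L)
})

test_that("a breakpoint-spanning query splits into two strand-discordant hits", {
  sim <- single_inversion_pair(seed = 61)
  b <- chain_blocks(find_anchors(sim$derived, sim$ancestor), 3L, 8000)
  iv <- breakpoint_intervals(b)
  rep <- map_flank(sim$derived, "c1", iv$start[1], iv$end[1],
                   sim$ancestor, flank_width = 1000L)
  expect_equal(nrow(rep$hits), 2L)
  expect_setequal(rep$hits$strand, c("+", "-"))
  # hit endpoints coincide with the true ancestral cuts within resolution
  truth <- c(sim$event$left_bp, sim$event$right_bp)
  ends <- c(rep$hits$target_start, rep$hits$target_end)
  for (tp in truth)
    expect_lte(min(abs(ends - tp)), 10L)
})

test_that("reciprocal consistency holds for true breakpoints and fails when perturbed", {
  sim <- single_inversion_pair(seed = 71)
  bder <- chain_blocks(find_anchors(sim$derived, sim$ancestor), 3L, 8000)
  banc <- chain_blocks(find_anchors(sim$ancestor, sim$derived), 3L, 8000)
  ivd <- breakpoint_intervals(bder)
  iva <- breakpoint_intervals(banc)
  rep12 <- map_flank(sim$derived, "c1", ivd$start[1], ivd$end[1],
                     sim$ancestor, flank_width = 1000L)
  rep21 <- map_flank(sim$ancestor, "c1", iva$start[1], iva$end[1],
                     sim$derived, flank_width = 1000L)
  expect_true(reciprocal_consistency(rep12, rep21, tol = 1000L))

  empty <- rep21; empty$hits <- empty$hits[0L, ]
  expect_false(reciprocal_consistency(rep12, empty, tol = 1000L))

  shifted <- rep21
  shifted$hits$target_start <- shifted$hits$target_start + 2500L
  shifted$hits$target_end <- shifted$hits$target_end + 2500L
  shifted$query$breakpoint <- shifted$query$breakpoint + 2500L
  expect_false(reciprocal_consistency(rep12, shifted, tol = 1000L))
})

test_that("inverted duplications are detected at their simulated length", {
  set.seed(81)
  # random unrelated flanks: no call
  expect_null(detect_inverted_duplication(random_dna(2000), random_dna(2000)))

  for (off in c(300L, 689L)) {
    sim <- single_inversion_pair(seed = 80 + off, mechanism = "staggered",
                                 offset = off)
    rl <- sim$realized
    ch <- sim$derived$chromosomes[[1]]
    # flanks must span both stagger fragments on each side of a junction
    fw <- 2L * off + 500L
    fl <- subseq_chr(ch, rl[["left"]] - fw, rl[["left"]] + fw)
    fr <- subseq_chr(ch, rl[["right"]] - fw, rl[["right"]] + fw)
    dup <- detect_inverted_duplication(fl, fr)
    expect_false(is.null(dup))
    expect_lte(abs(dup$length - off), 5L)
    expect_gte(dup$identity, 0.95)
  }
})

test_that("the mechanism decision table is applied as stated", {
  dup <- structure(list(length = 689L, identity = 1, orientation = "inverted"),
                   class = "duplication_call")
  expect_equal(classify_mechanism(dup, NULL)$mechanism, "staggered")
  expect_equal(classify_mechanism(NULL, NULL)$mechanism,
               "straight_or_nearly_straight")
  expect_equal(classify_mechanism(dup, dup)$mechanism,
               "ectopic_recombination")
  expect_equal(classify_mechanism(NULL, dup)$mechanism, "undetermined")
})

test_that("gene disruption reflects true overlap with the breakpoint interval", {
  markers <- data.frame(id = c("a", "b"), start = c(100L, 500L),
                        end = c(200L, 600L), strand = "+")
  expect_false(check_gene_disruption(list(start = 250L, end = 400L),
                                     markers)$disrupted)
  hit <- check_gene_disruption(list(start = 150L, end = 300L), markers)
  expect_true(hit$disrupted)
  expect_equal(hit$genes, "a")
  # zero-length interval tested as a point
  expect_true(check_gene_disruption(list(start = 150L, end = 150L),
                                    markers)$disrupted)
  expect_false(check_gene_disruption(list(start = 200L, end = 200L),
                                     markers)$disrupted)

  # simulated disruption mode is recovered
  g <- toy_genome("t", length = 5000L, starts = c(1000L, 3000L),
                  ids = c("a", "b"), with_sequence = TRUE, seed = 91)
  ev <- inversion_event("e", "chr1", 1050L, 4000L)
  g2 <- simulate_gene_disruption(g, ev)
  m2 <- g2$chromosomes[[1]]$markers
  iv <- list(start = 1040L, end = 1060L)
  expect_true(any(grepl("^a\\.", check_gene_disruption(iv, m2)$genes)) ||
                check_gene_disruption(iv, m2)$disrupted)
})

test_that("flank repeat content is the covered fraction", {
  bed <- data.frame(chrom = "c1", start = c(0L, 150L), end = c(100L, 250L))
  expect_equal(flank_repeat_content("c1", 0L, 200L, bed), 150 / 200)
  expect_equal(flank_repeat_content("c1", 300L, 400L, bed), 0)
  expect_equal(flank_repeat_content("c2", 0L, 200L, bed), 0)
})
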
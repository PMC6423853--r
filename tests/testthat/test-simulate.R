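test_that("ancestral genome generation honours the request exactly", {
  # degenerate case: no markers at all
  g0 <- make_ancestral_genome(1L, 10000L, 0L, seed = 1)
  expect_equal(nrow(g0$chromosomes[[1]]$markers), 0L)
  expect_equal(g0$chromosomes[[1]]$length, 10000L)

  # chromosome length ratios match the request exactly (dot:O style 1:17)
  lens <- c(17000L, 34000L, 1000L)
  g <- make_ancestral_genome(3L, lens, c(5L, 8L, 0L), seed = 7)
  expect_identical(vapply(g$chromosomes, `[[`, 0L, "length"),
                   setNames(lens, paste0("chr", 1:3)))
  expect_silent(validate_marker_genome(g))

  # infeasible packing errors out
  expect_error(make_ancestral_genome(1L, 1000L, 10L, seed = 1,
                                     marker_length = 200L),
               "cannot fit")
})

test_that("identical seeds give byte-identical FASTA/GFF3 output", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- make_ancestral_genome(2L, c(20000L, 8000L), 6L, seed = 42)
  g2 <- make_ancestral_genome(2L, c(20000L, 8000L), 6L, seed = 42)
  write_genome(g1, d1); write_genome(g2, d2)
  for (f in c("ancestor.fasta", "ancestor.gff3"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("a straight inversion reverses markers and is an involution", {
  g <- toy_genome("t", length = 2000L, starts = c(100, 400, 700),
                  strands = c("+", "+", "+"), ids = c("a", "b", "c"),
                  with_sequence = TRUE, seed = 3)
  ev <- inversion_event("e1", "chr1", 50L, 900L)
  g2 <- apply_inversion(g, ev)
  m2 <- g2$chromosomes[[1]]$markers
  expect_identical(m2$id, c("c", "b", "a"))
  expect_identical(m2$strand, c("-", "-", "-"))
  expect_equal(g2$chromosomes[[1]]$length, 2000L)
  # involution: same breakpoints again restores the genome exactly
  g3 <- apply_inversion(g2, ev)
  attr(g3, "realized") <- NULL
  expect_identical(g3$chromosomes[[1]]$sequence,
                   g$chromosomes[[1]]$sequence)
  expect_identical(g3$chromosomes[[1]]$markers,
                   g$chromosomes[[1]]$markers)
})

test_that("staggered cuts duplicate the stagger fragments in inverted orientation", {
  set.seed(11)
  L <- 5000L
  g <- toy_genome("t", length = L, with_sequence = TRUE, seed = 11)
  s0 <- g$chromosomes[[1]]$sequence
  l <- 1000L; r <- 4000L; a <- 300L; b <- 300L
  ev <- inversion_event("e1", "chr1", l, r, mechanism = "staggered",
                        offset_left = a, offset_right = b)
  g2 <- apply_inversion(g, ev)
  s2 <- g2$chromosomes[[1]]$sequence
  expect_equal(nchar(s2), L + a + b)
  A <- substr(s0, l + 1, l + a)
  M <- substr(s0, l + a + 1, r - b)
  B <- substr(s0, r - b + 1, r)
  expect_identical(s2, paste0(substr(s0, 1, l), A, revcomp(B), revcomp(M),
                              revcomp(A), B,
                              substr(s0, r + 1, L)))
  # each flank carries an inverted duplicate of the opposite flank's
  # stagger fragment
  left_flank <- substr(s2, l + 1, l + a + b)
  right_flank <- substr(s2, nchar(s2) - (L - r) - a - b + 1,
                        nchar(s2) - (L - r))
  expect_identical(substr(left_flank, 1, a),
                   revcomp(substr(right_flank, 1, a)))
  expect_identical(attr(g2, "realized"), c(left = l, right = r + a + b))
})

test_that("ectopic events require their repeat pair and keep it on both flanks", {
  g <- toy_genome("t", length = 20000L, with_sequence = TRUE, seed = 5)
  ev <- inversion_event("e1", "chr1", 2000L, 15000L, mechanism = "ectopic",
                        repeat_id = "rp1")
  expect_error(apply_inversion(g, ev), "no repeat pair")
  g <- place_inverted_repeat_pair(g, "chr1", 2000L, 15000L, 400L, "rp1",
                                  seed = 9)
  s_anc <- g$chromosomes[[1]]$sequence
  unit <- substr(s_anc, 2001, 2400)
  expect_identical(substr(s_anc, 15001, 15400), revcomp(unit))
  g2 <- apply_inversion(g, ev)
  s_der <- g2$chromosomes[[1]]$sequence
  expect_equal(nchar(s_der), 20000L)  # no length change
  # the pair is present at the flanks of both arrangements
  expect_identical(substr(s_der, 2001, 2400), unit)
  expect_identical(substr(s_der, 15001, 15400), revcomp(unit))
})

test_that("marker content and length bookkeeping hold across mechanisms", {
  for (seed in 1:5) {
    g <- make_ancestral_genome(1L, 40000L, 15L, seed = seed,
                               chrom_names = "c1", marker_length = 300L)
    ids0 <- sort(marker_table(g)$id)
    l <- snap_intergenic(g, "c1", 9000, clearance = 300)
    r <- snap_intergenic(g, "c1", 31000, clearance = 300)
    for (mech in c("straight", "staggered")) {
      off <- if (mech == "staggered") 200L else 0L
      ev <- inversion_event("e", "c1", l, r, mechanism = mech,
                            offset_left = off, offset_right = off)
      g2 <- apply_inversion(g, ev)
      expect_identical(sort(marker_table(g2)$id), ids0)
      expect_equal(g2$chromosomes[[1]]$length, 40000L + 2L * off)
    }
  }
  # offsets larger than the segment are rejected
  g <- make_ancestral_genome(1L, 10000L, 0L, seed = 1, chrom_names = "c1")
  expect_error(apply_inversion(g, inversion_event(
    "e", "c1", 4000L, 4300L, mechanism = "staggered",
    offset_left = 200L, offset_right = 200L)), "exceed")
})

test_that("breakpoints inside markers are rejected unless disruption is simulated", {
  g <- toy_genome("t", length = 3000L, starts = c(500, 1500),
                  ids = c("a", "b"), with_sequence = TRUE, seed = 2)
  ev <- inversion_event("e", "chr1", 550L, 2500L)
  expect_error(apply_inversion(g, ev), "inside a marker")
  g2 <- simulate_gene_disruption(g, ev)
  m <- g2$chromosomes[[1]]$markers
  expect_true(all(c("a.5p", "a.3p") %in% m$id))
})

test_that("evolving a subgroup with no events leaves all tips identical", {
  g <- make_ancestral_genome(2L, c(20000L, 10000L), 5L, seed = 8)
  tree <- subgroup_tree()
  evo <- evolve_subgroup(g, tree, list(), seed = 1)
  for (tx in names(evo$genomes))
    expect_identical(marker_table(evo$genomes[[tx]]), marker_table(g))
  expect_equal(nrow(evo$truth$events), 0L)
})

test_that("the template scenario realizes the expected branch partition", {
  cfg <- default_config()
  anc <- make_ancestral_genome(6L, cfg$simulate$chrom_lengths,
                               cfg$simulate$markers_per_chrom,
                               seed = cfg$seed,
                               chrom_names = cfg$simulate$chrom_names,
                               marker_length = cfg$simulate$marker_length)
  events <- template_events(anc, subgroup_tree())
  ev <- do.call(rbind, lapply(events, function(e)
    data.frame(chrom = e$chrom, branch = e$branch, state = e$state,
               mech = e$mechanism)))
  # partition: 6 on A, 3 fixed autosomal, 2 polymorphic, 1 on guanche
  expect_equal(sum(ev$chrom == "A"), 6L)
  expect_equal(sum(ev$chrom != "A" & ev$state == "fixed" &
                     ev$branch != "guanche"), 3L)
  expect_equal(sum(ev$state == "polymorphic"), 2L)
  expect_equal(sum(ev$branch == "guanche"), 1L)
  # staggered duplication offsets bracket the observed lengths
  offs <- vapply(events, `[[`, 0L, "offset_left")
  expect_setequal(offs[offs > 0], c(689L, 1007L, 513L, 538L))
})

test_that("truth-table coordinates track later rearrangements on a lineage", {
  # two stacked events on one branch: a staggered one proximal of an
  # earlier inversion shifts the earlier realized coordinates
  g <- make_ancestral_genome(1L, 60000L, 20L, seed = 13, chrom_names = "c1",
                             marker_length = 300L)
  l1 <- snap_intergenic(g, "c1", 40000, 100)
  r1 <- snap_intergenic(g, "c1", 55000, 100)
  tree <- subgroup_tree()
  e1 <- inversion_event("late", "c1", l1, r1, branch = "subobscura")
  g_after <- apply_inversion(g, e1)
  l2 <- snap_intergenic(g_after, "c1", 5000, 400)
  r2 <- snap_intergenic(g_after, "c1", 20000, 400)
  e2 <- inversion_event("early", "c1", l2, r2, mechanism = "staggered",
                        offset_left = 300L, offset_right = 300L,
                        branch = "subobscura")
  evo <- evolve_subgroup(g, tree, list(e1, e2), seed = 1)
  rz <- evo$truth$realized
  rz <- rz[rz$taxon == "subobscura", ]
  # the later staggered event grew the genome by 600 bp upstream of e1
  expect_equal(rz$left[rz$event_id == "late"], l1 + 600L)
  expect_equal(rz$right[rz$event_id == "late"], r1 + 600L)
  # and the derived genome reflects the growth
  expect_equal(evo$genomes$subobscura$chromosomes[[1]]$length, 60600L)
})

test_that("uniform repeat placement is statistically uniform", {
  model <- repeat_model(data.frame(
    name = "nonLTR", count = 150L, unit_length = 100L,
    pericentromeric_enrichment = 1, telomeric_gradient_slope = 0))
  g <- make_ancestral_genome(1L, 200000L, 0L, seed = 1, chrom_names = "c1",
                             with_sequence = FALSE)
  not_rejected <- 0L
  for (s in 1:100) {
    bed <- place_repeats(g, model, seed = s)
    mids <- (bed$start + bed$end) / 2
    p <- suppressWarnings(ks.test(mids / 200000, "punif")$p.value)
    if (p > 0.01) not_rejected <- not_rejected + 1L
  }
  expect_gte(not_rejected, 95L)
  # zero-count classes yield zero records
  model0 <- repeat_model(data.frame(
    name = "satellite", count = 0L, unit_length = 290L,
    pericentromeric_enrichment = 2, telomeric_gradient_slope = 0))
  expect_equal(nrow(place_repeats(g, model0, seed = 1)), 0L)
})

test_that("a telomeric gradient is recovered by the density regression", {
  # slope chosen to give a strong relative gradient over a 250 kb
  # chromosome, matching the pronounced telomere-ward trends the windowed
  # regressions are meant to pick up
  model <- repeat_model(data.frame(
    name = "microsatellite", count = 200L, unit_length = 40L,
    pericentromeric_enrichment = 1, telomeric_gradient_slope = 8))
  g <- make_ancestral_genome(1L, 250000L, 0L, seed = 1, chrom_names = "c1",
                             with_sequence = FALSE)
  hits <- 0L
  for (s in 1:100) {
    bed <- place_repeats(g, model, seed = s)
    wp <- window_density(bed, 250000, window = 25000, step = 12500)
    fit <- linreg_density(wp$windows$mid, wp$density)
    if (fit$slope > 0) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
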
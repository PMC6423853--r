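test_that("polarity follows the outgroup match", {
  out <- c("m1", "m2", "m3", "m4", "m5", "m6")
  a <- out
  b <- c("m1", "m2", "m3", "m6", "m5", "m4")
  pc <- infer_polarity(a, b, out, taxon_a = "A", taxon_b = "B")
  expect_equal(pc$status, "resolved")
  expect_equal(pc$ancestral_taxon, "A")
  expect_equal(pc$derived_taxon, "B")

  expect_equal(infer_polarity(a, a, out)$status, "no_inversion")
  # too few shared markers: undetermined, never a guess
  expect_equal(infer_polarity(a[1:4], b[1:4], out[1:4])$status,
               "undetermined")
})

test_that("the subobscura A_h4 marker orders polarize against melanogaster", {
  # breakpoint-flanking windows; the outgroup order spans both breakpoint
  # regions of the chromosome
  melano <- c("CG2076", "CG2081", "CG18085", "CG15203", "CG1537", "CG1545",
              "CG32677", "CG43347", "CG1628", "CG15302", "CG32683", "CG2096")
  guanche_prox <- c("CG2076", "CG2081", "CG18085",
                    "CG15203", "CG1537", "CG1545")
  subobs_prox <- c("CG2076", "CG2081", "CG18085",
                   "CG1628", "CG43347", "CG32677")
  pc <- infer_polarity(subobs_prox, guanche_prox, melano,
                       taxon_a = "subobscura", taxon_b = "guanche",
                       inversion_id = "A_h4")
  expect_equal(pc$status, "resolved")
  expect_equal(pc$ancestral_taxon, "guanche")
  expect_equal(pc$derived_taxon, "subobscura")

  # the distal windows polarize the same way
  guanche_dist <- c("CG32677", "CG43347", "CG1628",
                    "CG15302", "CG32683", "CG2096")
  subobs_dist <- c("CG1545", "CG1537", "CG15203",
                   "CG15302", "CG32683", "CG2096")
  pc2 <- infer_polarity(subobs_dist, guanche_dist, melano,
                        taxon_a = "subobscura", taxon_b = "guanche")
  expect_equal(pc2$derived_taxon, "subobscura")
})

test_that("reversal distance matches its defining examples", {
  expect_equal(reversal_distance(c(1L, 2L, 3L)), 0L)
  expect_equal(reversal_distance(c(-2L, -1L)), 1L)
  expect_equal(reversal_distance(c(2L, 1L)), 3L)
  expect_equal(reversal_distance(integer(0)), 0L)
  expect_equal(reversal_distance(signed_permutation(c(-1L))), 1L)
})

test_that("reversal distance is symmetric in the signed inverse", {
  signed_inverse <- function(e) {
    q <- integer(length(e))
    q[abs(e)] <- sign(e) * seq_along(e)
    q
  }
  # exhaustively for n <= 4 against the independent oracle
  for (n in 2:4) {
    for (e in all_signed_perms(n)) {
      expect_equal(reversal_distance_bfs(e),
                   reversal_distance_bfs(signed_inverse(e)))
    }
  }
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(2:7, 1L)
    e <- random_signed_perm(n)
    expect_equal(reversal_distance(e),
                 reversal_distance(signed_inverse(e)))
  }
})

test_that("optimal scenarios sort to the identity in oracle-verified length", {
  expect_equal(sort_by_reversals(c(1L, 2L))$distance, 0L)
  sc1 <- sort_by_reversals(c(-1L))
  expect_equal(sc1$distance, 1L)
  expect_equal(sc1$reversals[[1L]], c(start = 1L, end = 1L))

  set.seed(6)
  for (rep in 1:20) {
    n <- sample(2:7, 1L)
    e <- random_signed_perm(n)
    sc <- sort_by_reversals(e)
    expect_equal(sc$distance, reversal_distance_bfs(e))
    x <- e
    for (r in sc$reversals) x <- apply_reversal(x, r[["start"]], r[["end"]])
    expect_identical(x, seq_len(n))
  }
})

test_that("branch assignment follows single-origin parsimony", {
  tree <- subgroup_tree()
  ts <- data.frame(inversion_id = "E_g1", taxon = "guanche",
                   state = "fixed")
  br <- assign_to_branches(ts, tree)
  expect_equal(br$branch, "guanche")
  expect_equal(br$state_subobscura, "absent")

  # O_ms pattern: fixed in madeirensis, extinct ancestral in subobscura
  # (replaced by nested derivatives), absent in guanche
  ts2 <- data.frame(
    inversion_id = "O_ms",
    taxon = c("madeirensis", "subobscura"),
    state = c("fixed", "extinct_ancestral"))
  br2 <- assign_to_branches(ts2, tree)
  expect_equal(br2$branch, "ms")
  expect_equal(br2$state_subobscura, "extinct_ancestral")
  expect_equal(br2$state_madeirensis, "fixed")

  # a non-clade carrier pattern is impossible under a single origin
  ts3 <- data.frame(inversion_id = "X",
                    taxon = c("guanche", "madeirensis"),
                    state = c("fixed", "fixed"))
  expect_error(assign_to_branches(ts3, tree), "single origin")
})

test_that("fixation rates and their display match the reported arithmetic", {
  expect_equal(signif(fixation_rate(6, 1.72), 2), 3.5)
  expect_equal(signif(fixation_rate(3, 4 * 1.72), 2), 0.44)
  expect_equal(fixation_rate(0, 2), 0)
  expect_error(fixation_rate(3, 0), "> 0")
  # rate times exposure returns the count exactly before rounding
  for (k in c(0, 3, 11)) expect_equal(fixation_rate(k, 1.72) * 1.72, k)
})

test_that("the exact conditional rate test reproduces binomial tails", {
  rc <- rate_ratio_test(10, 1, 1, 1)
  expect_equal(rc$p_one_sided, 12 / 2048)
  rc2 <- rate_ratio_test(4, 1, 4, 1)
  expect_equal(rc2$p_two_sided, 1)
  rc3 <- rate_ratio_test(2, 1, 0, 1)
  expect_equal(rc3$p_one_sided, 0.25)
  expect_equal(rate_ratio_test(0, 1, 0, 1)$p_two_sided, 1)
  expect_equal(rc$rate1 / rc$rate2, rc$ratio)
})
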
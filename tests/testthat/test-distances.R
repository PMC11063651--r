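test_that("relative displacement distance reproduces the worked example", {
  ex <- example_alignments()
  expect_equal(relative_displacement_distance(ex$a1, ex$a2), 12 / 54)
  expect_equal(relative_displacement_distance(ex$a2, ex$a1), 12 / 54)
  expect_equal(relative_displacement_distance(ex$a1, ex$a1), 0)
  # position maps behind it
  expect_equal(escore:::position_index_map(ex$a1),
               list(p = c(2L, 3L, 4L), q = c(1L, 2L, 4L)))
  expect_equal(escore:::position_index_map(ex$a2),
               list(p = c(1L, 2L, 3L), q = c(1L, 3L, 4L)))
})

test_that("closest context distance reproduces the worked example", {
  ex <- example_alignments()
  expect_equal(closest_context_distance(ex$a1, ex$a2), 11 / 36)
  expect_equal(closest_context_distance(ex$a2, ex$a1), 11 / 36)
  cc <- closest_context_contributions(ex$a1, ex$a2)
  # printed per-residue contributions from alignment 1
  expect_equal(cc$d_p[1, 1], 1)  # letter case, nearest same letter
  expect_equal(cc$d_p[2, 1], 1)  # gap case, preceding letter counts
  expect_equal(cc$d_p[3, 1], 0)  # same opposite residue in both
  expect_equal(cc$d_q[3, 1], 1)  # reversed-range letter count
  expect_equal(sum(cc$d_p) + sum(cc$d_q), 11)
  expect_equal(closest_context_distance(ex$a1, ex$a1), 0)
})

test_that("homology sets follow the three gap treatments", {
  ex <- example_alignments()
  hp <- homology_sets(ex$a1, "pos")
  expect_equal(hp$p[[1]], "N")
  expect_equal(hp$p[[2]], "g2_2")
  hs <- homology_sets(ex$a1, "seq")
  expect_equal(hs$p[[2]], "g2")
  expect_equal(hs$q[[1]], "g1")
  hssp <- homology_sets(ex$a1, "ssp")
  expect_length(hssp$p[[2]], 0L)     # gap column: empty set
  expect_equal(hssp$q[[2]], "R")
  # gap-free alignment: every set is the opposite residue, all variants
  gapless <- pairwise_alignment("RKD", "DNN")
  for (v in c("ssp", "seq", "pos"))
    expect_equal(unlist(homology_sets(gapless, v)$p), c("D", "N", "N"))
})

test_that("homology-set distances match hand enumeration on the example", {
  ex <- example_alignments()
  # hand enumeration over the 12 homology sets of the two alignments:
  # intersections 1, unions 7 for ssp; 4 of 6 seq terms differ; 5 of 6 pos
  expect_equal(d_ssp(ex$a1, ex$a2), 6 / 7)
  expect_equal(d_seq(ex$a1, ex$a2), 4 / 6)
  expect_equal(d_pos(ex$a1, ex$a2), 5 / 6)
  for (f in list(d_ssp, d_seq, d_pos)) expect_equal(f(ex$a1, ex$a1), 0)
  # fully disjoint residue pairings drive d_ssp to 1
  x1 <- pairwise_alignment("RK", "DN")
  x2 <- pairwise_alignment("-RK", "DN-")
  expect_equal(d_ssp(x1, x2), 1)
})

test_that("induced pairwise alignments drop double-gap columns only", {
  m <- msa(c("a", "b"), c("-RKD", "DN-N"))
  a <- induced_pairwise(m, 1, 2)
  expect_equal(a$p_row, "-RKD")
  expect_equal(a$q_row, "DN-N")

  m2 <- msa(c("a", "b"), c("A--C", "A-GC"))
  a2 <- induced_pairwise(m2, 1, 2)
  expect_equal(a2$p_row, "A-C")
  expect_equal(a2$q_row, "AGC")

  # identical rows induce a gap-free self alignment
  m3 <- msa(c("a", "b"), c("AR-N", "AR-N"))
  a3 <- induced_pairwise(m3, 1, 2)
  expect_equal(a3$p_row, "ARN")
  expect_equal(a3$q_row, "ARN")
  expect_error(induced_pairwise(m3, 2, 2), "differ")
  # an all-gap row can never enter: the MSA invariant rejects it upstream
  expect_error(msa(c("a", "b", "c"), c("AR", "A-", "--")), "empty")
})

test_that("all five distances satisfy the metric axioms on random pairs", {
  set.seed(71)
  n_pairs <- 0L
  while (n_pairs < 120L) {
    p <- random_protein(sample(1:5, 1), id = "p")
    q <- random_protein(sample(1:5, 1), id = "q")
    a1 <- random_alignment(p, q)
    a2 <- random_alignment(p, q)
    d12 <- alignment_distances(a1, a2)
    d21 <- alignment_distances(a2, a1)
    dself <- alignment_distances(a1, a1)
    expect_equal(d12, d21)
    expect_equal(unname(dself), rep(0, 5))
    expect_true(all(d12 >= 0 & d12 <= 1))

    # per-term bound of the displacement distance
    diff <- abs(escore:::displacement_profile(a1) -
                  escore:::displacement_profile(a2))
    expect_true(all(diff <= length(p) + length(q)))
    # contribution bounds of the closest context distance
    cc <- closest_context_contributions(a1, a2)
    expect_true(all(cc$d_p <= length(q)))
    expect_true(all(cc$d_q <= length(p)))
    n_pairs <- n_pairs + 1L
  }
})

test_that("distances refuse alignments of different sequence pairs", {
  a1 <- pairwise_alignment("RKD", "DNN")
  a2 <- pairwise_alignment("RKN", "DNN")
  for (f in list(relative_displacement_distance, closest_context_distance,
                 d_ssp, d_seq, d_pos))
    expect_error(f(a1, a2), "same sequences")
})
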
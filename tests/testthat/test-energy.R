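test_that("forced-helix energies match hand-computed decompositions", {
  em <- energy_model()
  # GGGG-CCCC: hairpin(6) 5.40 + 3 GC/GC stacks (-3.30 each) + closing-GC
  # term (-0.50); no terminal penalties
  expect_equal(forced_helix_energy("GGGG-CCCC", p1ex_helix(), em), -5.00)
  # master AGGU/ACAU: A.U + G.A(mismatch) + G.C + U.A(closing);
  # 5.40 + 0 + 0 + stack(GC->UA) -2.20 + penalty 7.10
  # + terminal A.U at both ends of the isolated A.U segment (2 x 0.50)
  # + terminal A.U at the open end of the GC-UA segment (0.50)
  expect_equal(forced_helix_energy(MASTER_GENOTYPE, p1ex_helix(), em), 11.80)
  # four forced A.A pairs: hairpin + 4 penalties, no stacks
  expect_equal(forced_helix_energy("AAAA-AAAA", p1ex_helix(), em),
               5.40 + 4 * 7.10)
  # AUAU/AUAU: alternating A.U helix
  # 5.40 + stacks (AU|UA -1.10, UA|AU -1.30, AU|UA -1.10) + 2 terminal A.U
  expect_equal(forced_helix_energy("ATAT-ATAT", p1ex_helix(), em),
               5.40 - 1.10 - 1.30 - 1.10 + 1.00)
  expect_error(forced_helix_energy("AGGT-ACAX"), "invalid genotype")
})

test_that("GC helices are more stable than AT helices", {
  expect_lt(forced_helix_energy("GGGG-CCCC"), forced_helix_energy("AAAA-TTTT"))
  # forced mismatches are less stable than any fully paired helix
  expect_gt(forced_helix_energy("AAAA-AAAA"), forced_helix_energy("AAAA-TTTT"))
})

test_that("energy is additive over stacks when a pair is inserted", {
  em <- energy_model()
  # turning the closing rung of GGGA-ACCC (G5.A18 mismatch) into U5.A18
  # appends a U.A pair to the GC helix: removes one mismatch penalty, adds
  # the GC->UA stack, and the new U.A closing rung carries a terminal A.U
  e_mm <- forced_helix_energy("GGGA-ACCC", model = em)
  e_wc <- forced_helix_energy("GGGT-ACCC", model = em)
  stack_gc_ua <- -2.20
  expect_equal(e_wc - e_mm, -7.10 + stack_gc_ua + 0.50)
})

test_that("unique-energy spectra have the reference counts", {
  g <- enumerate_genotypes()
  sp1 <- unique_energy_spectrum(g, p1ex_helix())
  expect_identical(nrow(sp1), 211L)
  expect_identical(sum(sp1$n), 65536L)
  sp10 <- unique_energy_spectrum(g, p10_helix())
  expect_identical(nrow(sp10), 21L)
  expect_identical(sum(sp10$n), 65536L)
  # over the 4^4 right-half genotypes only (left fixed), still 21 values
  right <- paste0("AGGT", enumerate_genotypes(4, 4))
  sp10b <- unique_energy_spectrum(right, p10_helix())
  expect_identical(nrow(sp10b), 21L)
  expect_identical(sum(sp10b$n), 256L)
  # single genotype: one value
  expect_identical(nrow(unique_energy_spectrum(MASTER_GENOTYPE)), 1L)
})

test_that("stability rank bins order by stability and respect ties", {
  # constant energies: everything in bin 1
  expect_identical(unique(stability_rank_bins(rep(1.5, 10), 4)), 1L)
  # -1 < -3 < -5 in stability; ranks/bins follow
  b <- stability_rank_bins(c(-5, -3, -1), 3)
  expect_identical(as.integer(b), c(3L, 2L, 1L))
  # identity binning when n_bins >= number of unique values
  g <- enumerate_genotypes()
  e10 <- forced_helix_energy(g, p10_helix())
  b21 <- stability_rank_bins(e10, 21)
  expect_identical(max(b21), 21L)
  expect_identical(as.integer(b21), as.integer(attr(b21, "rank")))
  # ties always share a bin
  b10 <- stability_rank_bins(e10, 10)
  expect_true(all(tapply(b10, round(e10 * 100), function(x) length(unique(x))) == 1L))
})

test_that("landscape surface reports medians and flags empty cells", {
  f <- rep(1, 100)
  b1 <- rep(1:2, each = 50)
  b2 <- rep(1:2, 50)
  s <- landscape_surface(f, b1, b2)
  expect_true(all(s == 1))
  # single genotype: one populated cell, rest NA
  s1 <- landscape_surface(2.5, 1L, 1L)
  expect_identical(dim(s1), c(1L, 1L))
  expect_identical(s1[1, 1], 2.5)
  # empty cells are NA, not zero
  s2 <- landscape_surface(c(1, 2), c(1L, 3L), c(1L, 2L))
  expect_true(is.na(s2[2, 1]))
  expect_identical(attr(s2, "n")[2, 1], 0L)
})

test_that("two-state landscape has the documented shape", {
  tl <- true_landscape()  # sigma noise off (no seed)
  # master in the top decile of fitness
  expect_identical(tl$w[tl$genotype == "AGGT-ACAT"], 1)
  expect_gte(mean(tl$w < 1), 0.9)
  # C2/C21 factor is exactly delta
  g_cc <- "CGGT-ACAC"
  g_ref <- "AGGT-ACAA"  # same energies not required; test the factor directly
  expect_identical(tl$geom[tl$genotype == gt_format(g_cc)], 0.1)
  expect_identical(tl$geom[tl$genotype == gt_format(g_ref)], 1)
  # 37C raises the band ceiling: stable genotypes are fitter at 37C
  tl37 <- true_landscape(temperature = "37C")
  stable <- tl$dg_p1ex <= -4
  expect_gt(median(tl37$w[stable] / tl$w[stable]), 1)
})
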
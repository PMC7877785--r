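test_that("enumeration is complete, distinct and lexicographic", {
  g1 <- enumerate_genotypes(1, 4)
  expect_identical(g1, c("A", "C", "G", "T"))
  g2 <- enumerate_genotypes(2, 4)
  expect_length(g2, 16L)
  expect_identical(g2[1], "AA")
  expect_identical(g2[16], "TT")
  expect_identical(g2, sort(g2))

  g8 <- enumerate_genotypes()
  expect_length(g8, 65536L)
  expect_false(anyDuplicated(g8) > 0)
  expect_error(enumerate_genotypes(13), "guard")
})

test_that("genotype parsing and formatting round-trip", {
  expect_identical(gt_parse("AGGT-ACAT"), "AGGTACAT")
  expect_identical(gt_parse("agguacau"), "AGGTACAT")
  expect_identical(gt_format("AGGTACAT"), "AGGT-ACAT")
  expect_identical(gt_format("AGGTACAT", rna = TRUE), "AGGU-ACAU")
  expect_error(gt_parse("AGGT-ACA"), "invalid genotype")
  expect_error(gt_parse("AGGT-ACAX"), "invalid genotype")
})

test_that("hamming distance is a metric with the expected values", {
  expect_identical(hamming("AGGT-ACAT", "AGGT-ACAT"), 0L)
  expect_identical(hamming("AGGT-ACAT", "AGGT-ACAC"), 1L)
  # master vs its mirror differ at every site
  expect_identical(hamming("AGGT-ACAT", "TACA-TGGA"), 8L)

  set.seed(42)
  g <- enumerate_genotypes()
  for (k in 1:200) {
    tri <- sample(g, 3)
    dab <- hamming(tri[1], tri[2])
    dba <- hamming(tri[2], tri[1])
    expect_identical(dab, dba)
    expect_lte(hamming(tri[1], tri[3]), dab + hamming(tri[2], tri[3]))
    expect_identical(dab == 0L, tri[1] == tri[2])
  }
})

test_that("distance classes around any reference have size C(8,d) 3^d", {
  g <- enumerate_genotypes()
  for (ref in c(MASTER_GENOTYPE, "CCCC-GGGG")) {
    tab <- table(hamming(g, ref))
    expect_identical(as.integer(tab), as.integer(choose(8, 0:8) * 3^(0:8)))
  }
})

test_that("mirror is an involution that preserves distances", {
  expect_identical(mirror("AAAG-CTTT"), "TTTCGAAA")  # the canonical example
  expect_identical(mirror("AGGT-ACAT"), "TACATGGA")
  set.seed(7)
  g <- sample(enumerate_genotypes(), 500)
  expect_identical(mirror(mirror(g)), gt_parse(g))
  h <- sample(g)
  expect_identical(hamming(mirror(g), mirror(h)), hamming(g, h))
})

test_that("pair profiles classify strong/weak/wobble/unpaired correctly", {
  pp <- pair_profile(MASTER_GENOTYPE)
  expect_identical(pp[, c("strong", "weak", "wobble", "unpaired")],
                   data.frame(strong = 1L, weak = 2L, wobble = 0L,
                              unpaired = 1L))
  expect_identical(pair_profile("GGGG-CCCC")$strong, 4L)
  # master with A20C forms a fourth pair
  a20c <- substitute_site(MASTER_GENOTYPE, 20, "C")
  pp2 <- pair_profile(a20c)
  expect_identical(c(pp2$strong, pp2$weak, pp2$unpaired), c(2L, 2L, 0L))
  # rows always sum to the number of scheme pairs
  set.seed(1)
  g <- sample(enumerate_genotypes(), 200)
  pp3 <- pair_profile(g)
  expect_true(all(pp3$strong + pp3$weak + pp3$wobble + pp3$unpaired == 4L))
})

test_that("wobble policy flag reassigns G.T pairs", {
  g <- "GGGT-ACCT"  # G2.T21 wobble, G3.C20 strong, G4.C19 strong, T5.A18 weak
  sep <- pair_profile(g, p1ex_scheme("separate_class"))
  expect_identical(c(sep$strong, sep$weak, sep$wobble, sep$unpaired),
                   c(2L, 1L, 1L, 0L))
  weak <- pair_profile(g, p1ex_scheme("count_as_weak"))
  expect_identical(c(weak$weak, weak$wobble), c(2L, 0L))
  excl <- pair_profile(g, p1ex_scheme("exclude"))
  expect_identical(c(excl$wobble, excl$unpaired), c(0L, 1L))
})

test_that("exactly G3T and A20C complete the master P1ex helix", {
  fpm <- full_pairing_mutants(MASTER_GENOTYPE)
  expect_setequal(fpm$mutation, c("G3T", "A20C"))
  expect_false(attr(fpm, "already_paired"))

  done <- full_pairing_mutants("GGGG-CCCC")
  expect_identical(nrow(done), 0L)
  expect_true(attr(done, "already_paired"))

  # all-weak helix: already fully paired, and every substitution breaks it
  none <- full_pairing_mutants("ATAT-ATAT")
  expect_identical(nrow(none), 0L)
  expect_true(attr(none, "already_paired"))
  # a genuinely incompletable genotype (two mismatched rungs)
  none2 <- full_pairing_mutants("AAGT-ACAA")
  expect_identical(nrow(none2), 0L)
  expect_false(attr(none2, "already_paired"))
})
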
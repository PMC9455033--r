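# Population-genetic summaries: frequencies, diversity indices, HWE.

smad5_counts <- c(AA = 256, AG = 150, GG = 27)
smad7_counts <- c(CC = 409, CT = 24)

test_that("tabulate_genotypes tallies, pools unordered pairs and tracks missing", {
  recs <- expand_counts(smad5_counts, "g.51537A>G")
  gc <- tabulate_genotypes(recs)
  expect_equal(unname(gc$counts[c("AA", "AG", "GG")]), c(256, 150, 27))
  expect_equal(gc$n, 433)
  expect_equal(gc$alleles, c("A", "G"))

  # unordered-pair symmetry: AG and GA are one class
  gc2 <- tabulate_genotypes(data.frame(genotype = c("AG", "GA")))
  expect_equal(unname(gc2$counts), 2)
  expect_equal(names(gc2$counts), "AG")

  # singleton
  gc3 <- tabulate_genotypes(data.frame(genotype = "AA"))
  expect_equal(unname(gc3$counts), 1)
  expect_equal(gc3$n, 1)

  # missing genotypes excluded from N but counted
  gc4 <- tabulate_genotypes(
    data.frame(genotype = c("AA", "./.", "", "AG", NA)))
  expect_equal(gc4$n, 2)
  expect_equal(gc4$n_missing, 3)
})

test_that("tabulate_genotypes errors name the offending row", {
  expect_error(tabulate_genotypes(data.frame(genotype = c("AA", "AZ"))),
               "row 2.*unknown allele")
  expect_error(tabulate_genotypes(data.frame(genotype = c("./.", ""))),
               "zero non-missing")
  expect_error(
    tabulate_genotypes(data.frame(locus = c("l1", "l2"),
                                  genotype = c("AA", "AA"))),
    "2 loci")
})

test_that("genotype and allele frequencies match the flock tallies", {
  gc5 <- genotype_counts("g.51537A>G", smad5_counts)
  gf <- genotype_frequencies(gc5)
  expect_equal(sum(gf), 1)
  expect_equal(unname(round(gf[c("AA", "AG", "GG")], 2)),
               c(0.59, 0.35, 0.06))

  af <- allele_frequencies(gc5)
  expect_equal(sum(af$freqs), 1)
  expect_equal(unname(af$freqs["A"]), 662 / 866)
  expect_equal(unname(round(af$freqs, 2)), c(0.76, 0.24))

  gc7 <- genotype_counts("g.319C>T", smad7_counts)
  expect_equal(unname(round(genotype_frequencies(gc7), 2)), c(0.94, 0.06))
  af7 <- allele_frequencies(gc7)
  expect_equal(unname(af7$freqs["C"]), 842 / 866)
  expect_equal(unname(round(af7$freqs, 2)), c(0.97, 0.03))

  # monomorphic
  expect_equal(unname(genotype_frequencies(
    genotype_counts("m", c(AA = 10)))), 1)
  expect_equal(unname(allele_frequencies(
    genotype_counts("m", c(AA = 5)))$freqs), 1)
})

test_that("diversity indices reproduce the reported table values", {
  di5 <- diversity_indices(allele_frequencies(
    genotype_counts("g.51537A>G", smad5_counts)))
  expect_equal(round(di5$ho, 2), 0.64)
  expect_equal(round(di5$he, 2), 0.36)
  expect_equal(round(di5$ne, 2), 1.56)
  expect_equal(round(di5$pic, 2), 0.30)
  expect_equal(di5$pic_class, "moderate")

  di7 <- diversity_indices(allele_frequencies(
    genotype_counts("g.319C>T", smad7_counts)))
  expect_equal(round(c(di7$ho, di7$he, di7$ne, di7$pic), 2),
               c(0.95, 0.05, 1.06, 0.05))
  expect_equal(di7$pic_class, "low")

  # hand evaluation of Botstein's formula at p = q = 0.5
  di_half <- diversity_indices(c(A = 0.5, B = 0.5))
  expect_equal(di_half$pic, 0.375)
  expect_equal(di_half$ne, 2)

  # monomorphic limit
  dim1 <- diversity_indices(c(A = 1))
  expect_equal(c(dim1$ho, dim1$he, dim1$ne, dim1$pic), c(1, 0, 1, 0))
})

test_that("PIC boundaries fall in the moderate class", {
  expect_equal(ovigene:::pic_class(0.25), "moderate")
  expect_equal(ovigene:::pic_class(0.5), "moderate")
  expect_equal(ovigene:::pic_class(0.2499), "low")
  expect_equal(ovigene:::pic_class(0.5001), "high")
})

test_that("diversity identities hold over random allele-frequency simplexes", {
  set.seed(42)
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    p <- rgamma(k, 1)
    p <- p / sum(p)
    names(p) <- LETTERS[1:k]
    di <- diversity_indices(p)
    expect_identical(di$ho + di$he, 1)         # exact complement
    expect_equal(di$ne * di$ho, 1)             # Ne = 1/Ho
    expect_gte(di$ne, 1)
    expect_lte(di$ne, k + 1e-12)
    expect_gte(di$pic, 0)
    expect_lte(di$pic, di$he + 1e-12)          # PIC <= He
  }
})

test_that("HWE chi-square reproduces the reported test and hand calculations", {
  gc5 <- genotype_counts("g.51537A>G", smad5_counts)
  h <- hwe_chi_square(gc5)
  # independent arithmetic from the allele counts
  p <- 662 / 866
  q <- 1 - p
  e <- c(AA = 433 * p^2, AG = 2 * 433 * p * q, GG = 433 * q^2)
  expect_equal(h$expected[names(e)], e)
  expect_equal(h$chi2, sum((smad5_counts - e)^2 / e))
  expect_equal(round(h$chi2, 2), 0.63)
  expect_equal(h$df, 1)
  expect_equal(round(h$p_value, 2), 0.43)

  # observed at exact HW proportions: chi2 identically 0
  h0 <- hwe_chi_square(genotype_counts("hw", c(AA = 25, AG = 50, GG = 25)))
  expect_identical(h0$chi2, 0)
  expect_identical(h0$p_value, 1)
})

test_that("chi2 is zero whenever counts equal HW expectations from their own frequencies", {
  for (k in 1:9) {
    p <- k * 0.05 + 0.25
    n <- 400
    counts <- round(c(AA = n * p^2, AG = 2 * n * p * (1 - p),
                      GG = n * (1 - p)^2))
    expect_equal(sum(counts), n)  # construction yields exact HW integers
    h <- hwe_chi_square(genotype_counts("x", counts))
    expect_equal(h$chi2, 0)
  }
})

test_that("HWE warns on small expected classes and errors on degenerate input", {
  gc7 <- genotype_counts("g.319C>T", smad7_counts)
  expect_warning(h7 <- hwe_chi_square(gc7), "below 5.*TT")
  # unobserved TT class enters the expectation: E = (409.33, 23.33, 0.33)
  expect_equal(unname(round(h7$expected, 2)), c(409.33, 23.33, 0.33))
  expect_equal(round(h7$chi2, 2), 0.35)
  expect_equal(h7$df, 1)
  expect_equal(round(h7$p_value, 2), 0.55)

  expect_error(hwe_chi_square(genotype_counts("m", c(AA = 10))),
               "monomorphic")
})

test_that("popgen_summary lays out the per-locus report at table precision", {
  tab <- popgen_summary(genotype_counts("g.51537A>G", smad5_counts))
  expect_equal(tab$genotype_freq, c(0.59, 0.35, 0.06))
  expect_equal(tab$allele_freq[1:2], c(0.76, 0.24))
  expect_equal(tab$Ho[1], 0.64)
  expect_equal(tab$He[1], 0.36)
  expect_equal(tab$Ne[1], 1.56)
  expect_equal(tab$PIC[1], 0.30)
  expect_equal(tab$PIC_class[1], "moderate")
  expect_equal(tab$p_HWE[1], 0.43)

  # full precision when digits = NULL
  tab_full <- popgen_summary(genotype_counts("g.51537A>G", smad5_counts),
                             digits = NULL)
  expect_equal(tab_full$allele_freq[1], 662 / 866)
})
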
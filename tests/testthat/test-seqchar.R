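# cDNA characterization: ORF, translation, protein properties,
# identity matrices and neighbor-joining trees.

test_that("longest ORF detection handles canonical cases", {
  # minimal ORF
  orf <- find_longest_orf("ATGTAA")
  expect_true(orf$found)
  expect_equal(orf$nt_length, 6)
  expect_equal(orf$peptide, "M")

  # a 1398-nt ORF encodes 465 residues (stop translated and removed)
  cdna <- paste0("GC", "ATG", strrep("GCT", 464), "TAA",
                 strrep("C", 100))
  orf <- find_longest_orf(cdna)
  expect_equal(orf$nt_length, 1398)
  expect_equal(nchar(orf$peptide), 465)
  expect_equal(orf$nt_length / 3 - 1, nchar(orf$peptide))
  expect_equal(orf$end - orf$start, orf$nt_length)

  # no ORF is a result, not an exception
  res <- find_longest_orf("CCCCCCCCCCCC")
  expect_false(res$found)
  expect_equal(res$nt_length, 0)

  # ties broken by the 5'-most start
  two <- paste0("ATGTAA", "ATGTGA")
  expect_equal(find_longest_orf(two)$start, 0)
})

test_that("longest ORF agrees with the exhaustive oracle on random sequences", {
  set.seed(101)
  for (r in 1:250) {
    s <- random_dna(300)
    got <- find_longest_orf(s)
    want <- orf_oracle(s)
    expect_equal(got$nt_length, want$nt_length, info = s)
    if (want$nt_length > 0) {
      expect_equal(got$start, want$start, info = s)
      expect_equal(nchar(got$peptide), got$nt_length / 3 - 1)
    }
  }
})

test_that("reverse-complement scanning finds minus-strand frames when asked", {
  plus <- paste0("ATG", strrep("GAA", 20), "TAA")
  minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus)))
  expect_false(find_longest_orf(minus)$nt_length == 66)
  orf <- find_longest_orf(minus, revcomp = TRUE)
  expect_equal(orf$nt_length, 66)
  expect_equal(orf$strand, "-")
})

test_that("translation follows the standard code and rejects internal stops", {
  expect_equal(translate_orf("ATGGCCTAA"), "MA")
  expect_equal(translate_orf("ATGTAA"), "M")
  expect_error(translate_orf("ATGTAAGCCTAA"), "internal stop")
  expect_error(translate_orf("ATGGC"), "multiple of 3")
  # a 1284-nt ORF gives a 427-residue protein
  orf1284 <- paste0("ATG", strrep("GTT", 426), "TGA")
  expect_equal(nchar(orf1284), 1284)
  expect_equal(nchar(translate_orf(orf1284)), 427)
})

test_that("molecular weight uses average residue masses plus one water", {
  expect_equal(protein_mw("G"), 0.0750672, tolerance = 1e-7)
  expect_error(protein_mw(""), "empty")
  expect_error(protein_mw("GZ"), "unknown residue")

  # peptide-bond mass balance: mw(AB) = mw(A) + mw(B) - water
  set.seed(5)
  aas <- names(ovigene:::AA_RESIDUE_MASS)
  for (r in 1:20) {
    a <- paste(sample(aas, 5, TRUE), collapse = "")
    b <- paste(sample(aas, 7, TRUE), collapse = "")
    expect_equal(protein_mw(paste0(a, b)),
                 protein_mw(a) + protein_mw(b) - 18.0153 / 1000)
  }
})

test_that("molecular weight agrees with seqinr's mass table", {
  set.seed(6)
  aas <- names(ovigene:::AA_RESIDUE_MASS)
  for (r in 1:20) {
    pep <- paste(sample(aas, 50, TRUE), collapse = "")
    expect_equal(protein_mw(pep) * 1000,
                 seqinr::pmw(strsplit(pep, "")[[1]]),
                 tolerance = 1e-4)
  }
})

test_that("isoelectric point: closed forms, sign checks and grid oracle", {
  # no ionizable side chains: midpoint of the terminal pKa values
  expect_equal(isoelectric_point("GG"), (7.50 + 3.55) / 2, tolerance = 1e-3)
  # a lone lysine is basic
  expect_gt(isoelectric_point("K"), 7)
  # a lone aspartate is acidic
  expect_lt(isoelectric_point("D"), 7)

  set.seed(8)
  aas <- names(ovigene:::AA_RESIDUE_MASS)
  for (r in 1:25) {
    pep <- paste(sample(aas, sample(3:30, 1), TRUE), collapse = "")
    expect_equal(isoelectric_point(pep), pi_grid_oracle(pep),
                 tolerance = 0.01)
  }
})

test_that("characterize_cdna assembles the per-sequence report", {
  seqs <- c(geneA = paste0("AA", "ATG", strrep("GCT", 10), "TAA", "CC"),
            geneB = "CCCCCCCCC")
  tab <- characterize_cdna(seqs)
  expect_equal(tab$orf_len, c(36, 0))
  expect_equal(tab$aa_len, c(11, 0))
  expect_true(is.na(tab$mw_kda[2]))
  expect_equal(tab$aa_len[1], tab$orf_len[1] / 3 - 1)
})

test_that("identity matrix: exact cases and DP-oracle agreement", {
  im <- identity_matrix(c(a = "ACGT", b = "ACGT"))
  expect_equal(im$identity["a", "b"], 100)
  expect_equal(im$distance["a", "b"], 0)

  im2 <- identity_matrix(c(a = "ACGT", b = "ACGA"))
  expect_equal(im2$identity["a", "b"], 75)

  set.seed(12)
  for (r in 1:60) {
    s1 <- random_dna(sample(4:12, 1))
    s2 <- random_dna(sample(4:12, 1))
    im <- identity_matrix(c(x = s1, y = s2))
    oracle <- nw_oracle(s1, s2)
    # our identity must be attainable by an optimal-score alignment
    expect_true(any(abs(im$identity["x", "y"] / 100 - oracle$identities)
                    < 1e-9),
                info = paste(s1, s2))
    expect_equal(im$identity["x", "y"], im$identity["y", "x"])
  }
  expect_error(identity_matrix(c(a = "ACGT")), "at least two")
})

test_that("identity matrix works on protein sequences", {
  im <- identity_matrix(c(p1 = "MKVLAG", p2 = "MKVLAG", p3 = "MKVVAG"))
  expect_equal(im$identity["p1", "p2"], 100)
  expect_equal(im$identity["p1", "p3"], 100 * 5 / 6)
})

test_that("neighbor joining: three-taxon closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj <- nj_tree(d)
  tr <- nj$tree
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 0, B = 2, C = 4))
})

test_that("neighbor joining is exact on additive matrices and round-trips Newick", {
  set.seed(31)
  for (r in 1:25) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(tree)
    nj <- nj_tree(d)
    d_hat <- ape::cophenetic.phylo(nj$tree)[rownames(d), colnames(d)]
    expect_lt(max(abs(d_hat - d)), 1e-9)

    # writer/parser round trip preserves topology and branch lengths
    back <- read_newick(nj$newick)
    d_back <- ape::cophenetic.phylo(back)[rownames(d), colnames(d)]
    expect_lt(max(abs(d_back - d_hat)), 1e-10)
  }
})

test_that("neighbor joining rejects malformed matrices and clamps negatives", {
  d <- matrix(c(0, 1, 1, 0), 2)
  expect_error(nj_tree(d), "three taxa")
  d3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3)
  expect_error(nj_tree(d3), "symmetric")
  d4 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3)
  expect_error(nj_tree(d4), "non-negative")

  # near-degenerate input can imply a negative branch; it is clamped
  d5 <- matrix(c(0, 0.1, 0.5, 0.55,
                 0.1, 0, 0.45, 0.55,
                 0.5, 0.45, 0, 0.1,
                 0.55, 0.55, 0.1, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  nj <- nj_tree(d5)
  expect_true(all(nj$tree$edge.length >= 0))
})

test_that("a zero-distance homolog clusters with the query; the far taxon splits off", {
  # sheep-study-like identity pattern: query identical to sheep, far zebra
  id <- matrix(c(100, 100, 99, 64,
                 100, 100, 99, 64,
                 99, 99, 100, 65,
                 64, 64, 65, 100) / 1, 4,
               dimnames = list(c("query", "sheep", "yak", "zebra"),
                               c("query", "sheep", "yak", "zebra")))
  nj <- nj_tree(1 - id / 100)
  tr <- ape::root(nj$tree, "zebra", resolve.root = TRUE)
  # query and sheep form a cherry
  pair <- ape::extract.clade(tr, ape::getMRCA(tr, c("query", "sheep")))
  expect_setequal(pair$tip.label, c("query", "sheep"))
})

test_that("FASTA writer and reader round-trip sequences", {
  seqs <- c(s1 = random_dna(150), s2 = random_dna(90))
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(back, seqs)
})
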
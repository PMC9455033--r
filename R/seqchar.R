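# Cloned-cDNA characterization: longest-ORF detection, translation,
# protein molecular weight and isoelectric point, pairwise percent
# identity and neighbor-joining phylogeny.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Average residue masses (Da); peptide mass = sum(residues) + one water.
AA_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.0153

# pKa set used for the isoelectric point (termini + ionizable side chains)
DEFAULT_PKA <- list(
  positive = c(Nterm = 7.50, K = 10.00, R = 12.00, H = 5.98),
  negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00))

clean_nt <- function(x) {
  x <- toupper(gsub("\\s", "", x))
  bad <- setdiff(unique(strsplit(x, "")[[1]]),
                 c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V"))
  if (length(bad))
    stop("non-IUPAC nucleotide symbol(s): ", paste(bad, collapse = ", "))
  x
}

#' Find the longest open reading frame
#'
#' Scans the three forward frames (optionally also the reverse
#' complement) for ATG-to-stop spans and returns the longest; ties are
#' broken in favour of the 5'-most start. The reported length includes
#' the stop codon, so an ORF of `L` nt encodes `L/3 - 1` residues.
#'
#' @param cdna Nucleotide sequence (character scalar, IUPAC DNA).
#' @param revcomp Also scan the reverse complement (default FALSE: input
#'   is assumed to be oriented cDNA).
#' @return An `orf_result` list: `found`, `start`/`end` (0-based
#'   half-open, on the scanned strand), `strand`, `frame` (0-2),
#'   `nt_length` (multiple of 3, stop included), `peptide` (stop
#'   removed). When no ORF exists, `found = FALSE` and `nt_length = 0`.
#' @examples
#' find_longest_orf("CCATGGCCTAAGG")
#' @export
find_longest_orf <- function(cdna, revcomp = FALSE) {
  s <- clean_nt(cdna)
  if (nchar(s) < 6)
    stop("sequence shorter than one start plus one stop codon")
  strands <- list("+" = s)
  if (revcomp)
    strands[["-"]] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
  best <- NULL
  for (strand in names(strands)) {
    seq <- strands[[strand]]
    n <- nchar(seq)
    for (frame in 0:2) {
      starts <- seq.int(frame + 1, n, by = 3)
      starts <- starts[starts + 2 <= n]
      if (!length(starts)) next
      codons <- substring(seq, starts, starts + 2)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% STOP_CODONS)
      if (!length(atg) || !length(stp)) next
      # first stop at or after each start codon
      nxt <- stp[findInterval(atg - 1L, stp) + 1L]
      ok <- !is.na(nxt)
      if (!any(ok)) next
      len <- (nxt[ok] - atg[ok] + 1L) * 3L
      cand_start <- starts[atg[ok]]
      for (m in seq_along(len)) {
        better <- is.null(best) || len[m] > best$nt_length ||
          (len[m] == best$nt_length && strand == best$strand &&
           cand_start[m] < best$start + 1L)
        if (better)
          best <- list(found = TRUE, start = cand_start[m] - 1L,
                       end = cand_start[m] - 1L + len[m], strand = strand,
                       frame = frame, nt_length = len[m],
                       nt = substring(seq, cand_start[m],
                                      cand_start[m] + len[m] - 1L))
      }
    }
  }
  if (is.null(best))
    return(structure(list(found = FALSE, start = NA_integer_,
                          end = NA_integer_, strand = NA_character_,
                          frame = NA_integer_, nt_length = 0L,
                          peptide = ""),
                     class = "orf_result"))
  best$peptide <- translate_orf(best$nt)
  best$nt <- NULL
  structure(best, class = "orf_result")
}

#' @export
print.orf_result <- function(x, ...) {
  if (!x$found) cat("No open reading frame found\n")
  else cat(sprintf(
    "ORF: %d nt [%d, %d) strand %s frame %d, encoding %d aa\n",
    x$nt_length, x$start, x$end, x$strand, x$frame, nchar(x$peptide)))
  invisible(x)
}

#' Translate an open reading frame
#'
#' Standard genetic code; a single terminal stop codon is removed from
#' the peptide. An internal stop codon is an error.
#'
#' @param orf_nt Nucleotide sequence whose length is a multiple of 3.
#' @return Amino-acid string.
#' @export
translate_orf <- function(orf_nt) {
  s <- clean_nt(orf_nt)
  if (nchar(s) %% 3 != 0) stop("ORF length must be a multiple of 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "X"))
  if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1)
  if (grepl("\\*", aa)) stop("internal stop codon in ORF")
  aa
}

validate_peptide <- function(peptide) {
  if (!nzchar(peptide)) stop("empty peptide")
  res <- strsplit(toupper(peptide), "")[[1]]
  bad <- setdiff(unique(res), names(AA_RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  res
}

#' Protein molecular weight
#'
#' Average (not monoisotopic) residue masses plus one water molecule,
#' reported in kilodaltons.
#'
#' @param peptide Amino-acid string (20 standard residues).
#' @return Molecular weight in kDa.
#' @examples
#' protein_mw("G")  # glycine: 75.07 Da
#' @export
protein_mw <- function(peptide) {
  res <- validate_peptide(peptide)
  (sum(AA_RESIDUE_MASS[res]) + WATER_MASS) / 1000
}

# Henderson-Hasselbalch net charge at a given pH
peptide_charge <- function(counts_pos, counts_neg, ph) {
  pos <- sum(counts_pos / (1 + 10^(ph - names_num(counts_pos))))
  neg <- sum(counts_neg / (1 + 10^(names_num(counts_neg) - ph)))
  pos - neg
}
names_num <- function(x) as.numeric(names(x))

#' Protein isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge of the peptide
#' (free termini plus D, E, C, Y, H, K, R side chains) is zero, found by
#' bisection on [0, 14]. Net charge is monotone decreasing in pH, so the
#' root is unique.
#'
#' @param peptide Amino-acid string.
#' @param pka pKa table: list with named numeric vectors `positive`
#'   (must include `Nterm`) and `negative` (must include `Cterm`).
#' @param tol Bisection stops when |charge| < `tol`.
#' @return Isoelectric point (pH units).
#' @export
isoelectric_point <- function(peptide, pka = DEFAULT_PKA, tol = 1e-4) {
  res <- validate_peptide(peptide)
  n_res <- table(res)
  cnt <- function(a) if (a %in% names(n_res)) as.numeric(n_res[[a]]) else 0
  pos <- c(cnt("K"), cnt("R"), cnt("H"), 1)
  names(pos) <- c(pka$positive[["K"]], pka$positive[["R"]],
                  pka$positive[["H"]], pka$positive[["Nterm"]])
  neg <- c(cnt("D"), cnt("E"), cnt("C"), cnt("Y"), 1)
  names(neg) <- c(pka$negative[["D"]], pka$negative[["E"]],
                  pka$negative[["C"]], pka$negative[["Y"]],
                  pka$negative[["Cterm"]])
  lo <- 0; hi <- 14
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    q <- peptide_charge(pos, neg, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Full characterization of a set of cDNA sequences
#'
#' For each sequence: longest ORF, encoded peptide, molecular weight and
#' isoelectric point — the standard cloned-cDNA report row.
#'
#' @param seqs Named character vector of nucleotide sequences, or a
#'   `DNAStringSet`.
#' @param revcomp Passed to [find_longest_orf].
#' @return Data frame `name, seq_len, orf_start, orf_end, orf_len,
#'   aa_len, mw_kda, pi`.
#' @export
characterize_cdna <- function(seqs, revcomp = FALSE) {
  seqs <- as_named_chars(seqs)
  rows <- lapply(names(seqs), function(nm) {
    orf <- find_longest_orf(seqs[[nm]], revcomp = revcomp)
    if (!orf$found || !nzchar(orf$peptide))
      return(data.frame(name = nm, seq_len = nchar(seqs[[nm]]),
                        orf_start = NA_integer_, orf_end = NA_integer_,
                        orf_len = 0L, aa_len = 0L, mw_kda = NA_real_,
                        pi = NA_real_, stringsAsFactors = FALSE))
    data.frame(name = nm, seq_len = nchar(seqs[[nm]]),
               orf_start = orf$start, orf_end = orf$end,
               orf_len = orf$nt_length, aa_len = nchar(orf$peptide),
               mw_kda = round(protein_mw(orf$peptide), 2),
               pi = round(isoelectric_point(orf$peptide), 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

as_named_chars <- function(seqs) {
  if (inherits(seqs, "XStringSet")) {
    out <- as.character(seqs)
  } else if (is.character(seqs)) {
    out <- seqs
  } else stop("sequences must be a named character vector or XStringSet")
  if (is.null(names(out)) || anyDuplicated(names(out)))
    stop("sequences must carry unique names")
  out
}

#' Pairwise percent-identity matrix
#'
#' Needleman-Wunsch global alignment of every pair (match +1, mismatch
#' -1, linear gap -2) with identity defined as matching positions over
#' alignment length.
#'
#' @param seqs Named character vector (all nucleotide or all protein) or
#'   an `XStringSet`.
#' @param alphabet `"dna"` or `"protein"`; `"auto"` guesses from residue
#'   content.
#' @return List with `identity` (symmetric percent matrix, diagonal 100)
#'   and `distance` (1 - fractional identity, zero diagonal).
#' @export
identity_matrix <- function(seqs, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  seqs <- as_named_chars(seqs)
  if (length(seqs) < 2) stop("need at least two sequences")
  if (alphabet == "auto") {
    letters_seen <- unique(strsplit(paste(toupper(seqs), collapse = ""),
                                    "")[[1]])
    alphabet <- if (all(letters_seen %in% c("A", "C", "G", "T", "N")))
      "dna" else "protein"
  }
  if (alphabet == "dna") {
    xss <- Biostrings::DNAStringSet(toupper(seqs))
    submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE)
  } else {
    xss <- Biostrings::AAStringSet(toupper(seqs))
    aas <- Biostrings::AA_ALPHABET
    submat <- matrix(-1, length(aas), length(aas),
                     dimnames = list(aas, aas))
    diag(submat) <- 1
  }
  k <- length(seqs)
  id <- matrix(100, k, k, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    aln <- Biostrings::pairwiseAlignment(
      xss[[i]], xss[[j]], type = "global",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 2)
    a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    id[i, j] <- id[j, i] <- 100 * sum(a == b & a != "-") / length(a)
  }
  list(identity = id, distance = 1 - id / 100)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (exact on additive distances). Negative
#' branch lengths, which NJ can produce on noisy input, are clamped to
#' zero with the total deficit reported in the result.
#'
#' @param dm Symmetric non-negative distance matrix with zero diagonal
#'   and at least three named taxa, or the `distance` element of
#'   [identity_matrix] output.
#' @return An `nj_result` list: `tree` (an `ape::phylo`), `newick`
#'   (Newick string), `clamped` (total negative length removed).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining needs at least three taxa")
  if (max(abs(dm - t(dm))) > 1e-10) stop("distance matrix must be symmetric")
  if (any(dm < 0)) stop("distances must be non-negative")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(dm)))
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  tree <- ape::nj(dm)
  neg <- tree$edge.length < 0
  clamped <- -sum(tree$edge.length[neg])
  tree$edge.length[neg] <- 0
  structure(list(tree = tree, newick = ape::write.tree(tree, digits = 15),
                 clamped = clamped),
            class = "nj_result")
}

#' @export
print.nj_result <- function(x, ...) {
  cat("Neighbor-joining tree over", length(x$tree$tip.label), "taxa\n")
  cat(x$newick, "\n")
  if (x$clamped > 0)
    cat(sprintf("(%.4g of negative branch length clamped to zero)\n",
                x$clamped))
  invisible(x)
}

#' Parse a Newick string
#'
#' Thin wrapper around `ape::read.tree` so that trees written by
#' [nj_tree] round-trip within the package.
#'
#' @param text Newick string.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(text) ape::read.tree(text = text)

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  xss <- if (alphabet == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  stats::setNames(as.character(xss), sub("\\s.*$", "", names(xss)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_named_chars(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(gsub("(.{70})", "\\1\n", seqs[[nm]]), con)
  }
  invisible(path)
}
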
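# Independent oracles used to validate the implementation paths.

# Exhaustive longest-ORF oracle: enumerate every ATG..stop span in all
# three forward frames by direct string inspection.
orf_oracle <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best_len <- 0L
  best_start <- NA_integer_
  for (start in seq_len(max(0, n - 5))) {
    if (substring(seq, start, start + 2) != "ATG") next
    pos <- start + 3L
    while (pos + 2 <= n) {
      codon <- substring(seq, pos, pos + 2)
      if (codon %in% stops) {
        len <- pos + 3L - start
        if (len > best_len) {  # strictly longer keeps the 5'-most tie
          best_len <- len
          best_start <- start
        }
        break
      }
      pos <- pos + 3L
    }
  }
  list(nt_length = best_len, start = best_start - 1L)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Global-alignment score oracle (match +1, mismatch -1, gap -2) plus the
# set of identity fractions attainable by optimal alignments, found by
# exhaustive backtracking. Intended for short sequences only.
nw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (a[i] == b[j]) match else mismatch,
      S[i, j + 1] + gap,
      S[i + 1, j] + gap)
  }
  idents <- new.env()
  walk <- function(i, j, matches, len) {
    if (i == 0 && j == 0) {
      key <- sprintf("%.12f", matches / len)
      assign(key, TRUE, envir = idents)
      return(invisible())
    }
    if (i > 0 && j > 0) {
      sub <- if (a[i] == b[j]) match else mismatch
      if (S[i + 1, j + 1] == S[i, j] + sub)
        walk(i - 1, j - 1, matches + (a[i] == b[j]), len + 1)
    }
    if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap)
      walk(i - 1, j, matches, len + 1)
    if (j > 0 && S[i + 1, j + 1] == S[i + 1, j] + gap)
      walk(i, j - 1, matches, len + 1)
  }
  walk(n, m, 0, 0)
  list(score = S[n + 1, m + 1],
       identities = sort(as.numeric(ls(idents))))
}

# Grid-scan oracle for the isoelectric point: minimise |net charge| over
# a fine pH grid using the same pKa table as the implementation.
pi_grid_oracle <- function(peptide, step = 0.001) {
  pka <- ovigene:::DEFAULT_PKA
  res <- strsplit(toupper(peptide), "")[[1]]
  cnt <- function(a) sum(res == a)
  ph <- seq(0, 14, by = step)
  pos <- cnt("K") / (1 + 10^(ph - pka$positive[["K"]])) +
    cnt("R") / (1 + 10^(ph - pka$positive[["R"]])) +
    cnt("H") / (1 + 10^(ph - pka$positive[["H"]])) +
    1 / (1 + 10^(ph - pka$positive[["Nterm"]]))
  neg <- cnt("D") / (1 + 10^(pka$negative[["D"]] - ph)) +
    cnt("E") / (1 + 10^(pka$negative[["E"]] - ph)) +
    cnt("C") / (1 + 10^(pka$negative[["C"]] - ph)) +
    cnt("Y") / (1 + 10^(pka$negative[["Y"]] - ph)) +
    1 / (1 + 10^(pka$negative[["Cterm"]] - ph))
  ph[which.min(abs(pos - neg))]
}

# Check the defining property of a compact letter display against its
# p-value matrix: share a letter <=> non-significant pair.
cld_matches_pmatrix <- function(letters_vec, pmat, alpha = 0.05) {
  k <- nrow(pmat)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    share <- length(intersect(strsplit(letters_vec[i], "")[[1]],
                              strsplit(letters_vec[j], "")[[1]])) > 0
    if (share != (pmat[i, j] >= alpha)) return(FALSE)
  }
  TRUE
}

# random symmetric p-value matrix with unit diagonal
random_pmatrix <- function(k) {
  p <- matrix(1, k, k)
  v <- runif(k * (k - 1) / 2)
  p[lower.tri(p)] <- v
  p <- pmin(p, t(p))
  p[upper.tri(p)] <- t(p)[upper.tri(p)]
  diag(p) <- 1
  dimnames(p) <- list(paste0("g", 1:k), paste0("g", 1:k))
  p
}

# Expand Table-style genotype counts into one row per animal.
expand_counts <- function(counts, locus = "locus") {
  g <- rep(names(counts), counts)
  data.frame(animal_id = seq_along(g), locus = locus, genotype = g,
             stringsAsFactors = FALSE)
}
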
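# Single-locus population-genetic summaries: genotype/allele frequencies,
# gene-diversity indices (Ho, He, Ne, PIC) and the Hardy-Weinberg
# chi-square goodness-of-fit test.

# genotype strings accepted as missing and excluded from N
MISSING_GENOTYPE_CODES <- c("", ".", "./.", "NA")

#' Construct a per-locus genotype tally
#'
#' A `genotype_counts` object is the unit of all downstream population
#' statistics: a named vector of animal counts per unordered genotype class
#' at one locus (e.g. `c(AA = 256, AG = 150, GG = 27)`).
#'
#' @param locus_id Character label for the locus (e.g. `"g.51537A>G"`).
#' @param counts Named non-negative integer vector; names are two-allele
#'   genotype strings. Heterozygote names are normalised so that `"GA"` and
#'   `"AG"` denote the same class.
#' @param alleles Optional ordered character vector of allele symbols;
#'   defaults to the sorted set of alleles seen in `counts`.
#' @param n_missing Number of records excluded as missing when tallying.
#' @return An object of class `genotype_counts` with fields `locus_id`,
#'   `alleles`, `counts`, `n` (total non-missing animals) and `n_missing`.
#' @export
genotype_counts <- function(locus_id, counts, alleles = NULL, n_missing = 0L) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("`counts` must be a named vector of genotype classes")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  key <- normalize_genotype(names(counts))
  if (any(nchar(key) != 2L))
    stop("genotype class names must be two allele symbols, got: ",
         paste(names(counts)[nchar(key) != 2L], collapse = ", "))
  counts <- tapply(as.integer(counts), key, sum)  # pool AG/GA style duplicates
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[order(names(counts))]
  seen <- sort(unique(unlist(strsplit(names(counts), ""))))
  if (is.null(alleles)) alleles <- seen
  if (length(setdiff(seen, alleles)))
    stop("alleles in counts not listed in `alleles`: ",
         paste(setdiff(seen, alleles), collapse = ", "))
  n <- sum(counts)
  if (n <= 0) stop("total genotype count must be positive")
  structure(
    list(locus_id = locus_id, alleles = alleles,
         counts = counts, n = n, n_missing = as.integer(n_missing)),
    class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("Genotype counts for locus", x$locus_id, "\n")
  print(x$counts)
  cat("N =", x$n, "animals")
  if (x$n_missing > 0) cat(" (", x$n_missing, " missing excluded)", sep = "")
  cat("\n")
  invisible(x)
}

# "A/G", "ga" etc. -> canonical sorted uppercase pair "AG"
normalize_genotype <- function(g) {
  g <- gsub("[/|]", "", toupper(trimws(as.character(g))))
  vapply(strsplit(g, ""),
         function(a) paste(sort(a), collapse = ""), character(1))
}

#' Tally per-animal genotype records at one locus
#'
#' Aggregates a long-format genotype table (one row per animal) into a
#' [genotype_counts] tally. Missing genotypes (blank, `"."`, `"./."` or
#' `NA`) are excluded from N and counted in `n_missing`.
#'
#' @param records Data frame with a `genotype` column and optionally
#'   `locus` and `animal_id` columns. Genotypes are two allele characters,
#'   optionally separated by `/` or `|`; `"AG"` and `"GA"` are pooled.
#' @param locus Locus to tally. Required when `records` holds several loci;
#'   the function processes exactly one locus per call.
#' @param alleles Allowed allele symbols (default the DNA bases). A
#'   genotype containing any other symbol is an error naming the offending
#'   row.
#' @return A [genotype_counts] object.
#' @examples
#' recs <- data.frame(animal_id = 1:4, genotype = c("AA", "AG", "GA", "./."))
#' tabulate_genotypes(recs, locus = "g.51537A>G")
#' @export
tabulate_genotypes <- function(records, locus = NULL,
                               alleles = c("A", "C", "G", "T")) {
  stopifnot(is.data.frame(records))
  if (!"genotype" %in% names(records))
    stop("`records` must have a `genotype` column")
  if ("locus" %in% names(records)) {
    loci <- unique(as.character(records$locus))
    if (is.null(locus)) {
      if (length(loci) > 1L)
        stop("records contain ", length(loci),
             " loci; supply `locus` and call once per locus")
      locus <- loci
    } else {
      records <- records[records$locus == locus, , drop = FALSE]
      if (!nrow(records)) stop("no records for locus ", locus)
    }
  } else if (is.null(locus)) locus <- "locus"

  g <- as.character(records$genotype)
  g[is.na(g)] <- ""
  is_missing <- trimws(g) %in% MISSING_GENOTYPE_CODES
  rows <- which(!is_missing)
  g <- g[!is_missing]
  if (!length(g)) stop("zero non-missing genotypes for locus ", locus)

  stripped <- gsub("[/|]", "", toupper(trimws(g)))
  bad <- which(nchar(stripped) != 2L)
  if (length(bad))
    stop("row ", rows[bad[1]], ": genotype '", g[bad[1]],
         "' is not a two-allele pair")
  pair <- strsplit(stripped, "")
  unknown <- which(vapply(pair, function(a) !all(a %in% alleles), logical(1)))
  if (length(unknown))
    stop("row ", rows[unknown[1]], ": unknown allele symbol in genotype '",
         g[unknown[1]], "'")
  key <- vapply(pair, function(a) paste(sort(a), collapse = ""), character(1))
  tab <- table(key)
  genotype_counts(locus,
                  stats::setNames(as.integer(tab), names(tab)),
                  n_missing = sum(is_missing))
}

#' Genotype frequencies
#'
#' @param gc A [genotype_counts] object.
#' @return Named numeric vector of proportions summing to 1.
#' @export
genotype_frequencies <- function(gc) {
  stopifnot(inherits(gc, "genotype_counts"))
  gc$counts / gc$n
}

#' Allele frequencies by gene counting
#'
#' Each homozygote contributes two copies of its allele, each heterozygote
#' one copy of each, out of 2N gametes.
#'
#' @param gc A [genotype_counts] object.
#' @return An `allele_freqs` object: `locus_id` plus a named vector `freqs`
#'   of proportions summing to 1.
#' @export
allele_frequencies <- function(gc) {
  stopifnot(inherits(gc, "genotype_counts"))
  copies <- stats::setNames(numeric(length(gc$alleles)), gc$alleles)
  pair <- strsplit(names(gc$counts), "")
  for (i in seq_along(pair))
    for (a in pair[[i]]) copies[a] <- copies[a] + gc$counts[i]
  structure(list(locus_id = gc$locus_id, freqs = copies / (2 * gc$n)),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("Allele frequencies for locus", x$locus_id, "\n")
  print(round(x$freqs, 4))
  invisible(x)
}

#' Botstein's polymorphism information content
#'
#' PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2 for allele frequencies
#' p. Classified as low (< 0.25), moderate (0.25-0.5) or high (> 0.5);
#' boundary values fall in the moderate class.
#'
#' @param p Numeric vector of allele frequencies (must sum to 1).
#' @return PIC value in [0, 1].
#' @export
botstein_pic <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0), abs(sum(p) - 1) < 1e-8)
  sum2 <- sum(p^2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - sum2 - (sum2^2 - sum(p^4))
}

pic_class <- function(pic) {
  if (pic < 0.25) "low" else if (pic > 0.5) "high" else "moderate"
}

#' Gene-diversity indices from allele frequencies
#'
#' Computes homozygosity Ho = sum(p^2), gene diversity (heterozygosity)
#' He = 1 - sum(p^2), effective allele number Ne = 1 / sum(p^2) and
#' Botstein's PIC, with the conventional diversity classification.
#'
#' Note: "Ho" here is expected homozygosity under random mating computed
#' from allele frequencies, the quantity reported alongside He and Ne in
#' livestock SNP tables, not the observed homozygote proportion.
#'
#' @param af An `allele_freqs` object (from [allele_frequencies]) or a bare
#'   numeric frequency vector.
#' @return A `diversity_indices` object: `locus_id`, `ho`, `he`, `ne`,
#'   `pic`, `pic_class`.
#' @export
diversity_indices <- function(af) {
  if (is.numeric(af)) af <- structure(list(locus_id = "locus", freqs = af),
                                      class = "allele_freqs")
  stopifnot(inherits(af, "allele_freqs"))
  p <- af$freqs
  if (abs(sum(p) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  sum2 <- sum(p^2)
  pic <- botstein_pic(p)
  structure(
    list(locus_id = af$locus_id, ho = sum2, he = 1 - sum2, ne = 1 / sum2,
         pic = pic, pic_class = pic_class(pic)),
    class = "diversity_indices")
}

#' @export
print.diversity_indices <- function(x, ...) {
  cat(sprintf(
    "Locus %s: Ho %.2f  He %.2f  Ne %.2f  PIC %.2f (%s diversity)\n",
    x$locus_id, x$ho, x$he, x$ne, x$pic, x$pic_class))
  invisible(x)
}

# all unordered genotype classes over an allele set, in sorted-name order
all_genotype_classes <- function(alleles) {
  alleles <- sort(alleles)
  k <- length(alleles)
  out <- character(0)
  for (i in seq_len(k))
    for (j in i:k)
      out <- c(out, paste0(alleles[i], alleles[j]))
  sort(out)
}

#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' Expected genotype counts are computed from the sample allele
#' frequencies (N p^2, 2 N p q, N q^2 for a biallelic locus; all
#' k(k+1)/2 classes included for k alleles even when unobserved). The
#' statistic sums (O-E)^2/E over classes with E > 0 and is referred to a
#' chi-square distribution on k(k-1)/2 degrees of freedom (1 for a
#' biallelic SNP).
#'
#' Classes with expected count below 5 trigger a warning (classical
#' validity condition) but are not pooled.
#'
#' @param gc A [genotype_counts] object with at least two alleles.
#' @return An `hwe_test` object: `locus_id`, `observed`, `expected`,
#'   `chi2`, `df`, `p_value`, and `small_expected` (names of classes with
#'   E < 5).
#' @export
hwe_chi_square <- function(gc) {
  stopifnot(inherits(gc, "genotype_counts"))
  af <- allele_frequencies(gc)
  p <- af$freqs[af$freqs > 0]
  if (length(p) < 2)
    stop("HWE undefined for a monomorphic locus (", gc$locus_id, ")")
  alleles <- names(p)
  classes <- all_genotype_classes(alleles)
  expected <- vapply(classes, function(cl) {
    a <- strsplit(cl, "")[[1]]
    if (a[1] == a[2]) gc$n * p[a[1]]^2 else 2 * gc$n * p[a[1]] * p[a[2]]
  }, numeric(1))
  observed <- stats::setNames(numeric(length(classes)), classes)
  observed[names(gc$counts)] <- gc$counts
  if (any(expected == 0 & observed > 0))
    stop("observed genotypes in a class with zero expected count at ",
         gc$locus_id)
  use <- expected > 0
  chi2 <- sum((observed[use] - expected[use])^2 / expected[use])
  k <- length(alleles)
  df <- k * (k - 1) / 2
  small <- names(expected)[use & expected < 5]
  if (length(small))
    warning("locus ", gc$locus_id, ": expected count below 5 for class ",
            paste(small, collapse = ", "),
            "; chi-square approximation may be poor")
  structure(
    list(locus_id = gc$locus_id, observed = observed, expected = expected,
         chi2 = chi2, df = df,
         p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
         small_expected = small),
    class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("HWE chi-square test, locus %s: chi2 = %.3f, df = %d, p = %.3f\n",
              x$locus_id, x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Per-locus population-genetics summary table
#'
#' One call produces the standard candidate-gene report row set for a
#' locus: genotype counts and frequencies, allele frequencies, Ho, He, Ne,
#' PIC with diversity class, and the HWE chi-square test. Internal
#' computation is full precision; `digits` only affects the returned
#' table.
#'
#' @param gc A [genotype_counts] object.
#' @param digits Rounding applied to the reported proportions and indices
#'   (`NULL` for full precision). Defaults to 2, the conventional table
#'   precision in this literature.
#' @return A data frame with one row per genotype class and columns
#'   `locus, genotype, count, genotype_freq, allele, allele_freq, Ho, He,
#'   Ne, PIC, PIC_class, chi2, df, p_HWE`. Allele columns are filled on
#'   the first rows; for a monomorphic locus the HWE columns are `NA`.
#' @export
popgen_summary <- function(gc, digits = 2) {
  stopifnot(inherits(gc, "genotype_counts"))
  gf <- genotype_frequencies(gc)
  af <- allele_frequencies(gc)
  di <- diversity_indices(af)
  hwe <- if (sum(af$freqs > 0) >= 2) hwe_chi_square(gc) else NULL
  nrows <- max(length(gf), length(af$freqs))
  pad <- function(x, fill = NA) c(x, rep(fill, nrows - length(x)))
  rnd <- function(x) if (is.null(digits)) x else round(x, digits)
  data.frame(
    locus = gc$locus_id,
    genotype = pad(names(gf), ""),
    count = pad(as.integer(gc$counts)),
    genotype_freq = rnd(pad(unname(gf))),
    allele = pad(names(af$freqs), ""),
    allele_freq = rnd(pad(unname(af$freqs))),
    Ho = rnd(di$ho), He = rnd(di$he), Ne = rnd(di$ne), PIC = rnd(di$pic),
    PIC_class = di$pic_class,
    chi2 = if (is.null(hwe)) NA_real_ else rnd(hwe$chi2),
    df = if (is.null(hwe)) NA_integer_ else hwe$df,
    p_HWE = if (is.null(hwe)) NA_real_ else rnd(hwe$p_value),
    stringsAsFactors = FALSE)
}
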
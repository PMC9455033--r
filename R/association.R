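# Fixed-effects association model for litter size:
#   Y_ijn = mu + parity_i + genotype_j + (parity x genotype)_ij + e_ijn
# fitted by least squares under sum-to-zero constraints with Type III
# partial F-tests, plus Table-style per-genotype summaries.

#' Validate a phenotype table
#'
#' Checks the contract of the litter-size phenotype table: columns
#' `animal_id`, `parity` (integer 1-3), `litter_size` (integer >= 1) and
#' `genotype`; at most one record per animal per parity.
#'
#' @param pt Data frame of phenotype records.
#' @return The validated data frame, invisibly coerced types.
#' @export
validate_phenotypes <- function(pt) {
  stopifnot(is.data.frame(pt))
  need <- c("animal_id", "parity", "litter_size", "genotype")
  miss <- setdiff(need, names(pt))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(pt)) stop("phenotype table is empty")
  if (!all(pt$parity %in% 1:3))
    stop("parity must be 1, 2 or 3")
  if (any(pt$litter_size < 1) || any(pt$litter_size != round(pt$litter_size)))
    stop("litter_size must be a positive integer count of lambs")
  if (anyDuplicated(pt[, c("animal_id", "parity")]))
    stop("an animal contributes at most one record per parity")
  pt$parity <- as.integer(pt$parity)
  pt$litter_size <- as.numeric(pt$litter_size)
  pt
}

#' Per-genotype litter-size summary
#'
#' Reproduces the conventional association-table row: for each genotype
#' class, the number of animals and the mean and sample standard deviation
#' (n - 1 denominator) of the per-animal mean litter size across parities.
#' Groups of a single animal report SD 0 and are flagged.
#'
#' @param pt Phenotype table (see [validate_phenotypes]).
#' @param digits Rounding for the reported mean and SD; `NULL` for full
#'   precision.
#' @return Data frame with columns `genotype, n, mean, sd, single_animal`.
#' @export
genotype_summary <- function(pt, digits = 2) {
  pt <- validate_phenotypes(pt)
  per_animal <- stats::aggregate(litter_size ~ animal_id + genotype,
                                 data = pt, FUN = mean)
  out <- do.call(rbind, lapply(split(per_animal, per_animal$genotype),
    function(d) data.frame(
      genotype = d$genotype[1], n = nrow(d),
      mean = mean(d$litter_size),
      sd = if (nrow(d) > 1) stats::sd(d$litter_size) else 0,
      single_animal = nrow(d) == 1,
      stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (!is.null(digits)) {
    out$mean <- round(out$mean, digits)
    out$sd <- round(out$sd, digits)
  }
  out[order(out$genotype), ]
}

# residual sum of squares of a least-squares fit on a design matrix
rss_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit the parity-by-genotype litter-size model
#'
#' Least-squares fit of `litter_size ~ parity + genotype +
#' parity:genotype` on per-parity records (the default) or of
#' `mean litter_size ~ genotype` on per-animal means, under sum-to-zero
#' effect coding. Because the field design is unbalanced, each term is
#' tested with a Type III partial F-test: the increase in residual sum of
#' squares when that term's columns are deleted from the full design
#' matrix.
#'
#' Degenerate designs are handled explicitly: a single genotype class is
#' an error; empty parity-by-genotype cells drop the interaction term with
#' a warning (main effects are kept); a zero-variance response reports all
#' F statistics as not computable and `significant = FALSE`; a saturated
#' design (zero residual df) is an error.
#'
#' @param pt Phenotype table (see [validate_phenotypes]).
#' @param alpha Significance level for the genotype-term decision.
#' @param response `"record"` (default) fits per-parity records with the
#'   full model; `"animal_mean"` fits per-animal mean litter size on
#'   genotype only.
#' @return An `association_fit` object: `anova` (term, df, sumsq, meansq,
#'   statistic, p_value rows plus residuals), `genotype_summary`,
#'   `overall_mean`, `significant` (genotype-term p < alpha),
#'   `interaction_dropped`, `zero_variance`, `alpha`, `response`.
#' @examples
#' g <- gen_genotypes(n = 60, p = 0.7, seed = 1)
#' pt <- gen_phenotypes(g, seed = 2)
#' fit_association(pt)
#' @export
fit_association <- function(pt, alpha = 0.05,
                            response = c("record", "animal_mean")) {
  response <- match.arg(response)
  pt <- validate_phenotypes(pt)
  if (length(unique(pt$genotype)) < 2)
    stop("association requires at least two genotype classes")

  if (response == "animal_mean") {
    per_animal <- stats::aggregate(litter_size ~ animal_id + genotype,
                                   data = pt, FUN = mean)
    dat <- data.frame(y = per_animal$litter_size,
                      genotype = factor(per_animal$genotype))
    terms_list <- list(genotype = ~genotype)
    frm <- y ~ genotype
    interaction_dropped <- FALSE
  } else {
    dat <- data.frame(y = pt$litter_size,
                      parity = factor(pt$parity),
                      genotype = factor(pt$genotype))
    cell <- table(dat$parity, dat$genotype)
    use_interaction <- nlevels(dat$parity) > 1 && all(cell > 0)
    interaction_dropped <- nlevels(dat$parity) > 1 && !use_interaction
    if (interaction_dropped)
      warning("empty parity x genotype cell(s): interaction term dropped")
    frm <- if (use_interaction) y ~ parity * genotype
           else if (nlevels(dat$parity) > 1) y ~ parity + genotype
           else y ~ genotype
  }

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  X <- stats::model.matrix(frm, dat)
  assign <- attr(X, "assign")
  term_labels <- attr(stats::terms(frm), "term.labels")
  y <- dat$y
  n <- length(y)

  rank <- qr(X)$rank
  if (rank < ncol(X))
    stop("rank-deficient design: drop aliased terms before fitting")
  df_res <- n - rank
  if (df_res == 0)
    stop("saturated design (zero residual degrees of freedom): ",
         "one observation per cell leaves no error term")

  rss_full <- rss_fit(X, y)
  zero_variance <- stats::var(y) == 0
  ms_res <- rss_full / df_res

  rows <- lapply(seq_along(term_labels), function(t) {
    cols <- assign == t
    ss <- rss_fit(X[, !cols, drop = FALSE], y) - rss_full
    df <- sum(cols)
    f <- if (zero_variance || ms_res == 0) NA_real_ else (ss / df) / ms_res
    data.frame(term = term_labels[t], df = df, sumsq = ss, meansq = ss / df,
               statistic = f,
               p_value = if (is.na(f)) NA_real_
                         else stats::pf(f, df, df_res, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  anova_tab <- do.call(rbind, rows)
  anova_tab <- rbind(anova_tab,
                     data.frame(term = "residuals", df = df_res,
                                sumsq = rss_full, meansq = ms_res,
                                statistic = NA_real_, p_value = NA_real_,
                                stringsAsFactors = FALSE))

  p_geno <- anova_tab$p_value[anova_tab$term == "genotype"]
  structure(
    list(anova = anova_tab,
         genotype_summary = genotype_summary(pt),
         overall_mean = mean(y),
         significant = isTRUE(!is.na(p_geno) && p_geno < alpha),
         interaction_dropped = interaction_dropped,
         zero_variance = zero_variance,
         alpha = alpha, response = response),
    class = "association_fit")
}

#' @export
print.association_fit <- function(x, ...) {
  cat("Fixed-effects litter-size association (", x$response,
      " response)\n\n", sep = "")
  tab <- x$anova
  tab$sumsq <- round(tab$sumsq, 4)
  tab$meansq <- round(tab$meansq, 4)
  tab$statistic <- round(tab$statistic, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  if (x$zero_variance)
    cat("\nNote: zero-variance response; F statistics not computable.\n")
  if (x$interaction_dropped)
    cat("\nNote: interaction dropped (empty cells).\n")
  cat(sprintf("\nGenotype effect %s at alpha = %.2f\n",
              if (x$significant) "significant" else "not significant",
              x$alpha))
  print(x$genotype_summary, row.names = FALSE)
  invisible(x)
}
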
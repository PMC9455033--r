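# Livak 2^-ddCt relative quantification across tissues, one-way ANOVA and
# pairwise post-hoc p-value matrices for the compact letter display.

#' The 13 sheep tissues profiled by the expression panel
#' @export
SHEEP_TISSUES <- c("hypothalamus", "hypophysis", "heart", "liver", "spleen",
                   "lung", "kidney", "ovary", "oviduct", "uterus", "rumen",
                   "duodenum", "longissimus dorsi")

validate_ct_table <- function(ct) {
  stopifnot(is.data.frame(ct))
  need <- c("animal", "tissue", "gene", "replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("all Ct values must be finite and positive")
  ct
}

#' Relative expression by the Livak 2^-ddCt method
#'
#' Technical replicates are averaged first; for each animal and tissue,
#' dCt = mean Ct(target) - mean Ct(reference). ddCt subtracts the
#' calibrator tissue's mean dCt, and fold change is 2^-ddCt. The
#' tissue-level fold change is computed from the tissue-mean dCt, so the
#' calibrator tissue reports fold change exactly 1; per-animal fold
#' changes (against the same calibrator mean) carry the biological
#' dispersion and feed the across-tissue ANOVA.
#'
#' @param ct Ct table with columns `animal, tissue, gene, replicate, ct`.
#' @param target Target gene symbol (e.g. `"SMAD5"`).
#' @param reference Reference gene symbol (default `"GAPDH"`); must be
#'   measured in every tissue that has a target measurement.
#' @param calibrator Calibrator tissue. Default `NULL` picks the tissue
#'   with the largest mean dCt, i.e. the lowest-expressing tissue, so the
#'   whole profile is >= 1-fold relative to it.
#' @return A `relative_expression` object: `table` (per tissue: `n`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change`, `sd_fold`),
#'   `per_animal` (animal-level dCt and fold change), `calibrator`,
#'   `target`, `reference`.
#' @export
relative_expression <- function(ct, target, reference = "GAPDH",
                                calibrator = NULL) {
  ct <- validate_ct_table(ct)
  ct <- ct[ct$gene %in% c(target, reference), , drop = FALSE]
  if (!any(ct$gene == target)) stop("no rows for target gene ", target)
  # technical replicates -> one Ct per animal x tissue x gene
  tech <- stats::aggregate(ct ~ animal + tissue + gene, data = ct, FUN = mean)
  tg <- tech[tech$gene == target, c("animal", "tissue", "ct")]
  rf <- tech[tech$gene == reference, c("animal", "tissue", "ct")]
  names(tg)[3] <- "ct_target"
  names(rf)[3] <- "ct_ref"
  m <- merge(tg, rf, by = c("animal", "tissue"), all.x = TRUE)
  if (any(is.na(m$ct_ref))) {
    bad <- unique(m$tissue[is.na(m$ct_ref)])
    stop("reference gene ", reference, " missing for tissue(s): ",
         paste(bad, collapse = ", "))
  }
  m$delta_ct <- m$ct_target - m$ct_ref

  tissue_dct <- tapply(m$delta_ct, m$tissue, mean)
  if (is.null(calibrator))
    calibrator <- names(tissue_dct)[which.max(tissue_dct)]
  if (!calibrator %in% names(tissue_dct))
    stop("calibrator tissue not present: ", calibrator)
  cal_dct <- tissue_dct[[calibrator]]

  m$fold_change <- 2^-(m$delta_ct - cal_dct)
  tab <- data.frame(
    tissue = names(tissue_dct),
    n = as.integer(tapply(m$animal, m$tissue, function(a) length(unique(a)))),
    delta_ct = as.numeric(tissue_dct),
    delta_delta_ct = as.numeric(tissue_dct - cal_dct),
    fold_change = 2^-(as.numeric(tissue_dct - cal_dct)),
    sd_fold = as.numeric(tapply(m$fold_change, m$tissue,
                                function(x) if (length(x) > 1) stats::sd(x) else 0)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, per_animal = m, calibrator = calibrator,
                 target = target, reference = reference),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("2^-ddCt relative expression: %s vs %s (calibrator: %s)\n",
              x$target, x$reference, x$calibrator))
  tab <- x$table
  tab$delta_ct <- round(tab$delta_ct, 3)
  tab$delta_delta_ct <- round(tab$delta_delta_ct, 3)
  tab$fold_change <- round(tab$fold_change, 3)
  tab$sd_fold <- round(tab$sd_fold, 3)
  print(tab[order(-tab$fold_change), ], row.names = FALSE)
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA decomposition of
#' between-group and within-group sums of squares. The degenerate case of
#' zero within-group variance with unequal means is reported as an
#' infinite F with p = 0 and flagged.
#'
#' @param values Numeric response vector, or a named list of per-group
#'   vectors (in which case `groups` is ignored).
#' @param groups Grouping vector parallel to `values`.
#' @return A list: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`, `ss_between`, `ss_within`, `degenerate` (TRUE when within
#'   variance is zero).
#' @export
one_way_anova <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(names(values) %||% seq_along(values),
                  lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2) stop("one-way ANOVA needs at least two groups")
  if (n - k < 1) stop("one-way ANOVA needs at least one residual df")
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ss_b <- sum(gn * (gm - mean(values))^2)
  ss_w <- sum((values - gm[groups])^2)
  df_b <- k - 1
  df_w <- n - k
  degenerate <- ss_w == 0
  if (degenerate && ss_b > 0) {
    f <- Inf; p <- 0
  } else if (degenerate) {
    f <- 0; p <- 1
  } else {
    f <- (ss_b / df_b) / (ss_w / df_w)
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  list(statistic = f, df_between = df_b, df_within = df_w, p_value = p,
       ss_between = ss_b, ss_within = ss_w, degenerate = degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise post-hoc p-values for grouped data
#'
#' Builds the symmetric p-value matrix that the compact letter display
#' consumes. `"lsd"` (default) is Fisher's least significant difference:
#' pairwise t-tests using the pooled ANOVA mean square error and its
#' residual df. `"tukey"` is the Tukey-Kramer studentized-range test.
#'
#' @inheritParams one_way_anova
#' @param method `"lsd"` or `"tukey"`.
#' @return Symmetric matrix of pairwise p-values with unit diagonal,
#'   dimnames the group levels.
#' @export
pairwise_posthoc <- function(values, groups = NULL,
                             method = c("lsd", "tukey")) {
  method <- match.arg(method)
  if (is.list(values) && is.null(groups)) {
    groups <- rep(names(values) %||% seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  k <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  aov1 <- one_way_anova(values, groups)
  mse <- aov1$ss_within / aov1$df_within
  p <- matrix(1, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se2 <- mse * (1 / gn[i] + 1 / gn[j])
    d <- abs(gm[i] - gm[j])
    pij <- if (se2 == 0) {
      if (d == 0) 1 else 0
    } else if (method == "lsd") {
      2 * stats::pt(d / sqrt(se2), aov1$df_within, lower.tail = FALSE)
    } else {
      stats::ptukey(d / sqrt(se2 / 2), nmeans = k, df = aov1$df_within,
                    lower.tail = FALSE)
    }
    p[i, j] <- p[j, i] <- pij
  }
  p
}

#' Full tissue-expression analysis for one target gene
#'
#' Convenience pipeline: [relative_expression], one-way ANOVA on
#' per-animal fold changes across tissues, post-hoc pairwise tests and
#' the compact letter display, returning a figure-ready per-tissue table.
#'
#' Pairwise comparisons are *protected*: when the overall ANOVA is not
#' significant at `alpha`, no pairwise difference is declared and all
#' groups share one letter (the classical protected-LSD convention).
#'
#' @inheritParams relative_expression
#' @param alpha Significance level for the letters.
#' @param posthoc Passed to [pairwise_posthoc].
#' @return List with `expression` (the `relative_expression` object),
#'   `anova`, `pairwise_p`, and `table` (tissue, n, mean fold, SD,
#'   letters, ordered by descending mean fold).
#' @export
expression_profile <- function(ct, target, reference = "GAPDH",
                               calibrator = NULL, alpha = 0.05,
                               posthoc = c("lsd", "tukey")) {
  rel <- relative_expression(ct, target, reference, calibrator)
  per <- rel$per_animal
  aov1 <- one_way_anova(per$fold_change, per$tissue)
  pmat <- pairwise_posthoc(per$fold_change, per$tissue, match.arg(posthoc))
  means <- tapply(per$fold_change, factor(per$tissue), mean)
  letters <- if (!is.na(aov1$p_value) && aov1$p_value < alpha)
    letter_display(pmat, means = means, alpha = alpha)
  else stats::setNames(rep("a", nrow(pmat)), rownames(pmat))
  tab <- rel$table
  tab$letters <- unname(letters[tab$tissue])
  tab <- tab[order(-tab$fold_change), ]
  rownames(tab) <- NULL
  list(expression = rel, anova = aov1, pairwise_p = pmat, table = tab)
}
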
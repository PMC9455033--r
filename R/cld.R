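# Compact letter display by the insert-and-absorb algorithm: groups that
# do not share a superscript letter differ significantly at alpha.

#' Compact letter display from a pairwise p-value matrix
#'
#' Assigns superscript letters so that two groups share at least one
#' letter if and only if their pairwise comparison is non-significant at
#' `alpha`. Uses the insert-and-absorb construction: start with a single
#' letter covering all groups; for each significant pair split every
#' letter class containing both members into two copies (one without each
#' member); then absorb classes that are subsets of other classes.
#'
#' @param pairwise_p Square symmetric matrix of pairwise p-values with
#'   unit diagonal; dimnames give group names.
#' @param means Optional named vector of group means; letters are assigned
#'   in descending-mean order so the highest group carries "a", the
#'   convention of expression bar charts. Default is column order.
#' @param alpha Significance threshold.
#' @return Named character vector: for each group, its letters in
#'   alphabetical order (e.g. `"ab"`).
#' @examples
#' p <- matrix(c(1, .001, .001, .001, 1, .9, .001, .9, 1), 3,
#'             dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
#' letter_display(p)
#' @export
letter_display <- function(pairwise_p, means = NULL, alpha = 0.05) {
  if (!is.matrix(pairwise_p) || nrow(pairwise_p) != ncol(pairwise_p))
    stop("`pairwise_p` must be a square matrix")
  if (max(abs(pairwise_p - t(pairwise_p))) > 1e-12)
    stop("`pairwise_p` must be symmetric")
  if (any(abs(diag(pairwise_p) - 1) > 1e-12))
    stop("`pairwise_p` must have unit diagonal")
  k <- nrow(pairwise_p)
  groups <- rownames(pairwise_p) %||% as.character(seq_len(k))
  ord <- if (is.null(means)) seq_len(k)
         else order(-as.numeric(means[groups]))

  classes <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (pairwise_p[i, j] >= alpha) next
    hit <- vapply(classes, function(cl) all(c(i, j) %in% cl), logical(1))
    if (!any(hit)) next
    split_new <- unlist(lapply(classes[hit], function(cl)
      list(setdiff(cl, i), setdiff(cl, j))), recursive = FALSE)
    classes <- c(classes[!hit], split_new)
    # absorb: drop classes contained in another class (and duplicates)
    keep <- rep(TRUE, length(classes))
    for (a in seq_along(classes)) for (b in seq_along(classes)) {
      if (a == b || !keep[a]) next
      if (all(classes[[a]] %in% classes[[b]]) &&
          (length(classes[[a]]) < length(classes[[b]]) ||
           (length(classes[[a]]) == length(classes[[b]]) && a > b && keep[b])))
        keep[a] <- FALSE
    }
    classes <- classes[keep]
    classes <- classes[lengths(classes) > 0]
  }

  # letters ordered by each class's highest-ranked member
  rank_of <- match(seq_len(k), ord)
  class_rank <- vapply(classes, function(cl) min(rank_of[cl]), numeric(1))
  classes <- classes[order(class_rank)]
  lab <- c(letters, as.vector(outer(letters, letters, paste0)))
  per_group <- rep(list(character(0)), k)
  for (ci in seq_along(classes))
    for (g in classes[[ci]])
      per_group[[g]] <- c(per_group[[g]], lab[ci])
  stats::setNames(
    vapply(per_group, function(l) paste(sort(l), collapse = ""),
           character(1)),
    groups)
}
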
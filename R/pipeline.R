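# CSV readers for the standard input dialects and the report
# orchestrator tying population-genetic and association stages together.

#' Read a per-animal genotype CSV
#'
#' Expected header: `animal_id,locus,genotype` (genotype as two allele
#' characters, e.g. "AG"; blank, "." or "./." mean missing).
#'
#' @param path CSV file.
#' @return Data frame of genotype records.
#' @export
read_genotype_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("animal_id", "locus", "genotype")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  d
}

#' Read a pre-tallied genotype counts CSV
#'
#' Expected header: `locus,genotype,count`.
#'
#' @param path CSV file.
#' @return Named list of [genotype_counts], one per locus.
#' @export
read_counts_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus", "genotype", "count")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  out <- lapply(split(d, d$locus), function(dd)
    genotype_counts(dd$locus[1],
                    stats::setNames(as.integer(dd$count), dd$genotype)))
  out[unique(d$locus)]
}

#' Read a phenotype CSV
#'
#' Expected header: `animal_id,parity,litter_size`.
#'
#' @param path CSV file.
#' @return Data frame of phenotype records.
#' @export
read_phenotype_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "parity", "litter_size")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  d
}

#' Read a qPCR Ct CSV
#'
#' Expected header: `animal,tissue,gene,replicate,ct`.
#'
#' @param path CSV file.
#' @return Validated Ct table.
#' @export
read_ct_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ct_table(d)
}

#' Run the full candidate-gene report
#'
#' Orchestrates the tabulation, population-genetics and (when phenotypes
#' are supplied) association stages for every locus in the input, and
#' writes the three standard summary tables plus a run log. Re-running
#' with identical inputs yields byte-identical tables.
#'
#' @param config Path to a YAML configuration file or an equivalent named
#'   list. Recognised keys: `genotypes` (per-animal CSV) or `counts`
#'   (pre-tallied CSV); optional `phenotypes` CSV; `alpha` (default
#'   0.05); `digits` (default 2); `out_dir` (default `"."`); `seed`
#'   (recorded in the log).
#' @return Invisibly, a list with `popgen` (combined summary data frame),
#'   `association` (per-locus `association_fit` objects or `NULL`),
#'   `files` (paths written), `log` (character lines).
#' @export
run_report <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  alpha <- cfg$alpha %||% 0.05
  digits <- cfg$digits %||% 2
  out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- c(paste0("ovigene ", as.character(utils::packageVersion("ovigene"))),
           paste0("R ", getRversion()),
           paste0("run at ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           if (!is.null(cfg$seed)) paste0("seed ", cfg$seed))
  note <- function(...) log <<- c(log, paste0(...))

  counts_list <- if (!is.null(cfg$counts)) {
    note("counts file: ", cfg$counts)
    read_counts_csv(cfg$counts)
  } else if (!is.null(cfg$genotypes)) {
    recs <- read_genotype_csv(cfg$genotypes)
    note("genotype file: ", cfg$genotypes, " (", nrow(recs), " rows)")
    out <- lapply(unique(recs$locus), function(l)
      withCallingHandlers(
        tabulate_genotypes(recs, locus = l),
        warning = function(w) {
          note("warning [", l, "]: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        }))
    names(out) <- unique(recs$locus)
    out
  } else stop("config must name a `genotypes` or `counts` input")
  for (l in names(counts_list))
    note("locus ", l, ": N = ", counts_list[[l]]$n, ", ",
         counts_list[[l]]$n_missing, " missing excluded")

  popgen <- do.call(rbind, lapply(counts_list, function(gc)
    withCallingHandlers(popgen_summary(gc, digits = digits),
                        warning = function(w) {
                          note("warning [", gc$locus_id, "]: ",
                               conditionMessage(w))
                          invokeRestart("muffleWarning")
                        })))
  rownames(popgen) <- NULL
  popgen_path <- file.path(out_dir, "popgen_summary.csv")
  utils::write.csv(popgen, popgen_path, row.names = FALSE, quote = FALSE)
  files <- popgen_path

  association <- NULL
  if (!is.null(cfg$phenotypes)) {
    if (is.null(cfg$genotypes))
      stop("association stage needs per-animal `genotypes` to join on")
    phen <- read_phenotype_csv(cfg$phenotypes)
    recs <- read_genotype_csv(cfg$genotypes)
    note("phenotype file: ", cfg$phenotypes, " (", nrow(phen), " rows)")
    association <- list()
    assoc_rows <- list(); anova_rows <- list()
    for (l in unique(recs$locus)) {
      gl <- recs[recs$locus == l, c("animal_id", "genotype")]
      pt <- merge(phen, gl, by = "animal_id")
      pt <- pt[!(trimws(pt$genotype) %in% MISSING_GENOTYPE_CODES), ]
      fit <- withCallingHandlers(
        fit_association(pt, alpha = alpha),
        warning = function(w) {
          note("warning [", l, "]: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      association[[l]] <- fit
      gs <- fit$genotype_summary
      assoc_rows[[l]] <- data.frame(locus = l, gs[c("genotype", "n",
                                                    "mean", "sd")],
                                    stringsAsFactors = FALSE)
      at <- fit$anova
      anova_rows[[l]] <- data.frame(locus = l, at, stringsAsFactors = FALSE)
      note("locus ", l, ": genotype term ",
           if (fit$significant) "significant" else "not significant",
           " at alpha = ", alpha)
    }
    assoc <- do.call(rbind, assoc_rows); rownames(assoc) <- NULL
    anova <- do.call(rbind, anova_rows); rownames(anova) <- NULL
    assoc_path <- file.path(out_dir, "association_summary.csv")
    anova_path <- file.path(out_dir, "association_anova.csv")
    utils::write.csv(assoc, assoc_path, row.names = FALSE, quote = FALSE)
    utils::write.csv(anova, anova_path, row.names = FALSE, quote = FALSE)
    files <- c(files, assoc_path, anova_path)
  }

  log_path <- file.path(out_dir, "report.log")
  writeLines(log, log_path)
  invisible(list(popgen = popgen, association = association,
                 files = c(files, log_path), log = log))
}
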
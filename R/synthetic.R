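# Synthetic-data generators emulating the study's inputs: biallelic SNP
# genotypes for a flock of ewes, Bernoulli singleton/twin litter records
# under the parity x genotype model, triplicate qPCR Ct tables across 13
# tissues, and homolog families evolved along a random tree.

#' Simulate biallelic genotype records
#'
#' Animals are drawn from the three-class genotype distribution
#' (p^2 + F p q, 2 p q (1 - F), q^2 + F p q), i.e. Hardy-Weinberg
#' proportions at `f = 0` with an inbreeding-like departure controlled by
#' `f`; `f = 1` removes all heterozygotes.
#'
#' Defaults mirror the study flock: 433 ewes at a major-allele frequency
#' of 0.76.
#'
#' @param n Number of animals.
#' @param p Major-allele frequency.
#' @param f Inbreeding-like departure in [0, 1].
#' @param alleles Two allele symbols, major first.
#' @param locus Locus label attached to every record.
#' @param seed Optional RNG seed (reproducible, bit-identical output).
#' @return Data frame `animal_id, locus, genotype`.
#' @export
gen_genotypes <- function(n = 433, p = 0.76, f = 0,
                          alleles = c("A", "G"), locus = "g.51537A>G",
                          seed = NULL) {
  stopifnot(p >= 0, p <= 1, f >= 0, f <= 1, length(alleles) == 2, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  q <- 1 - p
  probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
  a <- sort(alleles)
  classes <- c(paste0(alleles[1], alleles[1]),
               paste0(a[1], a[2]),
               paste0(alleles[2], alleles[2]))
  data.frame(
    animal_id = sprintf("ewe%04d", seq_len(n)),
    locus = locus,
    genotype = sample(classes, n, replace = TRUE, prob = probs),
    stringsAsFactors = FALSE)
}

#' Simulate litter-size records under the parity x genotype model
#'
#' Litter size is 1 + Bernoulli(pi): ewes in this population bear
#' singletons or twins, with baseline twin probability `pi0` (default
#' 0.07, giving mean litter size about 1.07 and SD about 0.26, the scale
#' of the study flock). Parity, genotype and interaction effects shift
#' the twin probability either on the log-odds scale (default) or as a
#' direct displacement of the probability itself.
#'
#' @param genotypes Data frame with `animal_id` and `genotype` columns
#'   (e.g. from [gen_genotypes]).
#' @param pi0 Baseline twin probability.
#' @param parity_effects Numeric length-3 vector of parity effects.
#' @param genotype_effects Named numeric vector of per-genotype effects
#'   (missing classes get 0).
#' @param interaction_effects Optional 3 x genotype matrix (rows =
#'   parities, columns named by genotype class).
#' @param effect_scale `"logit"` applies effects to the log-odds of
#'   twinning; `"probability"` adds them to the probability directly.
#' @param n_parities Records per animal (consecutive parities).
#' @param seed Optional RNG seed.
#' @return A phenotype table: `animal_id, parity, genotype, litter_size`.
#' @export
gen_phenotypes <- function(genotypes, pi0 = 0.07,
                           parity_effects = c(0, 0, 0),
                           genotype_effects = NULL,
                           interaction_effects = NULL,
                           effect_scale = c("logit", "probability"),
                           n_parities = 3, seed = NULL) {
  effect_scale <- match.arg(effect_scale)
  stopifnot(is.data.frame(genotypes),
            all(c("animal_id", "genotype") %in% names(genotypes)),
            pi0 >= 0, pi0 <= 1, length(parity_effects) >= n_parities)
  if (!is.null(seed)) set.seed(seed)
  classes <- sort(unique(genotypes$genotype))
  ge <- stats::setNames(numeric(length(classes)), classes)
  if (!is.null(genotype_effects))
    ge[names(genotype_effects)] <- genotype_effects
  ie <- matrix(0, n_parities, length(classes),
               dimnames = list(NULL, classes))
  if (!is.null(interaction_effects))
    ie[, colnames(interaction_effects)] <- interaction_effects

  out <- do.call(rbind, lapply(seq_len(n_parities), function(par) {
    eta <- parity_effects[par] + ge[genotypes$genotype] +
      ie[par, genotypes$genotype]
    pi <- if (effect_scale == "logit") {
      if (pi0 %in% c(0, 1)) rep(pi0, nrow(genotypes))
      else stats::plogis(stats::qlogis(pi0) + eta)
    } else pi0 + eta
    if (any(pi < -1e-12 | pi > 1 + 1e-12))
      stop("effects push the twin probability outside [0, 1]")
    pi <- pmin(pmax(pi, 0), 1)
    data.frame(animal_id = genotypes$animal_id, parity = par,
               genotype = genotypes$genotype,
               litter_size = 1L + stats::rbinom(nrow(genotypes), 1, pi),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Default per-tissue true fold changes for the Ct generator
#'
#' High expression in ovary, lung, spleen and uterus, lowest in
#' longissimus dorsi, matching the qualitative expression pattern the
#' analysis is designed to recover.
#' @export
DEFAULT_TISSUE_FOLD <- c(
  hypothalamus = 1.5, hypophysis = 1.2, heart = 1.0, liver = 1.3,
  spleen = 5, lung = 6, kidney = 1.4, ovary = 8, oviduct = 2, uterus = 4,
  rumen = 1.1, duodenum = 1.2, `longissimus dorsi` = 0.4)

#' Simulate a triplicate qPCR Ct table
#'
#' For each tissue, Ct(reference) = `ref_baseline` + technical noise and
#' Ct(target) = `target_baseline` - log2(fold) + biological noise (one
#' draw per animal x tissue) + technical noise. With all noise at zero
#' the Livak pipeline inverts the specified fold changes exactly (up to
#' normalisation by the calibrator tissue).
#'
#' @param fold Named vector of true fold changes per tissue.
#' @param target,reference Gene symbols placed in the `gene` column.
#' @param ref_baseline,target_baseline Baseline Ct values.
#' @param bio_sd Biological (animal-level) noise SD in Ct units.
#' @param tech_sd Technical replicate noise SD in Ct units.
#' @param n_animals Biological replicates (default 3 ewes).
#' @param n_tech Technical replicates per reaction (default 3).
#' @param seed Optional RNG seed.
#' @return A Ct table: `animal, tissue, gene, replicate, ct`.
#' @export
gen_ct_table <- function(fold = DEFAULT_TISSUE_FOLD, target = "SMAD5",
                         reference = "GAPDH", ref_baseline = 16,
                         target_baseline = 24, bio_sd = 0.2, tech_sd = 0.1,
                         n_animals = 3, n_tech = 3, seed = NULL) {
  stopifnot(all(fold > 0), bio_sd >= 0, tech_sd >= 0)
  if (is.null(names(fold))) stop("`fold` must be named by tissue")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(animal = sprintf("animal%d", seq_len(n_animals)),
                      tissue = names(fold), stringsAsFactors = FALSE)
  grid$bio <- stats::rnorm(nrow(grid), 0, bio_sd)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tis <- grid$tissue[i]
    mu_t <- target_baseline - log2(fold[[tis]]) + grid$bio[i]
    data.frame(
      animal = grid$animal[i], tissue = tis,
      gene = rep(c(target, reference), each = n_tech),
      replicate = rep(seq_len(n_tech), 2),
      ct = c(mu_t + stats::rnorm(n_tech, 0, tech_sd),
             ref_baseline + stats::rnorm(n_tech, 0, tech_sd)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a homolog family along a random tree
#'
#' Draws a random topology with uniform branch lengths, places a random
#' ancestral sequence at the root and evolves it towards the tips: on a
#' branch of length t each site substitutes independently with
#' probability `min(1, subst_rate * t)`, to a base chosen uniformly among
#' the other three. Returns both the sequences and the generating tree so
#' distance/phylogeny code can be validated against the truth.
#'
#' @param n_taxa Number of tips.
#' @param seq_length Sites in the ancestral sequence.
#' @param subst_rate Per-site substitution probability per unit branch
#'   length.
#' @param brlen Range (min, max) of uniform branch lengths.
#' @param tree Optional `ape::phylo` tree to use instead of a random one
#'   (must have branch lengths).
#' @param seed Optional RNG seed.
#' @return List: `sequences` (named character vector, one per tip),
#'   `tree` (the generating `phylo`).
#' @export
gen_homolog_family <- function(n_taxa = 6, seq_length = 500,
                               subst_rate = 0.5, brlen = c(0.05, 0.3),
                               tree = NULL, seed = NULL) {
  stopifnot(n_taxa >= 2 || !is.null(tree), seq_length >= 1, subst_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree))
    tree <- ape::rtree(n_taxa, br = function(n) stats::runif(n, brlen[1],
                                                             brlen[2]))
  bases <- c("A", "C", "G", "T")
  root_seq <- sample(bases, seq_length, replace = TRUE)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_seq <- vector("list", ntip + tree$Nnode)
  node_seq[[root]] <- root_seq
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  edge_len <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    s <- node_seq[[parent]]
    q <- min(1, subst_rate * edge_len[e])
    hit <- which(stats::runif(length(s)) < q)
    if (length(hit)) {
      s[hit] <- vapply(s[hit], function(b)
        sample(setdiff(bases, b), 1), character(1))
    }
    node_seq[[child]] <- s
  }
  seqs <- vapply(seq_len(ntip), function(i) paste(node_seq[[i]],
                                                  collapse = ""),
                 character(1))
  names(seqs) <- tree$tip.label
  list(sequences = seqs, tree = tree)
}
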
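## ---------------------------------------------------------------------------
## comparative_stats: phylogenetic independent contrasts, contrast
## regression through the origin, and phylogenetic-signal statistics
## (Blomberg's K with permutation p, Pagel's lambda with LR test).
## ---------------------------------------------------------------------------

#' Phylogenetic independent contrasts of a tip trait
#'
#' Felsenstein's recursion (standardised contrasts with branch-length
#' augmentation of internal nodes, via [ape::pic()]). Polytomies are
#' resolved deterministically into zero-length bifurcations first.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param trait named numeric vector leaf -> value (complete).
#' @return list of class `contrast_set`: `contrasts` (named by node),
#'   `tree` (the resolved binary tree).
#' @export
pic_contrasts <- function(tree, trait) {
  tree <- name_nodes(tree)
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing))
    stop2("missing trait value for leaf: ", paste(missing, collapse = ", "))
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  x <- trait[tree$tip.label]
  pc <- ape::pic(x, tree)
  structure(list(contrasts = pc, tree = tree), class = "contrast_set")
}

#' Regression through the origin of one contrast set on another
#'
#' Least-squares regression of y-contrasts on x-contrasts with no
#' intercept (the only valid form for independent contrasts), with the
#' correlation and a two-sided p-value from the origin-constrained model.
#'
#' @param x,y `contrast_set` objects on the same tree.
#' @return list with `slope`, `r` (signed), `p`, `n` (number of
#'   contrasts).
#' @export
contrast_regression <- function(x, y) {
  xc <- x$contrasts; yc <- y$contrasts
  if (length(xc) != length(yc))
    stop2("contrast sets have different sizes")
  if (sum(xc^2) == 0) stop2("zero-variance x contrasts")
  fit <- stats::lm(yc ~ xc - 1)
  s <- summary(fit)
  slope <- unname(stats::coef(fit)[1])
  r <- sign(slope) * sqrt(max(0, s$r.squared))
  p <- unname(s$coefficients[1, 4])
  list(slope = slope, r = r, p = p, n = length(xc))
}

## Blomberg's K for a named tip trait (statistic via phytools).
k_statistic <- function(tree, trait) {
  unname(phytools::phylosig(tree, trait[tree$tip.label], method = "K"))
}

#' Blomberg's K with a tip-shuffling permutation test
#'
#' K compares the observed ratio of cross-tip variance to
#' phylogenetically corrected variance with its Brownian-motion
#' expectation (K near 1 under BM, near 0 without signal). The p-value is
#' the add-one-corrected fraction of tip-shuffled datasets whose K is at
#' least the observed one.
#'
#' @param tree rooted `phylo`.
#' @param trait named numeric vector leaf -> value.
#' @param n_permutations number of tip shuffles (>= 99; default 999).
#' @param seed integer seed.
#' @return list with `K`, `p`, `n_permutations`.
#' @export
blomberg_k <- function(tree, trait, n_permutations = 999L, seed = 1L) {
  tree <- name_nodes(tree)
  if (n_permutations < 99L) stop2("use at least 99 permutations")
  x <- trait[tree$tip.label]
  if (stats::sd(x) == 0)
    return(list(K = NA_real_, p = NA_real_,
                n_permutations = n_permutations,
                note = "constant trait: K undefined"))
  k_obs <- k_statistic(tree, x)
  withr::with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_permutations)) {
      xp <- stats::setNames(sample(x), names(x))
      if (k_statistic(tree, xp) >= k_obs) hits <- hits + 1L
    }
    list(K = k_obs, p = (hits + 1) / (n_permutations + 1),
         n_permutations = n_permutations)
  })
}

#' Pagel's lambda with a likelihood-ratio test against no signal
#'
#' Maximum-likelihood estimate of the multiplier on the off-diagonal
#' (shared-history) entries of the Brownian covariance, bounded between 0
#' and the largest value keeping the covariance positive definite, with a
#' likelihood-ratio p-value against lambda = 0 (via
#' [phytools::phylosig()]).
#'
#' @param tree rooted `phylo` (>= 4 leaves).
#' @param trait named numeric vector leaf -> value.
#' @return list with `lambda`, `logL`, `logL0`, `LR`, `p`.
#' @export
pagel_lambda <- function(tree, trait) {
  tree <- name_nodes(tree)
  if (length(tree$tip.label) < 4L) stop2("need at least 4 leaves")
  fit <- phytools::phylosig(tree, trait[tree$tip.label],
                            method = "lambda", test = TRUE)
  list(lambda = fit$lambda, logL = fit$logL, logL0 = fit$logL0,
       LR = max(0, 2 * (fit$logL - fit$logL0)), p = fit$P)
}

#' Relative kinase frequency per taxon
#'
#' Number of kinases of the unit of interest divided by the total number
#' of kinases detected in the proteome.
#' @param counts data.frame with columns `taxon`, `unit_count`,
#'   `total_kinases`.
#' @return named numeric vector taxon -> frequency in \[0, 1\].
#' @export
relative_kinase_frequency <- function(counts) {
  if (any(counts$total_kinases <= 0))
    stop2("total kinase counts must be positive")
  if (any(counts$unit_count < 0 |
          counts$unit_count > counts$total_kinases))
    stop2("unit counts must lie in [0, total]")
  stats::setNames(counts$unit_count / counts$total_kinases, counts$taxon)
}

#' Kinome-phosphoproteome coevolution test for one motif/kinase pair
#'
#' Convenience wrapper: contrasts of the motif enrichment values (log10
#' fold enrichment by default) against contrasts of the relative
#' frequency of the cognate kinase unit, regressed through the origin.
#' @param tree species tree.
#' @param enrichment named vector species -> motif enrichment value
#'   (e.g. log10 fold enrichment).
#' @param kinase_freq named vector species -> relative kinase frequency.
#' @return [contrast_regression()] result.
#' @export
coevolution_test <- function(tree, enrichment, kinase_freq) {
  contrast_regression(pic_contrasts(tree, kinase_freq),
                      pic_contrasts(tree, enrichment))
}
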
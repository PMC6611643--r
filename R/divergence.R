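## ---------------------------------------------------------------------------
## divergence_scoring: the per-position divergence statistic
##   S = RC - AC * p(AC)
## between a focal clade (A) and its nearest sister clade (B), plus switch
## calling, cross-comparison aggregation and functional-category tests.
## ---------------------------------------------------------------------------

#' Select the focal clade for a family or subfamily
#'
#' Finds the clade holding the most focal-label sequences while tolerating
#' fewer than 15% spurious (non-focal) leaves; when no such clade exists
#' (spurious leaves would be 15% or more everywhere useful), this descends
#' to the largest fully pure subclade automatically, because pure subclades
#' compete in the same maximisation.
#'
#' @param tree rooted `phylo` whose leaves appear in `labels$id`.
#' @param labels data.frame with columns `id` and the level column.
#' @param focal name of the family/subfamily of interest.
#' @param level `"family"` or `"subfamily"`.
#' @param max_spurious spurious leaves must be strictly below this fraction
#'   (default 0.15).
#' @param min_size minimum clade size for a scorable comparison (default 5).
#' @return list of class `clade_comparison` (sister not yet attached) with
#'   `node`, `leaves`, `purity`, `coverage`, `scorable`, `reason`.
#' @export
select_focal_clade <- function(tree, labels, focal,
                               level = c("family", "subfamily"),
                               max_spurious = 0.15, min_size = 5L) {
  level <- match.arg(level)
  tree <- name_nodes(tree)
  lab <- stats::setNames(labels[[level]], labels$id)
  focal_leaves <- tree$tip.label[lab[tree$tip.label] %in% focal]
  if (!length(focal_leaves)) stop2("no leaf carries label '", focal, "'")
  ntip <- length(tree$tip.label)
  best <- NULL
  for (v in seq_len(ntip + tree$Nnode)) {
    tips <- tips_under(tree, v)
    f <- sum(tree$tip.label[tips] %in% focal_leaves)
    if (f == 0) next
    s <- length(tips) - f
    if (s / length(tips) >= max_spurious) next
    if (is.null(best) || f > best$f ||
        (f == best$f && s < best$s)) best <- list(v = v, f = f, s = s)
  }
  out <- list(focal = focal, level = level, node = node_name(tree, best$v),
              leaves = tree$tip.label[tips_under(tree, best$v)],
              purity = best$f / (best$f + best$s),
              coverage = best$f / length(focal_leaves),
              scorable = TRUE, reason = NA_character_)
  if (best$f < min_size) {
    out$scorable <- FALSE
    out$reason <- paste0("fewer than ", min_size, " focal sequences in clade")
  }
  class(out) <- "clade_comparison"
  out
}

#' Attach the nearest sister clade to a focal-clade candidate
#'
#' The sister is the other child subtree of the focal clade's parent (the
#' largest one at a polytomy). The comparison is valid only if both clades
#' hold at least `min_size` sequences and, below the top level, the two
#' clades' dominant labels share the same parent-level label (sister
#' subfamilies must belong to the same family; sister families to the same
#' group).
#'
#' @param tree rooted `phylo`.
#' @param candidate result of [select_focal_clade()].
#' @param labels data.frame with `id`, `group`, `family`, `subfamily`.
#' @param min_size minimum sequences per clade (default 5).
#' @return completed `clade_comparison` with `sister_node`, `sister_leaves`,
#'   `ancestor_A`, `ancestor_B`, `scorable`, `reason`.
#' @export
select_sister_clade <- function(tree, candidate, labels, min_size = 5L) {
  tree <- name_nodes(tree)
  if (!isTRUE(candidate$scorable)) return(candidate)
  v <- node_number(tree, candidate$node)
  if (v == root_node(tree)) {
    candidate$scorable <- FALSE
    candidate$reason <- "focal clade is the whole tree"
    return(candidate)
  }
  par <- parent_vector(tree)[v]
  sibs <- setdiff(tree$edge[tree$edge[, 1] == par, 2], v)
  sizes <- vapply(sibs, function(s) length(tips_under(tree, s)), 0L)
  sister <- sibs[which.max(sizes)]
  sister_leaves <- tree$tip.label[tips_under(tree, sister)]
  candidate$sister_node <- node_name(tree, sister)
  candidate$sister_leaves <- sister_leaves
  candidate$ancestor_A <- candidate$node
  candidate$ancestor_B <- candidate$sister_node
  if (length(candidate$leaves) < min_size ||
      length(sister_leaves) < min_size) {
    candidate$scorable <- FALSE
    candidate$reason <- paste0("both clades must contain ", min_size,
                               " or more sequences")
    return(candidate)
  }
  parent_level <- switch(candidate$level, family = "group",
                         subfamily = "family")
  dom <- function(leaves) {
    x <- labels[[parent_level]][match(leaves, labels$id)]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_character_)
    names(sort(table(x), decreasing = TRUE))[1]
  }
  a <- dom(candidate$leaves); b <- dom(sister_leaves)
  if (is.na(a) || is.na(b) || a != b) {
    candidate$scorable <- FALSE
    candidate$reason <- paste0("sister clade belongs to a different ",
                               parent_level)
  }
  candidate
}

#' Recent conservation of one alignment column within a clade
#'
#' Mean over all unordered sequence pairs of the substitution-matrix
#' similarity of their residues, with the matrix rescaled linearly so its
#' minimum maps to 0 and maximum to 1; pairs involving a gap contribute 0.
#' @param residues character vector of clade residues at the column
#'   (gap = `-`).
#' @param matrix 20 x 20 similarity matrix rescaled to \[0, 1\]
#'   (default BLOSUM62).
#' @return RC in \[0, 1\], or `NA` if fewer than 2 residues are non-gap.
#' @export
recent_conservation <- function(residues, matrix = rescaled_blosum62()) {
  res <- residues[residues %in% AA20]
  if (length(res) < 2L) return(NA_real_)
  n <- length(residues)
  total <- 0
  cnt <- table(factor(res, levels = AA20))
  nz <- names(cnt)[cnt > 0]
  for (i in seq_along(nz)) for (j in i:length(nz)) {
    a <- nz[i]; b <- nz[j]
    npair <- if (a == b) cnt[[a]] * (cnt[[a]] - 1) / 2 else cnt[[a]] * cnt[[b]]
    total <- total + npair * matrix[a, b]
  }
  total / (n * (n - 1) / 2)
}

#' Ancestral agreement between the two clade ancestors at one column
#'
#' `AC = +1` when the predicted ancestral residues of clades A and B are
#' identical, `-1` otherwise. Its confidence weight `p(AC)` is the
#' posterior probability of clade B's predicted residue when they match,
#' and the summed posterior of all residues other than clade A's predicted
#' residue when they differ.
#' @param residue_A,residue_B predicted ancestral residues (a gap or other
#'   non-residue symbol never matches a residue).
#' @param posterior_B clade-B posterior vector over AA20 (sums to 1).
#' @return list with `AC` (+1/-1) and `p_AC` in \[0, 1\].
#' @export
ancestral_agreement <- function(residue_A, residue_B, posterior_B) {
  pb <- function(r) {
    i <- match(r, names(posterior_B) %||% AA20)
    if (is.na(i)) 0 else unname(posterior_B[i])
  }
  if (identical(residue_A, residue_B) && residue_A %in% AA20) {
    list(AC = 1, p_AC = pb(residue_B))
  } else {
    list(AC = -1, p_AC = 1 - pb(residue_A))
  }
}

#' Per-column divergence scores for one clade comparison
#'
#' Computes, for every alignment column, `S = RC - AC * p(AC)`: recent
#' conservation of clade A minus the ancestral-agreement term between the
#' two clade ancestors. Columns where RC is undefined (fewer than two
#' non-gap residues in clade A) or where an ancestral entry is missing are
#' skipped and logged.
#'
#' @param comparison scorable `clade_comparison`.
#' @param aln `kinase_alignment`.
#' @param anc `ancestral_states` containing both ancestors.
#' @param matrix rescaled similarity matrix for RC (default BLOSUM62).
#' @return data.frame of class `divergence_scores` with columns `column`,
#'   `domain_position`, `RC`, `AC`, `p_AC`, `S`; attributes `comparison`
#'   and `skipped` (skipped columns).
#' @export
divergence_scores <- function(comparison, aln, anc,
                              matrix = rescaled_blosum62()) {
  if (!isTRUE(comparison$scorable))
    stop2("comparison is not scorable: ", comparison$reason)
  for (nd in c(comparison$ancestor_A, comparison$ancestor_B))
    if (is.null(anc$post[[nd]]))
      stop2("ancestor '", nd, "' missing from ancestral table")
  sub <- aln$mat[comparison$leaves, , drop = FALSE]
  ncols <- ncol(sub)
  stateA <- anc$state[[comparison$ancestor_A]]
  stateB <- anc$state[[comparison$ancestor_B]]
  postB <- anc$post[[comparison$ancestor_B]]
  rows <- vector("list", ncols)
  skipped <- integer(0)
  for (j in seq_len(ncols)) {
    rc <- recent_conservation(sub[, j], matrix)
    if (is.na(rc) || j > length(stateA) || j > length(stateB)) {
      skipped <- c(skipped, j)
      next
    }
    ag <- ancestral_agreement(stateA[j], stateB[j], postB[, j])
    rows[[j]] <- data.frame(column = j,
                            domain_position = aln$column_map[j],
                            RC = rc, AC = ag$AC, p_AC = ag$p_AC,
                            S = rc - ag$AC * ag$p_AC)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  attr(out, "comparison") <- comparison
  attr(out, "skipped") <- skipped
  class(out) <- c("divergence_scores", class(out))
  out
}

#' Call switches and aggregate them per domain position
#'
#' Pools the divergence scores of all comparisons at one level (after
#' collapsing comparisons that share the same unordered pair of ancestral
#' nodes, so a switch event is counted once), sets the threshold at the
#' 95th percentile (linear-interpolation quantile) of the pooled scores,
#' calls a (comparison, column) a switch when its score strictly exceeds
#' the threshold, and counts switches per kinase-domain position.
#'
#' @param tables list of `divergence_scores`.
#' @param level `"family"` or `"subfamily"` (annotation only).
#' @param percentile switch percentile (default 0.95).
#' @param n_positions domain length for the profile (default 246).
#' @return list of class `switch_profile` with `level`, `threshold`,
#'   `counts` (named integer vector per domain position) and `switches`
#'   (data.frame of the individual switch calls).
#' @export
call_switches <- function(tables, level = c("family", "subfamily"),
                          percentile = 0.95, n_positions = 246L) {
  level <- match.arg(level)
  if (!length(tables)) stop2("at least one score table required")
  key <- vapply(tables, function(tb) {
    cmp <- attr(tb, "comparison")
    paste(sort(c(cmp$ancestor_A, cmp$ancestor_B)), collapse = "|")
  }, "")
  tables <- tables[!duplicated(key)]
  pooled <- unlist(lapply(tables, function(tb) tb$S), use.names = FALSE)
  threshold <- interp_quantile(pooled, percentile)
  counts <- stats::setNames(integer(n_positions),
                            as.character(seq_len(n_positions)))
  calls <- list()
  for (tb in tables) {
    hit <- tb$S > threshold & !is.na(tb$domain_position)
    if (!any(hit)) next
    cmp <- attr(tb, "comparison")
    calls[[length(calls) + 1L]] <-
      data.frame(focal = cmp$focal, domain_position = tb$domain_position[hit],
                 S = tb$S[hit])
    dp <- tb$domain_position[hit]
    dp <- dp[dp >= 1 & dp <= n_positions]
    tabdp <- table(dp)
    counts[names(tabdp)] <- counts[names(tabdp)] + as.integer(tabdp)
  }
  structure(list(level = level, threshold = threshold, counts = counts,
                 switches = do.call(rbind, calls)),
            class = "switch_profile")
}

#' Frequently switching domain positions
#'
#' Positions whose switch count strictly exceeds the 90th percentile of the
#' counts across the whole domain.
#' @param profile `switch_profile`.
#' @param percentile percentile of the counts (default 0.90).
#' @return integer vector of domain positions.
#' @export
frequently_switching <- function(profile, percentile = 0.90) {
  thr <- interp_quantile(profile$counts, percentile)
  as.integer(names(profile$counts)[profile$counts > thr])
}

#' Functional-category enrichment tests for switch profiles
#'
#' (a) One-sided Fisher's exact test on the 2x2 table of frequently
#' switching vs not, crossed with membership of any named functional
#' category vs `other`. (b) One-tailed Mann-Whitney test (normal
#' approximation with tie correction) comparing the switch counts of one
#' chosen category against `other`.
#'
#' @param profile `switch_profile`.
#' @param frequent integer vector from [frequently_switching()].
#' @param categories category map from [functional_categories()].
#' @param mw_category category whose counts are compared to `other`
#'   (default `"proximal"`).
#' @return list with `fisher` (2x2 `table`, `p`) and `mann_whitney`
#'   (`U`, `p`).
#' @export
category_tests <- function(profile, frequent, categories,
                           mw_category = "proximal") {
  pos <- as.integer(names(profile$counts))
  cat_of <- categories[as.character(pos)]
  if (any(is.na(cat_of) | cat_of == ""))
    stop2("categories must cover all domain positions")
  named <- cat_of != "other"
  freq <- pos %in% frequent
  tab <- matrix(c(sum(freq & named), sum(freq & !named),
                  sum(!freq & named), sum(!freq & !named)),
                2, 2, byrow = TRUE,
                dimnames = list(c("frequent", "not_frequent"),
                                c("named_category", "other")))
  fisher_p <- stats::fisher.test(tab, alternative = "greater")$p.value
  if (!any(cat_of == mw_category))
    stop2("category '", mw_category, "' is empty")
  x <- profile$counts[cat_of == mw_category]
  y <- profile$counts[cat_of == "other"]
  mw <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                           correct = FALSE)
  list(fisher = list(table = tab, p = fisher_p),
       mann_whitney = list(U = unname(mw$statistic), p = mw$p.value))
}
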
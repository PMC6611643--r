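## ---------------------------------------------------------------------------
## specificity_models: PWMs over the 14 flank positions of 15-mer target
## sites, Frobenius-distance comparisons, the subsampling-derived
## specificity-divergence threshold, and identity-vs-distance analysis.
## ---------------------------------------------------------------------------

#' Build a position weight matrix from target-site 15-mers
#'
#' Per flank position (-7..-1, +1..+7), column probabilities are
#' `(count + pseudocount) / (n_eff + 20 * pseudocount)` where `n_eff` is
#' the number of non-padding characters at that position. The centre
#' column is excluded; its S:T ratio is recorded.
#'
#' @param sites character vector of 15-mers (centres all S/T).
#' @param kinase kinase identifier.
#' @param min_sites minimum number of sites (default 10).
#' @param pseudocount per-residue pseudocount (default 0.5).
#' @param group,family,subfamily optional classification labels.
#' @return object of class `kinase_pwm`: `matrix` (20 x 14; rows AA20,
#'   columns -7..-1, 1..7), `n_sites`, `st_ratio` (S count / T count),
#'   labels.
#' @export
build_pwm <- function(sites, kinase = "kinase", min_sites = 10L,
                      pseudocount = 0.5, group = NA_character_,
                      family = NA_character_, subfamily = NA_character_) {
  if (length(sites) < min_sites)
    stop2("kinase '", kinase, "': ", length(sites),
          " sites, fewer than the required ", min_sites)
  m <- site_matrix(sites)
  centre <- m[, 8]
  if (!all(centre %in% c("S", "T")))
    stop2("kinase '", kinase, "': all site centres must be S or T")
  pwm <- matrix(0, 20, 14, dimnames = list(AA20, as.character(FLANK_POS)))
  for (j in seq_along(FLANK_POS)) {
    chars <- m[, FLANK_POS[j] + 8L]
    chars <- chars[chars %in% AA20]
    cnt <- table(factor(chars, levels = AA20))
    pwm[, j] <- (as.numeric(cnt) + pseudocount) /
      (length(chars) + 20 * pseudocount)
  }
  st <- sum(centre == "S") / max(1L, sum(centre == "T"))
  structure(list(kinase = kinase, group = group, family = family,
                 subfamily = subfamily, matrix = pwm,
                 n_sites = length(sites), st_ratio = st),
            class = "kinase_pwm")
}

#' @export
print.kinase_pwm <- function(x, ...) {
  cat("kinase_pwm:", x$kinase, "(", x$n_sites, "sites )\n")
  invisible(x)
}

#' Frobenius distance between two specificity models
#'
#' The square root of the summed squared elementwise differences between
#' the two probability matrices.
#' @param a,b `kinase_pwm` objects (or bare matrices) of identical shape.
#' @return nonnegative distance; 0 iff the matrices are equal.
#' @export
frobenius_distance <- function(a, b) {
  ma <- if (inherits(a, "kinase_pwm")) a$matrix else a
  mb <- if (inherits(b, "kinase_pwm")) b$matrix else b
  if (!all(dim(ma) == dim(mb)))
    stop2("specificity matrices have different shapes")
  sqrt(sum((ma - mb)^2))
}

#' Derive the specificity-divergence threshold by same-kinase subsampling
#'
#' For every kinase with at least `min_sites` annotated target sites, two
#' independent subsamples of `subsample_size` sites are drawn (each without
#' replacement) `n_draws` times; a PWM is built from each and their
#' Frobenius distance recorded. The threshold is the maximum distance
#' observed over all kinases and draws — the largest divergence explainable
#' by sampling noise alone.
#'
#' @param site_sets named list: kinase -> character vector of 15-mer sites.
#' @param subsample_size sites per subsample (default 25).
#' @param n_draws draws per kinase (default 100).
#' @param min_sites minimum annotated sites for inclusion (default 50).
#' @param pseudocount pseudocount used for every PWM (must match the
#'   setting used for the compared models).
#' @param seed integer seed.
#' @return numeric threshold; attribute `distances` holds all recorded
#'   same-kinase distances, attribute `excluded` the skipped kinases.
#' @export
derive_threshold <- function(site_sets, subsample_size = 25L,
                             n_draws = 100L, min_sites = 50L,
                             pseudocount = 0.5, seed = 1L) {
  sizes <- lengths(site_sets)
  excluded <- names(site_sets)[sizes < min_sites]
  site_sets <- site_sets[sizes >= min_sites]
  if (!length(site_sets))
    stop2("no kinase has ", min_sites, " or more sites")
  withr::with_seed(seed, {
    d <- lapply(names(site_sets), function(k) {
      sites <- site_sets[[k]]
      vapply(seq_len(n_draws), function(i) {
        s1 <- sample(sites, subsample_size)
        s2 <- sample(sites, subsample_size)
        frobenius_distance(
          build_pwm(s1, k, min_sites = 1L, pseudocount = pseudocount),
          build_pwm(s2, k, min_sites = 1L, pseudocount = pseudocount))
      }, 0)
    })
    d <- unlist(d)
    structure(max(d), distances = d, excluded = excluded)
  })
}

## Label of a model at a level, and at the parent level.
pwm_label <- function(model, level) model[[level]]
parent_level_of <- c(group = NA, family = "group", subfamily = "family")

#' Within- vs between-grouping specificity distances at one level
#'
#' Computes all pairwise Frobenius distances within each grouping at the
#' given level, and between groupings that share the parent-level label
#' (families are only compared within a group, subfamilies within a
#' family), then contrasts the two distance samples with a two-sided
#' Kolmogorov-Smirnov test.
#'
#' @param models list of `kinase_pwm` with classification labels.
#' @param level `"group"`, `"family"` or `"subfamily"`.
#' @return list of class `specificity_report`: `level`, `within`,
#'   `between` (numeric distance vectors), `ks` (statistic, p), `pairs`
#'   (data.frame of all compared pairs).
#' @export
pairwise_level_analysis <- function(models,
                                    level = c("group", "family",
                                              "subfamily")) {
  level <- match.arg(level)
  labs <- vapply(models, pwm_label, "", level = level)
  keep <- !is.na(labs)
  models <- models[keep]; labs <- labs[keep]
  groupings <- unique(labs)
  if (length(groupings) < 2L)
    stop2("need at least 2 groupings with models at level '", level, "'")
  parent <- parent_level_of[[level]]
  plabs <- if (is.na(parent)) rep("", length(models))
           else vapply(models, pwm_label, "", level = parent)
  rows <- list()
  n <- length(models)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- labs[i] == labs[j]
    if (!same && !identical(plabs[i], plabs[j])) next
    if (!same && (is.na(plabs[i]) || is.na(plabs[j]))) next
    rows[[length(rows) + 1L]] <- data.frame(
      a = models[[i]]$kinase, b = models[[j]]$kinase,
      type = if (same) "within" else "between",
      distance = frobenius_distance(models[[i]], models[[j]]))
  }
  pairs <- do.call(rbind, rows)
  within <- pairs$distance[pairs$type == "within"]
  between <- pairs$distance[pairs$type == "between"]
  ks <- if (length(within) && length(between))
    suppressWarnings(stats::ks.test(within, between))
  else list(statistic = NA_real_, p.value = NA_real_)
  structure(list(level = level, within = within, between = between,
                 ks = list(statistic = unname(ks$statistic),
                           p = ks$p.value),
                 pairs = pairs),
            class = "specificity_report")
}

#' Sequence identity vs specificity distance across kinase pairs
#'
#' For every pair of models whose kinases appear in the alignment: percent
#' identity over the chosen domain-position subset, and the Frobenius
#' distance between their PWMs. Reports the Pearson correlation and a
#' binned specificity-divergence curve (fraction of pairs whose distance
#' exceeds the threshold, per identity bin).
#'
#' @param models list of `kinase_pwm` whose `kinase` ids are alignment rows.
#' @param aln `kinase_alignment`.
#' @param position_subset integer domain positions over which identity is
#'   computed (denominator = subset size).
#' @param threshold divergence threshold (default the 1.06 operating
#'   constant; synthetic pipelines should pass [derive_threshold()] output).
#' @param bins identity bin breaks (default 0,10,...,100).
#' @return list with `pairs` (identity, distance per pair), `r`, `p`
#'   (Pearson; `NA` with an explanation when variance is zero) and `curve`
#'   (per-bin fraction of diverged pairs).
#' @export
identity_vs_distance <- function(models, aln, position_subset,
                                 threshold = SPECIFICITY_DIVERGENCE_THRESHOLD,
                                 bins = seq(0, 100, 10)) {
  if (!length(position_subset)) stop2("empty domain-position subset")
  cols <- match(position_subset, aln$column_map)
  if (anyNA(cols))
    stop2("domain position(s) not mapped: ",
          paste(position_subset[is.na(cols)], collapse = ", "))
  ids <- vapply(models, `[[`, "", "kinase")
  missing <- setdiff(ids, rownames(aln$mat))
  if (length(missing))
    stop2("kinase(s) missing from alignment: ",
          paste(missing, collapse = ", "))
  n <- length(models)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- aln$mat[ids[i], cols]; b <- aln$mat[ids[j], cols]
    ident <- 100 * sum(a == b & a %in% AA20) / length(cols)
    rows[[length(rows) + 1L]] <- data.frame(
      a = ids[i], b = ids[j], identity = ident,
      distance = frobenius_distance(models[[i]], models[[j]]))
  }
  pairs <- do.call(rbind, rows)
  sdd <- stats::sd(pairs$distance); sdi <- stats::sd(pairs$identity)
  if (nrow(pairs) < 3 || is.na(sdd) || sdd == 0 || sdi == 0) {
    r <- NA_real_; p <- NA_real_
    note <- "correlation undefined: zero variance in identity or distance"
  } else {
    ct <- stats::cor.test(pairs$identity, pairs$distance)
    r <- unname(ct$estimate); p <- ct$p.value; note <- NA_character_
  }
  bin <- cut(pairs$identity, breaks = bins, include.lowest = TRUE)
  curve <- tapply(pairs$distance > threshold, bin, mean)
  list(pairs = pairs, r = r, p = p, note = note,
       curve = data.frame(bin = names(curve),
                          diverged_fraction = as.numeric(curve)))
}
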
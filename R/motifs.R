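## ---------------------------------------------------------------------------
## motif_analysis: shuffled-flank backgrounds, motif matching, the
## superset-conditioned binomial enrichment statistic, greedy motif
## discovery, the cross-species filtering protocol, and phosphoproteome
## coverage.
## ---------------------------------------------------------------------------

#' Construct a phosphorylation motif pattern
#'
#' A degenerate positional pattern over the 15-mer window: the centre is
#' fixed to S/T; each constrained flank position carries a nonempty residue
#' class. The padding character never matches any class.
#'
#' @param constraints named list: flank position (`-7..-1`, `1..7`, as
#'   names) -> character vector of residues.
#' @return object of class `kinase_motif`.
#' @export
motif_pattern <- function(constraints) {
  if (!length(constraints)) stop2("a motif needs >= 1 constrained position")
  pos <- as.integer(names(constraints))
  if (anyNA(pos) || any(pos == 0L) || any(abs(pos) > 7L))
    stop2("constraint positions must be in -7..7, excluding 0")
  constraints <- constraints[order(pos)]
  for (k in seq_along(constraints)) {
    cls <- sort(unique(toupper(constraints[[k]])))
    if (!length(cls) || !all(cls %in% AA20))
      stop2("residue classes must be nonempty subsets of the 20 residues")
    constraints[[k]] <- cls
  }
  structure(list(constraints = constraints), class = "kinase_motif")
}

#' Render a motif in dash notation (e.g. `R-x-x-S/T-P`)
#' @param motif `kinase_motif`.
#' @return character scalar; class members joined by `/`, unconstrained
#'   positions between the outermost constraints shown as `x`, centre as
#'   `S/T`.
#' @export
format_motif <- function(motif) {
  pos <- as.integer(names(motif$constraints))
  lo <- min(c(pos, 0L)); hi <- max(c(pos, 0L))
  tokens <- vapply(lo:hi, function(p) {
    if (p == 0L) return("S/T")
    cls <- motif$constraints[[as.character(p)]]
    if (is.null(cls)) "x" else paste(cls, collapse = "/")
  }, "")
  paste(tokens, collapse = "-")
}

#' @export
print.kinase_motif <- function(x, ...) {
  cat("kinase_motif:", format_motif(x), "\n")
  invisible(x)
}

#' Parse dash notation into a motif pattern
#'
#' The centre is the first token equal to `S/T`; remaining tokens are
#' residue classes (members joined by `/`) or `x` for unconstrained
#' positions.
#' @param text e.g. `"R-x-x-S/T-P"`.
#' @export
parse_motif <- function(text) {
  tokens <- strsplit(text, "-", fixed = TRUE)[[1]]
  centre <- which(tokens == "S/T")[1]
  if (is.na(centre)) stop2("motif '", text, "' has no S/T centre token")
  constraints <- list()
  for (i in seq_along(tokens)) {
    if (i == centre || tokens[i] == "x") next
    constraints[[as.character(i - centre)]] <-
      strsplit(tokens[i], "/", fixed = TRUE)[[1]]
  }
  motif_pattern(constraints)
}

#' Generate a shuffled-flank background collection
#'
#' For each foreground site, `shuffles_per_site` random permutations of the
#' 14 flank characters with the central S/T retained, so foreground and
#' background have identical amino-acid composition. Padding characters are
#' shuffled along with residues.
#'
#' @param fore `phosphosite_set` foreground.
#' @param shuffles_per_site permutations per site (default 10).
#' @param seed integer seed.
#' @return `phosphosite_set` (duplicates retained); attribute `source`
#'   gives, per background site, the index of its foreground site.
#' @export
generate_background <- function(fore, shuffles_per_site = 10L, seed = 1L) {
  m <- site_matrix(fore$sites)
  n <- nrow(m)
  withr::with_seed(seed, {
    out <- matrix("", n * shuffles_per_site, 15)
    for (i in seq_len(n)) {
      fl <- m[i, c(1:7, 9:15)]
      for (k in seq_len(shuffles_per_site)) {
        r <- (i - 1L) * shuffles_per_site + k
        sh <- sample(fl)
        out[r, ] <- c(sh[1:7], m[i, 8], sh[8:14])
      }
    }
    bg <- phosphosite_set(paste0(fore$species, "_background"),
                          apply(out, 1, paste, collapse = ""),
                          unique_sites = FALSE)
    attr(bg, "source") <- rep(seq_len(n), each = shuffles_per_site)
    bg
  })
}

## Logical match vector of a motif against an n x 15 site matrix.
match_matrix <- function(motif, m) {
  ok <- rep(TRUE, nrow(m))
  for (pos in names(motif$constraints)) {
    col <- as.integer(pos) + 8L
    ok <- ok & m[, col] %in% motif$constraints[[pos]]
  }
  ok
}

#' Does a site match a motif?
#'
#' Every constrained position's character must belong to its residue class;
#' unconstrained positions are free; the padding character matches nothing.
#' @param motif `kinase_motif`.
#' @param sites character vector of 15-mers.
#' @return logical vector.
#' @export
match_motif <- function(motif, sites) {
  match_matrix(motif, site_matrix(sites))
}

#' Superset-conditioned binomial enrichment of a motif
#'
#' The null probability of the motif is its match frequency in the
#' background, conditioned on the most frequent superset motif — the motif
#' with one constrained position removed, choosing the removal that
#' maximises background matches (for a single-constraint motif the superset
#' is the bare S/T centre, i.e. all sites). With `k` foreground motif
#' matches out of `n` foreground superset matches and null probability
#' `p0 = background motif matches / background superset matches`, the
#' p-value is the upper binomial tail `P(Bin(n, p0) >= k)`.
#'
#' @param motif `kinase_motif`.
#' @param fore,back `phosphosite_set` foreground and background.
#' @return list of class `enrichment_result`: `motif`, `species`, `k`, `n`,
#'   `back_motif`, `back_superset`, `p0`, `p_value`, `fold`,
#'   `superset` (the chosen superset motif, `NULL` for the bare centre),
#'   `testable`.
#' @export
superset_binomial <- function(motif, fore, back) {
  if (!length(back$sites)) stop2("background is empty")
  fm <- site_matrix(fore$sites)
  bm <- site_matrix(back$sites)
  k <- sum(match_matrix(motif, fm))
  b_motif <- sum(match_matrix(motif, bm))
  cons <- names(motif$constraints)
  if (length(cons) == 1L) {
    superset <- NULL
    n <- nrow(fm); b_sup <- nrow(bm)
  } else {
    sup_counts <- vapply(cons, function(drop) {
      sup <- motif_pattern(motif$constraints[setdiff(cons, drop)])
      sum(match_matrix(sup, bm))
    }, 0)
    drop <- cons[which.max(sup_counts)]
    superset <- motif_pattern(motif$constraints[setdiff(cons, drop)])
    b_sup <- max(sup_counts)
    n <- sum(match_matrix(superset, fm))
  }
  if (b_sup == 0) {
    return(structure(list(motif = motif, species = fore$species, k = k,
                          n = n, back_motif = b_motif, back_superset = 0,
                          p0 = NA_real_, p_value = NA_real_,
                          fold = NA_real_, superset = superset,
                          testable = FALSE),
                     class = "enrichment_result"))
  }
  p0 <- b_motif / b_sup
  p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  fold <- if (n > 0 && p0 > 0) (k / n) / p0 else NA_real_
  structure(list(motif = motif, species = fore$species, k = k, n = n,
                 back_motif = b_motif, back_superset = b_sup, p0 = p0,
                 p_value = p, fold = fold, superset = superset,
                 testable = TRUE),
            class = "enrichment_result")
}

#' Greedy motif discovery from foreground vs shuffled background
#'
#' Motif-x style recursive extraction: repeatedly add the (position,
#' residue) constraint that minimises the binomial p-value of the added
#' constraint, with the null probability taken from the current background
#' subset; a constraint is accepted when its p-value is below `p_threshold`
#' and the constrained foreground keeps at least `min_occurrences` sites.
#' When no further constraint passes, the motif is emitted, its matching
#' sites removed from the foreground and the corresponding shuffles from
#' the background, and extraction restarts. Ties break on smaller p-value,
#' then smaller absolute position, then alphabetical residue.
#'
#' @param fore `phosphosite_set` foreground.
#' @param back `phosphosite_set` background (ideally from
#'   [generate_background()]; its `source` attribute links shuffles to
#'   foreground sites — without it, background sites matching the emitted
#'   motif are removed instead).
#' @param p_threshold constraint acceptance p-value (default 1e-6).
#' @param min_occurrences minimum foreground matches per motif (default 20).
#' @param null_conf confidence level for the step null: the null
#'   probability of a candidate constraint is the upper `null_conf`
#'   Beta-posterior quantile of the background frequency in the current
#'   background subset (uniform prior), not its point estimate. Deep
#'   constraints can leave few background matches, where a point estimate
#'   is unstable and near-zero cells would let spurious constraints
#'   through; the upper bound accepts a constraint only when its
#'   foreground enrichment exceeds what background-estimation noise could
#'   explain. With a large background subset the bound converges to the
#'   observed frequency.
#' @return list of discoveries, each with `motif`, `n_fore` (matches at
#'   emission), `step_p` (p-value per accepted constraint).
#' @export
discover_motifs <- function(fore, back, p_threshold = 1e-6,
                            min_occurrences = 20L, null_conf = 0.999) {
  F_all <- site_matrix(fore$sites)
  B_all <- site_matrix(back$sites)
  src <- attr(back, "source")
  f_idx <- seq_len(nrow(F_all))
  b_idx <- seq_len(nrow(B_all))
  flank_cols <- c(1:7, 9:15)
  out <- list()
  repeat {
    if (length(f_idx) < min_occurrences || !length(b_idx)) break
    Fc <- f_idx; Bc <- b_idx
    constraints <- list(); step_p <- numeric(0)
    repeat {
      free <- setdiff(flank_cols,
                      as.integer(names(constraints)) + 8L)
      best <- NULL
      nF <- length(Fc); nB <- length(Bc)
      for (col in free) {
        fk <- table(factor(F_all[Fc, col], levels = AA20))
        bk <- table(factor(B_all[Bc, col], levels = AA20))
        p0 <- stats::qbeta(null_conf, as.numeric(bk) + 1,
                           nB - as.numeric(bk) + 1)
        k <- as.numeric(fk)
        pv <- stats::pbinom(k - 1, nF, p0, lower.tail = FALSE)
        pv[k < min_occurrences] <- 1  # cannot yield an emittable motif
        for (r in which(pv < p_threshold)) {
          cand <- list(col = col, res = AA20[r], p = pv[r])
          if (is.null(best) || cand$p < best$p ||
              (cand$p == best$p &&
               (abs(cand$col - 8L) < abs(best$col - 8L) ||
                (abs(cand$col - 8L) == abs(best$col - 8L) &&
                 cand$res < best$res))))
            best <- cand
        }
      }
      if (is.null(best)) break
      constraints[[as.character(best$col - 8L)]] <- best$res
      step_p <- c(step_p, best$p)
      Fc <- Fc[F_all[Fc, best$col] == best$res]
      Bc <- Bc[B_all[Bc, best$col] == best$res]
    }
    if (!length(constraints)) break
    motif <- motif_pattern(constraints)
    out[[length(out) + 1L]] <-
      list(motif = motif, n_fore = length(Fc), step_p = step_p)
    ## remove matched sites and their shuffles before the next round
    hitF <- f_idx[match_matrix(motif, F_all[f_idx, , drop = FALSE])]
    f_idx <- setdiff(f_idx, hitF)
    if (!is.null(src)) {
      b_idx <- b_idx[!(src[b_idx] %in% hitF)]
    } else {
      hitB <- b_idx[match_matrix(motif, B_all[b_idx, , drop = FALSE])]
      b_idx <- setdiff(b_idx, hitB)
    }
  }
  out
}

## Default synonym classes used when merging motifs across species.
SYNONYM_CLASSES <- list(c("R", "K"), c("D", "E"), c("L", "I", "V", "M"))

## Map a residue class to its synonym-class representation (sorted union of
## the synonym groups its members belong to, singletons otherwise).
canonical_class <- function(cls, synonyms = SYNONYM_CLASSES) {
  out <- character(0)
  for (r in cls) {
    hit <- Filter(function(g) r %in% g, synonyms)
    out <- c(out, if (length(hit)) hit[[1]] else r)
  }
  sort(unique(out))
}

## Canonicalise a motif under the synonym classes.
canonical_motif <- function(motif, synonyms = SYNONYM_CLASSES) {
  motif_pattern(lapply(motif$constraints, canonical_class,
                       synonyms = synonyms))
}

## Default classical-motif list for the S/T-addition rule (literature
## motifs with known upstream kinases).
classical_motif_strings <- function() {
  c("S/T-P", "R-x-x-S/T", "S/T-D/E-x-D/E", "R-R-x-S/T", "S/T-P-x-K",
    "L-x-R-x-x-S/T", "R-x-R-x-x-S/T", "S/T-x-x-D/E", "K-R-x-x-S/T",
    "S/T-Q", "R-x-x-S/T-L/I/V", "G-S/T", "S/T-F")
}

## Is `small` a sub-pattern of `big` (same classes at small's positions)?
is_subpattern <- function(small, big) {
  for (pos in names(small$constraints)) {
    if (is.null(big$constraints[[pos]])) return(FALSE)
    if (!setequal(small$constraints[[pos]], big$constraints[[pos]]))
      return(FALSE)
  }
  TRUE
}

#' Filter discovered motifs across species
#'
#' Applies the cross-species motif retention protocol: motifs are first
#' merged across species under the synonym classes R/K, D/E and L/I/V/M;
#' a merged motif is retained when it appears in at least a third of the
#' species of some superphylum, or in at least `excavate_min` excavate
#' species. Motifs exclusive to superphyla represented by a single species
#' (amoebozoa, heterokonts) are discarded, as are motifs whose only
#' additions over a classical motif are S/T constraints (likely phosphosite
#' misassignment) and motifs that add only further D/E constraints to the
#' classic casein-kinase-2 motif S/T-D/E-x-D/E. Every decision is recorded.
#'
#' @param discoveries data.frame with columns `species` and `motif`
#'   (dash notation), one row per (species, discovered motif).
#' @param species_phyla data.frame with columns `species`, `superphylum`.
#' @param classical character vector of classical motifs in dash notation
#'   (default [classical_motif_strings()]).
#' @param excavate_min minimum excavate species (default 2).
#' @param phylum_fraction minimum fraction of a superphylum's species
#'   (default 1/3).
#' @param single_species_phyla superphyla that can never qualify a motif.
#' @return list of class `motif_catalog`: `motifs` (data.frame with the
#'   merged motif, species count, rule decisions, `retained`), `retained`
#'   (list of retained `kinase_motif`).
#' @export
filter_motifs <- function(discoveries, species_phyla,
                          classical = classical_motif_strings(),
                          excavate_min = 2L, phylum_fraction = 1 / 3,
                          single_species_phyla = c("amoebozoa",
                                                   "heterokonts")) {
  unknown <- setdiff(discoveries$species, species_phyla$species)
  if (length(unknown))
    stop2("species without superphylum: ", paste(unknown, collapse = ", "))
  phylum_of <- stats::setNames(species_phyla$superphylum,
                               species_phyla$species)
  phylum_sizes <- table(species_phyla$superphylum)
  classical_canon <- lapply(classical,
                            function(s) canonical_motif(parse_motif(s)))
  ## merge across species under synonym classes
  canon <- lapply(discoveries$motif,
                  function(s) canonical_motif(parse_motif(s)))
  key <- vapply(canon, format_motif, "")
  merged <- split(seq_along(key), key)
  rows <- list(); retained <- list()
  for (k in names(merged)) {
    idx <- merged[[k]]
    motif <- canon[[idx[1]]]
    spp <- unique(discoveries$species[idx])
    phyla <- phylum_of[spp]
    ## prevalence rules
    qualifying <- vapply(unique(phyla), function(ph) {
      if (ph %in% single_species_phyla) return(FALSE)
      n_in <- sum(phyla == ph)
      if (ph == "excavata") n_in >= excavate_min
      else n_in >= phylum_fraction * phylum_sizes[[ph]]
    }, TRUE)
    prevalent <- any(qualifying)
    exclusive_single <- all(phyla %in% single_species_phyla)
    ## S/T-addition rule: extras over some classical motif are all S/T
    st_addition <- any(vapply(classical_canon, function(cm) {
      if (!is_subpattern(cm, motif)) return(FALSE)
      extra <- setdiff(names(motif$constraints), names(cm$constraints))
      length(extra) > 0 &&
        all(vapply(extra, function(p)
          all(motif$constraints[[p]] %in% c("S", "T")), TRUE))
    }, TRUE))
    ## CK2 rule: only D/E additions to S/T-D/E-x-D/E
    ck2 <- canonical_motif(parse_motif("S/T-D/E-x-D/E"))
    ck2_addition <- is_subpattern(ck2, motif) && {
      extra <- setdiff(names(motif$constraints), names(ck2$constraints))
      length(extra) > 0 &&
        all(vapply(extra, function(p)
          all(motif$constraints[[p]] %in% c("D", "E")), TRUE))
    }
    keep <- prevalent && !exclusive_single && !st_addition && !ck2_addition
    rows[[length(rows) + 1L]] <- data.frame(
      motif = k, n_species = length(spp),
      species = paste(sort(spp), collapse = ","),
      prevalent = prevalent, exclusive_single_species = exclusive_single,
      st_addition = st_addition, ck2_de_addition = ck2_addition,
      retained = keep)
    if (keep) retained[[k]] <- motif
  }
  structure(list(motifs = do.call(rbind, rows), retained = retained),
            class = "motif_catalog")
}

#' Fraction of a phosphoproteome matched by the motif catalog
#'
#' Percentage of sites matching at least one eligible motif. Motifs with a
#' single constrained flank position are excluded (chance matches), except
#' the classic S/T-P and R-x-x-S/T signatures, which suffice for kinase
#' targeting on their own.
#'
#' @param catalog `motif_catalog` (or a bare list of `kinase_motif`).
#' @param sites `phosphosite_set`.
#' @return coverage percentage in \[0, 100\]; attribute `eligible` lists
#'   the motifs used.
#' @export
phosphoproteome_coverage <- function(catalog, sites) {
  if (!length(sites$sites)) stop2("empty site collection")
  motifs <- if (inherits(catalog, "motif_catalog")) catalog$retained
            else catalog
  exceptions <- c(format_motif(parse_motif("S/T-P")),
                  format_motif(parse_motif("R-x-x-S/T")))
  eligible <- Filter(function(m) {
    length(m$constraints) >= 2L || format_motif(m) %in% exceptions
  }, motifs)
  m <- site_matrix(sites$sites)
  hit <- rep(FALSE, nrow(m))
  for (mo in eligible) hit <- hit | match_matrix(mo, m)
  structure(100 * mean(hit),
            eligible = vapply(eligible, format_motif, ""))
}
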
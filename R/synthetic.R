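## ---------------------------------------------------------------------------
## synthetic_data: generators for every input the pipeline consumes.
## All generators are pure functions of their arguments and seed (the RNG
## state of the caller is untouched; one stream per call, fixed traversal
## order).
## ---------------------------------------------------------------------------

#' Simulate a family alignment with implanted specificity switches
#'
#' Sequences evolve down the tree under the given substitution model, with
#' the expected number of substitutions on a branch equal to
#' `rate * branch length`. After the branch leading into each named clade,
#' the implanted residue is fixed at the given column in the clade's root
#' and every descendant node and leaf — the burst-after-duplication
#' scenario the divergence score is designed to detect.
#'
#' @param tree rooted `phylo` with branch lengths (internal nodes are
#'   auto-named if unnamed).
#' @param n_columns root sequence length.
#' @param rate expected substitutions per site per unit branch length.
#' @param switches data.frame with columns `clade` (node or leaf name),
#'   `column`, `residue`; may be empty.
#' @param model `subst_model` (default Poisson).
#' @param seed integer seed.
#' @param posterior_noise optional Dirichlet concentration: if given, the
#'   returned ancestral posteriors are Dirichlet draws centred on the true
#'   residue (alpha = `posterior_noise` on the true residue, 1 elsewhere)
#'   instead of point masses.
#' @return list with `alignment` (a [kinase_alignment()]; each leaf is
#'   labelled with the root-child subtree it belongs to as its family),
#'   `ancestral` (an [ancestral_states()] table holding the true simulated
#'   states), and `switches` (the implanted (clade, column, residue) set).
#' @export
simulate_family_alignment <- function(tree, n_columns, rate,
                                      switches = NULL,
                                      model = subst_model("poisson"),
                                      seed = 1L,
                                      posterior_noise = NULL) {
  tree <- name_nodes(tree)
  if (!is.null(switches) && nrow(switches)) {
    for (cl in switches$clade) node_number(tree, cl)  # validate
    if (any(switches$column > n_columns | switches$column < 1))
      stop2("implanted switch column outside sequence length")
  }
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  withr::with_seed(seed, {
    states <- matrix(NA_integer_, n_nodes, n_columns)
    r <- root_node(tree)
    states[r, ] <- sample.int(20, n_columns, replace = TRUE,
                              prob = model$pi)
    po <- ape::reorder.phylo(tree, "postorder")
    blen <- edge_length_into(tree)
    pre_edges <- rev(seq_len(nrow(po$edge)))
    for (ei in pre_edges) {
      par <- po$edge[ei, 1]; ch <- po$edge[ei, 2]
      P <- prob_matrix(model, rate * blen[ch])
      ## evolve each site given the parent state
      for (s in unique(states[par, ])) {
        idx <- which(states[par, ] == s)
        states[ch, idx] <- sample.int(20, length(idx), replace = TRUE,
                                      prob = P[s, ])
      }
    }
    if (!is.null(switches) && nrow(switches)) {
      for (k in seq_len(nrow(switches))) {
        v <- node_number(tree, switches$clade[k])
        members <- c(v, setdiff(descendant_nodes(tree, v), v))
        states[members, switches$column[k]] <-
          match(switches$residue[k], AA20)
      }
    }
    ## leaf labels: family = root-child subtree containing the leaf
    root_children <- tree$edge[tree$edge[, 1] == r, 2]
    fam <- rep(NA_character_, ntip)
    for (rc in root_children)
      fam[tips_under(tree, rc)] <- node_name(tree, rc)
    seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1,
                  function(z) paste(AA20[z], collapse = ""))
    names(seqs) <- tree$tip.label
    labels <- data.frame(id = tree$tip.label, species = tree$tip.label,
                         group = "SIM", family = fam,
                         subfamily = NA_character_)
    aln <- kinase_alignment(seqs, labels)
    ## true ancestral states, posterior 1 (or Dirichlet noise around truth)
    post <- list(); state <- list()
    for (v in (ntip + 1):n_nodes) {
      nm <- tree$node.label[v - ntip]
      p <- matrix(0, 20, n_columns, dimnames = list(AA20, NULL))
      p[cbind(states[v, ], seq_len(n_columns))] <- 1
      if (!is.null(posterior_noise)) {
        alpha <- matrix(1, 20, n_columns)
        alpha[cbind(states[v, ], seq_len(n_columns))] <- posterior_noise
        g <- matrix(stats::rgamma(20 * n_columns, shape = alpha),
                    20, n_columns)
        p <- sweep(g, 2, colSums(g), "/")
        rownames(p) <- AA20
      }
      colnames(p) <- as.character(seq_len(n_columns))
      post[[nm]] <- p
      state[[nm]] <- AA20[states[v, ]]
    }
    anc <- if (is.null(posterior_noise)) ancestral_states(post, state)
           else ancestral_states(post)
    list(alignment = aln, ancestral = anc,
         switches = switches %||%
           data.frame(clade = character(0), column = integer(0),
                      residue = character(0)))
  })
}

## All nodes (internal + tips) descending from a node, inclusive.
descendant_nodes <- function(tree, node) {
  children <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0); stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    out <- c(out, v)
    kids <- children[[as.character(v)]]
    if (!is.null(kids)) stack <- c(kids, stack)
  }
  out
}

#' Sample target-site 15-mers from a specificity model
#'
#' Each flank position is drawn independently from the corresponding PWM
#' column; the centre is S or T according to the model's centre ratio.
#' @param model `kinase_pwm`.
#' @param n number of sites (> 0).
#' @param seed integer seed.
#' @return character vector of 15-mers.
#' @export
sample_sites_from_pwm <- function(model, n, seed = 1L) {
  if (n <= 0) stop2("n must be positive")
  withr::with_seed(seed, {
    m <- matrix("", n, 15)
    for (j in seq_along(FLANK_POS)) {
      col_idx <- FLANK_POS[j] + 8L
      m[, col_idx] <- sample(AA20, n, replace = TRUE,
                             prob = model$matrix[, j])
    }
    p_s <- model$st_ratio / (1 + model$st_ratio)
    m[, 8] <- ifelse(stats::runif(n) < p_s, "S", "T")
    apply(m, 1, paste, collapse = "")
  })
}

#' Simulate a species phosphoproteome as a motif/background mixture
#'
#' Each site is independently assigned to one of the motif components (with
#' the given mixture weights; the remaining weight is pure background).
#' Motif-bearing sites have every constrained position set to a residue
#' drawn uniformly from that position's residue class; all other flank
#' positions are drawn from the background frequencies. The centre is S or
#' T with equal probability. The collection is deduplicated.
#'
#' @param species species name.
#' @param n_sites number of sites to draw (before deduplication).
#' @param motifs list of [motif_pattern()] objects (may be empty).
#' @param weights mixture weight per motif; `sum(weights) <= 1`.
#' @param background residue frequencies over AA20 (default uniform).
#' @param seed integer seed.
#' @return [phosphosite_set()]; attribute `components` gives the component
#'   index per drawn site (0 = background), before deduplication.
#' @export
simulate_phosphoproteome <- function(species, n_sites, motifs = list(),
                                     weights = numeric(0),
                                     background = rep(1 / 20, 20),
                                     seed = 1L) {
  if (length(weights) != length(motifs))
    stop2("one mixture weight per motif required")
  if (any(weights < 0) || sum(weights) > 1 + 1e-12)
    stop2("mixture weights must be >= 0 and sum to <= 1")
  background <- background / sum(background)
  withr::with_seed(seed, {
    comp <- sample.int(length(motifs) + 1L, n_sites, replace = TRUE,
                       prob = c(1 - sum(weights), weights)) - 1L
    m <- matrix(sample(AA20, n_sites * 14, replace = TRUE,
                       prob = background), n_sites, 14)
    full <- cbind(m[, 1:7, drop = FALSE],
                  ifelse(stats::runif(n_sites) < 0.5, "S", "T"),
                  m[, 8:14, drop = FALSE])
    for (k in seq_along(motifs)) {
      rows <- which(comp == k)
      if (!length(rows)) next
      for (pos in names(motifs[[k]]$constraints)) {
        cls <- motifs[[k]]$constraints[[pos]]
        full[rows, as.integer(pos) + 8L] <-
          sample(cls, length(rows), replace = TRUE)
      }
    }
    sites <- apply(full, 1, paste, collapse = "")
    out <- phosphosite_set(species, sites, unique_sites = TRUE)
    attr(out, "components") <- comp
    out
  })
}

#' Simulate a binary trait under a two-state Markov model
#'
#' Continuous-time two-state Markov simulation down the tree with gain rate
#' (0 to 1) and loss rate (1 to 0).
#' @param tree rooted `phylo` with branch lengths.
#' @param rate_gain,rate_loss nonnegative rates.
#' @param root_state 0 or 1.
#' @param seed integer seed.
#' @return named integer vector leaf -> state; attribute `node_states`
#'   holds the simulated state at every node (names = node names).
#' @export
simulate_binary_trait <- function(tree, rate_gain, rate_loss,
                                  root_state = 0L, seed = 1L) {
  if (rate_gain < 0 || rate_loss < 0) stop2("rates must be >= 0")
  tree <- name_nodes(tree)
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  withr::with_seed(seed, {
    states <- integer(n_nodes)
    states[root_node(tree)] <- as.integer(root_state)
    po <- ape::reorder.phylo(tree, "postorder")
    blen <- edge_length_into(tree)
    for (ei in rev(seq_len(nrow(po$edge)))) {
      par <- po$edge[ei, 1]; ch <- po$edge[ei, 2]
      P <- two_state_prob(rate_gain, rate_loss, blen[ch])
      states[ch] <- stats::rbinom(1, 1, P[states[par] + 1L, 2])
    }
    out <- stats::setNames(states[seq_len(ntip)], tree$tip.label)
    attr(out, "node_states") <-
      stats::setNames(states, node_name(tree, seq_len(n_nodes)))
    out
  })
}

## Two-state CTMC transition matrix over time t.
## Rows/cols ordered (0, 1); g = rate 0->1, l = rate 1->0.
two_state_prob <- function(g, l, t) {
  tot <- g + l
  if (tot == 0) return(diag(2))
  e <- exp(-tot * t)
  pi1 <- g / tot
  matrix(c(1 - pi1 * (1 - e), pi1 * (1 - e),
           (1 - pi1) * (1 - e), 1 - (1 - pi1) * (1 - e)),
         2, 2, byrow = TRUE)
}

#' Simulate a correlated pair of Brownian-motion traits
#'
#' `x` evolves by Brownian motion with variance `sigma2_x` per unit branch
#' length; `y = slope * x + e`, where `e` is an independent Brownian trait
#' with variance `sigma2_y` (zero gives `y` exactly proportional to `x`).
#' @param tree rooted `phylo` with branch lengths.
#' @param sigma2_x,sigma2_y Brownian variances (`sigma2_x > 0`,
#'   `sigma2_y >= 0`).
#' @param slope linear coefficient linking `y` to `x`.
#' @param seed integer seed.
#' @return data.frame with columns `leaf`, `x`, `y`.
#' @export
simulate_bm_traits <- function(tree, sigma2_x, sigma2_y, slope,
                               seed = 1L) {
  if (sigma2_x <= 0 || sigma2_y < 0) stop2("variances must be positive")
  tree <- name_nodes(tree)
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  withr::with_seed(seed, {
    bm_once <- function(s2) {
      z <- numeric(n_nodes)
      po <- ape::reorder.phylo(tree, "postorder")
      blen <- edge_length_into(tree)
      for (ei in rev(seq_len(nrow(po$edge)))) {
        par <- po$edge[ei, 1]; ch <- po$edge[ei, 2]
        z[ch] <- z[par] + stats::rnorm(1, 0, sqrt(s2 * blen[ch]))
      }
      z[seq_len(ntip)]
    }
    x <- bm_once(sigma2_x)
    e <- if (sigma2_y > 0) bm_once(sigma2_y) else numeric(ntip)
    data.frame(leaf = tree$tip.label, x = x, y = slope * x + e)
  })
}

#' Canonical sister-family recovery battery
#'
#' Builds the standard two-sister-clade simulation used to check that the
#' divergence score recovers implanted specificity-determining columns:
#' two clades of `n_leaves` leaves each hang off short internal branches
#' (length 0.25) with unit-length terminal branches; `n_switches` columns
#' carry a residue implanted after the duplication into clade A.
#'
#' @param n_leaves leaves per clade (default 20).
#' @param n_columns alignment length (default 500).
#' @param n_switches implanted switch columns (default 10).
#' @param rate substitutions per site per unit branch length
#'   (default 0.08).
#' @param seed integer seed.
#' @return list with `tree`, `simulation` (see
#'   [simulate_family_alignment()]), `switch_columns`, and `comparison`
#'   (the scorable clade A vs clade B [select_sister_clade()] result).
#' @export
sister_family_battery <- function(n_leaves = 20L, n_columns = 500L,
                                  n_switches = 10L, rate = 0.08,
                                  seed = 1L) {
  mk_clade <- function(nm, pref)
    paste0("(", paste0(pref, seq_len(n_leaves), ":1.0", collapse = ","),
           ")", nm, ":0.25")
  tree <- ape::read.tree(text = paste0("(", mk_clade("CA", "a"), ",",
                                       mk_clade("CB", "b"), ")R;"))
  cols <- round(seq(1, n_columns, length.out = n_switches + 2))
  cols <- cols[2:(n_switches + 1)]
  switches <- data.frame(clade = "CA", column = cols, residue = "W")
  sim <- simulate_family_alignment(tree, n_columns, rate, switches,
                                   seed = seed)
  cand <- select_focal_clade(tree, sim$alignment$labels, "CA", "family")
  cmp <- select_sister_clade(tree, cand, sim$alignment$labels)
  list(tree = tree, simulation = sim, switch_columns = cols,
       comparison = cmp)
}
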
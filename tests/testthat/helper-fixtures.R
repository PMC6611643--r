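## Shared fixtures and independent oracles, built in code.

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

tree_text <- function(txt) kinevo:::name_nodes(ape::read.tree(text = txt))

toy_labels <- function(ids, species = ids, group = "G", family = NA,
                       subfamily = NA) {
  data.frame(id = ids, species = species, group = group, family = family,
             subfamily = subfamily)
}

## Random reversible substitution model (GTR-style) for oracle batteries.
random_model <- function(seed) {
  withr::with_seed(seed, {
    ex <- matrix(0, 20, 20)
    ex[lower.tri(ex)] <- stats::rexp(190)
    ex <- ex + t(ex)
    pi <- stats::rgamma(20, 2)
    kinevo:::build_model("random", ex, pi / sum(pi))
  })
}

## Random rooted tree with <= n leaves and exponential branch lengths.
random_small_tree <- function(n_leaves, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_leaves, rooted = TRUE,
                     br = function(n) stats::rexp(n, 2))
    kinevo:::name_nodes(tr)
  })
}

## Independent matrix exponential (series route, via Matrix::expm).
expm_oracle <- function(Q, t) as.matrix(Matrix::expm(Q * t))

## Exhaustive-enumeration site likelihood + marginal posteriors for small
## trees: sums over all internal-node residue assignments.
enumerate_site <- function(tree, states, model) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  par <- kinevo:::parent_vector(tree)
  blen <- kinevo:::edge_length_into(tree)
  P <- lapply(seq_len(n_nodes), function(v)
    if (is.na(blen[v])) NULL else expm_oracle(model$Q, blen[v]))
  internal <- (ntip + 1):n_nodes
  root <- kinevo:::root_node(tree)
  grid <- do.call(expand.grid, rep(list(1:20), length(internal)))
  leaf_idx <- match(states[tree$tip.label], aa20)
  total <- 0
  post <- matrix(0, length(internal), 20)
  for (g in seq_len(nrow(grid))) {
    assign <- unlist(grid[g, ])
    state_of <- function(v) {
      if (v <= ntip) leaf_idx[v] else assign[match(v, internal)]
    }
    pr <- unname(model$pi[state_of(root)])
    for (v in seq_len(n_nodes)) {
      if (v == root) next
      sv <- state_of(v)
      if (v <= ntip && is.na(sv)) next  # gap leaf: marginalised out
      if (v <= ntip) pr <- pr * P[[v]][state_of(par[v]), sv]
      else pr <- pr * P[[v]][state_of(par[v]), sv]
    }
    total <- total + pr
    post[cbind(seq_along(internal), assign)] <-
      post[cbind(seq_along(internal), assign)] + pr
  }
  list(loglik = log(total), post = post / total,
       internal_names = kinevo:::node_name(tree, internal))
}

## Exhaustive two-state likelihood/marginals for small trees (flat root).
enumerate_mk <- function(tree, states, q) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  par <- kinevo:::parent_vector(tree)
  blen <- kinevo:::edge_length_into(tree)
  P <- lapply(seq_len(n_nodes), function(v)
    if (is.na(blen[v])) NULL else kinevo:::two_state_prob(q, q, blen[v]))
  internal <- (ntip + 1):n_nodes
  root <- kinevo:::root_node(tree)
  grid <- do.call(expand.grid, rep(list(0:1), length(internal)))
  leaf_state <- states[tree$tip.label]
  total <- 0
  post1 <- numeric(length(internal))
  for (g in seq_len(nrow(grid))) {
    assign <- unlist(grid[g, ])
    state_of <- function(v)
      if (v <= ntip) leaf_state[v] else assign[match(v, internal)]
    pr <- 0.5
    for (v in seq_len(n_nodes)) {
      if (v == root) next
      pr <- pr * P[[v]][state_of(par[v]) + 1, state_of(v) + 1]
    }
    total <- total + pr
    post1[assign == 1] <- post1[assign == 1] + pr
  }
  list(loglik = log(total), post1 = post1 / total,
       internal_names = kinevo:::node_name(tree, internal))
}

## A peaked toy PWM around given preferred residues.
toy_pwm <- function(kinase = "K1", prefs = list(), peak = 0.7,
                    group = NA, family = NA, subfamily = NA,
                    n_sites = 50L) {
  m <- matrix(1 / 20, 20, 14,
              dimnames = list(aa20, as.character(c(-7:-1, 1:7))))
  for (pos in names(prefs)) {
    col <- match(pos, colnames(m))
    m[, col] <- (1 - peak) / 19
    m[prefs[[pos]], col] <- peak
  }
  structure(list(kinase = kinase, group = group, family = family,
                 subfamily = subfamily, matrix = m, n_sites = n_sites,
                 st_ratio = 1),
            class = "kinase_pwm")
}

## Random stochastic PWM.
random_pwm <- function(seed, kinase = paste0("K", seed)) {
  withr::with_seed(seed, {
    m <- matrix(stats::rgamma(280, 1), 20, 14,
                dimnames = list(aa20, as.character(c(-7:-1, 1:7))))
    m <- sweep(m, 2, colSums(m), "/")
    structure(list(kinase = kinase, group = NA, family = NA,
                   subfamily = NA, matrix = m, n_sites = 50L,
                   st_ratio = 1),
              class = "kinase_pwm")
  })
}

## Random 15-mer sites with S/T centre under uniform composition.
random_sites <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(sample(aa20, n * 14, replace = TRUE), n, 14)
    apply(cbind(m[, 1:7], sample(c("S", "T"), n, TRUE), m[, 8:14]),
          1, paste, collapse = "")
  })
}
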
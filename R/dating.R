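## ---------------------------------------------------------------------------
## trait_dating: equal-rates two-state Markov (Mk) model fitting on a
## species tree, marginal ancestral presence probabilities, origin-node
## calling with the MRCA rule for multiple origins, and age assignment.
## ---------------------------------------------------------------------------

## Two-state pruning over the tree; returns per-node 2-vectors of partial
## likelihoods (columns (absent, present)) plus a log scale.
mk_prune <- function(tree, states, q) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  part <- matrix(0, n_nodes, 2)
  lsc <- numeric(n_nodes)
  part[cbind(seq_len(ntip), states[tree$tip.label] + 1L)] <- 1
  po <- ape::reorder.phylo(tree, "postorder")
  blen <- edge_length_into(tree)
  children <- split(po$edge[, 2], po$edge[, 1])
  for (v in rev(unique(rev(po$edge[, 1])))) {
    acc <- c(1, 1); ls <- 0
    for (ch in children[[as.character(v)]]) {
      P <- two_state_prob(q, q, blen[ch])
      acc <- acc * as.vector(P %*% part[ch, ])
      ls <- ls + lsc[ch]
    }
    m <- max(acc)
    part[v, ] <- acc / m
    lsc[v] <- ls + log(m)
  }
  list(part = part, lsc = lsc)
}

## Log-likelihood with a flat root prior.
mk_loglik <- function(tree, states, q) {
  pr <- mk_prune(tree, states, q)
  r <- root_node(tree)
  log(sum(0.5 * pr$part[r, ])) + pr$lsc[r]
}

#' Fit the equal-rates two-state Markov model
#'
#' Maximises the pruning-algorithm likelihood of the symmetric (single
#' rate q) two-state model by bounded one-dimensional search, with a flat
#' prior on the root state. If all leaves share one state the fit is
#' degenerate: the rate is returned at the search floor with a boundary
#' flag.
#'
#' @param tree rooted `phylo` with branch lengths (polytomies allowed).
#' @param states named vector leaf -> 0/1.
#' @param q_bounds search interval for the rate (default `c(1e-8, 1e3)`,
#'   on the branch-length scale of the tree).
#' @return list of class `mk_model`: `q`, `loglik`, `boundary`.
#' @export
fit_er_model <- function(tree, states, q_bounds = c(1e-8, 1e3)) {
  tree <- name_nodes(tree)
  st <- states[tree$tip.label]
  if (anyNA(st)) stop2("missing state for some leaf")
  if (!all(st %in% 0:1)) stop2("states must be binary 0/1")
  if (length(unique(st)) == 1L) {
    q <- q_bounds[1]
    return(structure(list(q = q, loglik = mk_loglik(tree, st, q),
                          boundary = TRUE),
                     class = "mk_model"))
  }
  opt <- stats::optimize(function(lq) mk_loglik(tree, st, exp(lq)),
                         interval = log(q_bounds), maximum = TRUE,
                         tol = 1e-10)
  structure(list(q = exp(opt$maximum), loglik = opt$objective,
                 boundary = FALSE),
            class = "mk_model")
}

#' Marginal presence probability at every node
#'
#' Inside-outside computation of the marginal posterior of state 1
#' (present) at every node of the tree under the fitted equal-rates model,
#' with a flat root prior. Leaves carry their observed state.
#'
#' @param tree rooted `phylo`.
#' @param states named vector leaf -> 0/1.
#' @param model `mk_model` from [fit_er_model()].
#' @return named numeric vector node name -> P(present), over all nodes.
#' @export
marginal_presence <- function(tree, states, model) {
  tree <- name_nodes(tree)
  st <- states[tree$tip.label]
  q <- model$q
  pr <- mk_prune(tree, st, q)
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  out <- matrix(0, n_nodes, 2)
  r <- root_node(tree)
  out[r, ] <- c(0.5, 0.5)
  blen <- edge_length_into(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  po <- ape::reorder.phylo(tree, "postorder")
  for (v in unique(rev(po$edge[, 1]))) {
    kids <- children[[as.character(v)]]
    down <- lapply(kids, function(ch)
      as.vector(two_state_prob(q, q, blen[ch]) %*% pr$part[ch, ]))
    for (j in seq_along(kids)) {
      ch <- kids[j]
      acc <- out[v, ]
      for (k in seq_along(kids)) if (k != j) acc <- acc * down[[k]]
      o <- as.vector(t(two_state_prob(q, q, blen[ch])) %*% acc)
      out[ch, ] <- o / sum(o)
    }
  }
  post <- out * pr$part
  post <- post / rowSums(post)
  stats::setNames(post[, 2], node_name(tree, seq_len(n_nodes)))
}

#' Call the origin node of a kinase unit
#'
#' Candidate origins are the deepest nodes (closest to the root) whose
#' presence probability strictly exceeds the threshold while their parent
#' does not (the root qualifies on its own). A single candidate is the
#' origin; multiple candidates are resolved to their most recent common
#' ancestor with the multiple-origin flag set (assumes no horizontal
#' transfer or convergent gain).
#'
#' @param tree rooted `phylo`.
#' @param presence named vector node -> P(present) from
#'   [marginal_presence()].
#' @param threshold presence threshold (default 0.5).
#' @param unit unit name for the report.
#' @return list of class `origin_assignment`: `unit`, `origin` (node name
#'   or `NA`), `support`, `multiple_origin`, `candidates`, `status`.
#' @export
call_origin <- function(tree, presence, threshold = 0.5, unit = "unit") {
  tree <- name_nodes(tree)
  n_nodes <- length(tree$tip.label) + tree$Nnode
  par <- parent_vector(tree)
  nm <- node_name(tree, seq_len(n_nodes))
  above <- presence[nm] > threshold
  cand <- which(above & (par == 0L | !above[ifelse(par == 0L, 1L, par)]))
  if (!length(cand)) {
    return(structure(list(unit = unit, origin = NA_character_,
                          support = NA_real_, multiple_origin = FALSE,
                          candidates = character(0),
                          status = "not reconstructed present"),
                     class = "origin_assignment"))
  }
  if (length(cand) == 1L) {
    origin <- cand
    multiple <- FALSE
  } else {
    tips <- unique(unlist(lapply(cand, tips_under, tree = tree)))
    origin <- ape::getMRCA(tree, tips)
    multiple <- TRUE
  }
  structure(list(unit = unit, origin = nm[origin],
                 support = unname(presence[nm[origin]]),
                 multiple_origin = multiple, candidates = nm[cand],
                 status = "ok"),
            class = "origin_assignment")
}

#' Assign an age (in million years) to an origin node
#'
#' The age is the node's entry in the divergence-time table; the interval
#' spans from the node's age to its parent's (unbounded above at the
#' root).
#'
#' @param origin `origin_assignment`.
#' @param times named numeric vector node -> age in mya (see
#'   [read_divergence_times()]).
#' @param tree the dated tree (for the parent lookup).
#' @return the `origin_assignment` with `age_mya`, `age_interval` added.
#' @export
assign_age <- function(origin, times, tree) {
  if (is.na(origin$origin)) return(origin)
  tree <- name_nodes(tree)
  if (!origin$origin %in% names(times))
    stop2("node '", origin$origin, "' missing from the time table")
  v <- node_number(tree, origin$origin)
  par <- parent_vector(tree)[v]
  upper <- if (par == 0L) Inf else {
    pnm <- node_name(tree, par)
    if (!pnm %in% names(times))
      stop2("node '", pnm, "' missing from the time table")
    unname(times[pnm])
  }
  origin$age_mya <- unname(times[origin$origin])
  origin$age_interval <- c(origin$age_mya, upper)
  origin
}

#' Date every unit of a presence/absence matrix
#'
#' Convenience pipeline: per kinase unit, fit the equal-rates model,
#' reconstruct marginal presence, call the origin and assign its age.
#' @param tree dated species tree.
#' @param pres list from [read_presence_matrix()].
#' @param times divergence-time table.
#' @param threshold presence threshold for origin calling.
#' @return data.frame with one row per unit: origin node, support,
#'   multiple-origin flag, age and interval.
#' @export
date_kinase_units <- function(tree, pres, times, threshold = 0.5) {
  units <- colnames(pres$matrix)
  rows <- lapply(units, function(u) {
    states <- stats::setNames(pres$matrix[, u], rownames(pres$matrix))
    fit <- fit_er_model(tree, states)
    pp <- marginal_presence(tree, states, fit)
    og <- assign_age(call_origin(tree, pp, threshold, unit = u),
                     times, tree)
    data.frame(unit = u, level = unname(pres$levels[u]),
               origin_node = og$origin %||% NA_character_,
               support = og$support,
               multiple_origin = og$multiple_origin,
               age_mya = og$age_mya %||% NA_real_,
               age_low = (og$age_interval %||% c(NA, NA))[1],
               age_high = (og$age_interval %||% c(NA, NA))[2],
               q = fit$q, status = og$status)
  })
  do.call(rbind, rows)
}
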
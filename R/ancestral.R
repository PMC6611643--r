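## ---------------------------------------------------------------------------
## ancestral_reconstruction: reversible amino-acid substitution models,
## Felsenstein pruning site likelihoods, and marginal (inside-outside)
## ancestral state posteriors. A single-rate stand-in for external
## reconstruction tools; real reconstructions can be supplied as
## ancestral_states tables instead.
## ---------------------------------------------------------------------------

#' Construct a reversible amino-acid substitution model
#'
#' `"poisson"` uses equal exchangeabilities and (by default) uniform
#' equilibrium frequencies; `"lg"` uses the LG exchangeabilities and
#' frequencies (taken from the installed phangorn). The rate matrix is
#' normalised to one expected substitution per unit branch length.
#'
#' @param name `"poisson"` or `"lg"`.
#' @param freqs optional equilibrium frequencies over the 20 residues
#'   (order ACDEFGHIKLMNPQRSTVWY); defaults depend on `name`.
#' @return object of class `subst_model` with elements `name`, `Q`
#'   (20 x 20, rows sum to 0), `pi`, and a cached eigendecomposition.
#' @export
subst_model <- function(name = c("poisson", "lg"), freqs = NULL) {
  name <- match.arg(name)
  if (name == "poisson") {
    ex <- matrix(1, 20, 20)
    pi <- freqs %||% rep(1 / 20, 20)
  } else {
    if (!requireNamespace("phangorn", quietly = TRUE))
      stop2("the LG model requires the phangorn package")
    lg <- utils::getFromNamespace(".LG", "phangorn")
    ## phangorn stores the lower triangle in PAML residue order
    paml <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    ex_paml <- matrix(0, 20, 20, dimnames = list(paml, paml))
    ex_paml[lower.tri(ex_paml)] <- lg$Q
    ex_paml <- ex_paml + t(ex_paml)
    ex <- ex_paml[AA20, AA20]
    pi <- freqs %||% {
      bf <- lg$bf
      names(bf) <- paml
      unname(bf[AA20])
    }
  }
  build_model(name, ex, pi)
}

## Assemble a reversible model from symmetric exchangeabilities + freqs.
build_model <- function(name, exch, pi) {
  pi <- pi / sum(pi)
  Q <- exch * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(pi * diag(Q))   # mean rate 1
  dimnames(Q) <- list(AA20, AA20)
  ## symmetrise for a stable eigendecomposition: S = D^1/2 Q D^-1/2
  sq <- sqrt(pi)
  S <- Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  structure(list(name = name, Q = Q, pi = stats::setNames(pi, AA20),
                 eig = eig, sqrt_pi = sq),
            class = "subst_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the cached eigendecomposition of the symmetrised rate
#' matrix; entries below 1e-12 are clipped to zero and rows renormalised.
#' @param model `subst_model`.
#' @param t branch length (expected substitutions per site).
#' @export
prob_matrix <- function(model, t) {
  if (t < 0 || !is.finite(t)) stop2("branch length must be finite and >= 0")
  V <- model$eig$vectors
  P <- (V %*% (exp(model$eig$values * t) * t(V)))
  P <- P * ((1 / model$sqrt_pi) %o% model$sqrt_pi)
  P[P < 1e-12] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA20, AA20)
  P
}

## Leaf partial likelihoods for a character state vector over columns:
## indicator for observed residues, all-ones for gaps/ambiguity.
leaf_partials <- function(states) {
  C <- length(states)
  L <- matrix(0, 20, C)
  idx <- match(states, AA20)
  obs <- !is.na(idx)
  L[cbind(idx[obs], which(obs))] <- 1
  L[, !obs] <- 1
  L
}

## Pruning (inside) pass over all columns at once.
## X: list leaf name -> character vector of states (length C).
## Returns list(partials = per-node 20 x C, logscale = per-node length-C).
prune_tree <- function(tree, X, model) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  C <- length(X[[1]])
  po <- ape::reorder.phylo(tree, "postorder")
  blen <- edge_length_into(tree)
  partials <- vector("list", n_nodes)
  logscale <- vector("list", n_nodes)
  for (i in seq_len(ntip)) {
    nm <- tree$tip.label[i]
    if (is.null(X[[nm]])) stop2("leaf '", nm, "' missing from alignment")
    partials[[i]] <- leaf_partials(X[[nm]])
    logscale[[i]] <- numeric(C)
  }
  children <- split(po$edge[, 2], po$edge[, 1])
  ## visit each parent only after every edge below it has been visited
  parents_post <- rev(unique(rev(po$edge[, 1])))
  for (v in parents_post) {
    acc <- matrix(1, 20, C)
    ls <- numeric(C)
    for (ch in children[[as.character(v)]]) {
      P <- prob_matrix(model, blen[ch])
      acc <- acc * (P %*% partials[[ch]])
      ls <- ls + logscale[[ch]]
    }
    m <- apply(acc, 2, max)
    m[m == 0] <- 1
    partials[[v]] <- sweep(acc, 2, m, "/")
    logscale[[v]] <- ls + log(m)
  }
  list(partials = partials, logscale = logscale)
}

#' Site log-likelihood by the pruning algorithm
#'
#' Gaps are treated as fully ambiguous; the root is weighted by the
#' equilibrium frequencies.
#' @param tree rooted `phylo` with branch lengths.
#' @param column_states named character vector: leaf -> residue or `"-"`.
#' @param model `subst_model`.
#' @return list with `column` (NA here) and `loglik`.
#' @export
site_log_likelihood <- function(tree, column_states, model) {
  states <- column_states[tree$tip.label]
  if (all(is.na(match(states, AA20))))
    stop2("all leaves are gaps: site likelihood undefined")
  X <- lapply(stats::setNames(nm = tree$tip.label),
              function(nm) column_states[[nm]])
  pr <- prune_tree(tree, X, model)
  r <- root_node(tree)
  ll <- log(sum(model$pi * pr$partials[[r]][, 1])) + pr$logscale[[r]][1]
  list(column = NA_integer_, loglik = ll)
}

## Outside pass: per-node outside weights (normalised per column).
outside_pass <- function(tree, pr, model) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  C <- ncol(pr$partials[[1]])
  blen <- edge_length_into(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  out <- vector("list", n_nodes)
  r <- root_node(tree)
  out[[r]] <- matrix(model$pi, 20, C)
  ## preorder: parents strictly before children (reverse of the safe
  ## postorder parent sequence)
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- unique(rev(po$edge[, 1]))
  for (v in pre) {
    kids <- children[[as.character(v)]]
    down <- lapply(kids, function(ch)
      prob_matrix(model, blen[ch]) %*% pr$partials[[ch]])
    for (j in seq_along(kids)) {
      ch <- kids[j]
      acc <- out[[v]]
      for (k in seq_along(kids)) if (k != j) acc <- acc * down[[k]]
      o <- t(prob_matrix(model, blen[ch])) %*% acc
      s <- colSums(o)
      s[s == 0] <- 1
      out[[ch]] <- sweep(o, 2, s, "/")
    }
  }
  out
}

#' Marginal ancestral state posteriors for every internal node
#'
#' Standard inside-outside computation: at each internal node the posterior
#' over residues is proportional to the product of the inside (pruning)
#' partial and the outside weight. The predicted residue is the argmax with
#' alphabetical tie-break (ties flagged via the `ties` attribute).
#'
#' @param tree rooted `phylo` whose leaves appear in `aln`.
#' @param aln `kinase_alignment` (gaps treated as fully ambiguous).
#' @param model `subst_model`.
#' @return [ancestral_states()] table over internal nodes.
#' @export
marginal_ancestral_states <- function(tree, aln, model) {
  tree <- name_nodes(tree)
  missing <- setdiff(tree$tip.label, rownames(aln$mat))
  if (length(missing))
    stop2("leaf '", missing[1], "' missing from alignment")
  X <- lapply(stats::setNames(nm = tree$tip.label),
              function(nm) aln$mat[nm, ])
  pr <- prune_tree(tree, X, model)
  out <- outside_pass(tree, pr, model)
  ntip <- length(tree$tip.label)
  post <- list(); state <- list(); ties <- list()
  for (v in (ntip + 1):(ntip + tree$Nnode)) {
    p <- pr$partials[[v]] * out[[v]]
    p <- sweep(p, 2, colSums(p), "/")
    rownames(p) <- AA20
    colnames(p) <- as.character(seq_len(ncol(p)))
    nm <- tree$node.label[v - ntip]
    post[[nm]] <- p
    mx <- apply(p, 2, max)
    state[[nm]] <- AA20[apply(p, 2, which.max)]  # which.max = first = A..Y
    ties[[nm]] <- colSums(abs(sweep(p, 2, mx)) < 1e-12) > 1
  }
  res <- ancestral_states(post, state)
  attr(res, "ties") <- ties
  res
}

#' Alignment log-likelihood (sum of per-column site likelihoods)
#' @inheritParams marginal_ancestral_states
#' @return numeric vector of per-column log-likelihoods.
#' @export
alignment_site_likelihoods <- function(tree, aln, model) {
  X <- lapply(stats::setNames(nm = tree$tip.label),
              function(nm) aln$mat[nm, ])
  pr <- prune_tree(tree, X, model)
  r <- root_node(tree)
  log(colSums(model$pi * pr$partials[[r]])) + pr$logscale[[r]]
}
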
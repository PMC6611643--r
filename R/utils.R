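#' @keywords internal
"_PACKAGE"

## Amino-acid alphabet used throughout: alphabetical one-letter codes.
## Posterior TSV columns, PWM rows and rate-matrix dimensions all follow
## this order.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Flank positions of a 15-mer phosphosite relative to the central S/T.
FLANK_POS <- c(-7:-1, 1:7)

## Terminal-padding character for truncated peptides; excluded from all
## residue counts and never matched by any motif class.
PAD_CHAR <- "_"

## Operating specificity-divergence threshold (Frobenius distance) reported
## for the curated kinase specificity models; pipelines on synthetic data
## should derive their own with derive_threshold().
#' Frobenius-distance threshold separating conserved from diverged specificity
#'
#' The operating constant used to split kinase pairs into
#' "specificity-conserved" and "specificity-diverged"; derived from the
#' maximum distance between same-kinase PWMs built by subsampling 25 target
#' sites from kinases with at least 50 curated targets. Synthetic pipelines
#' should recompute their own threshold with [derive_threshold()].
#' @export
SPECIFICITY_DIVERGENCE_THRESHOLD <- 1.06

`%||%` <- function(a, b) if (is.null(a)) b else a

## Linear-interpolation quantile (type 7), the fixed convention for all
## percentile thresholds so they are reproducible.
interp_quantile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

stop2 <- function(...) stop(..., call. = FALSE)

## Split peptides into an n x 15 character matrix.
site_matrix <- function(sites) {
  if (length(sites) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = 15))
  }
  m <- matrix(unlist(strsplit(sites, "", fixed = TRUE), use.names = FALSE),
              nrow = length(sites), byrow = TRUE)
  if (ncol(m) != 15L) stop2("all phosphosite peptides must have length 15")
  m
}

## Ensure a phylo object has unique, non-empty internal node labels.
## Unnamed nodes get deterministic names "N<node number>".
name_nodes <- function(tree) {
  nn <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", nn)
  lab[is.na(lab)] <- ""
  empty <- lab == ""
  lab[empty] <- paste0("N", which(empty) + length(tree$tip.label))
  if (anyDuplicated(lab)) stop2("internal node labels are not unique")
  tree$node.label <- lab
  tree
}

## Node name (tip label or internal label) for node number(s).
node_name <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- character(length(node))
  tip <- node <= ntip
  out[tip] <- tree$tip.label[node[tip]]
  out[!tip] <- tree$node.label[node[!tip] - ntip]
  out
}

## Node number for a node name; errors if absent.
node_number <- function(tree, name) {
  ntip <- length(tree$tip.label)
  i <- match(name, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(name, tree$node.label)
  if (is.na(j)) stop2("node '", name, "' not found in tree")
  j + ntip
}

## Tip numbers descending from a node (the node itself if a tip).
tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  unlist(phangorn_free_descendants(tree, node))
}

## Tip descendants without depending on phangorn: iterative stack walk.
phangorn_free_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  children <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= ntip) out <- c(out, v)
    else stack <- c(children[[as.character(v)]], stack)
  }
  out
}

## Parent node number of each node (0 for the root).
parent_vector <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  par <- integer(n_nodes)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

root_node <- function(tree) length(tree$tip.label) + 1L

## Edge length leading into each node (NA for the root).
edge_length_into <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  len <- rep(NA_real_, n_nodes)
  len[tree$edge[, 2]] <- tree$edge.length
  len
}

## BLOSUM62 rescaled to [0, 1] over the 20 standard-residue block
## (min -4 -> 0, max 11 -> 1), the default conservation scoring matrix.
rescaled_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20]
  (m - min(m)) / (max(m) - min(m))
}
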
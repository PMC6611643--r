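## ---------------------------------------------------------------------------
## io_formats: readers/writers for every external file the pipeline touches,
## plus the alignment quality filters.
##
## Coordinate conventions: alignment columns are 1-based R indices internally;
## kinase-domain positions are 1-based (1..246) in all outputs. The column map
## records, for each alignment column, its domain position (NA = unmapped).
## ---------------------------------------------------------------------------

#' Construct a labelled kinase alignment
#'
#' @param seqs named character vector of aligned sequences (equal length,
#'   gap character `-`).
#' @param labels data.frame with columns `id`, `species`, `group`, `family`,
#'   `subfamily` (family/subfamily may be `NA`).
#' @param column_map integer vector, one entry per alignment column, giving
#'   the kinase-domain position of that column (`NA` for unmapped columns);
#'   must be strictly increasing over mapped columns. Defaults to `1:ncol`.
#' @return An object of class `kinase_alignment` with elements `mat`
#'   (sequence-by-column character matrix), `labels` and `column_map`.
#' @export
kinase_alignment <- function(seqs, labels, column_map = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop2("sequences must have unique identifiers")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names(seqs)[which(lens != lens[1])[1]]
    stop2("ragged alignment: sequence '", bad, "' has length ",
          nchar(seqs[bad]), ", expected ", lens[1])
  }
  seqs <- toupper(gsub("[.]", "-", seqs))
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(names(seqs), NULL))
  missing <- setdiff(rownames(mat), labels$id)
  if (length(missing))
    stop2("missing label for identifier(s): ", paste(missing, collapse = ", "))
  labels <- labels[match(rownames(mat), labels$id), , drop = FALSE]
  for (col in c("group", "family", "subfamily", "species"))
    if (is.null(labels[[col]])) labels[[col]] <- NA_character_
  if (is.null(column_map)) column_map <- seq_len(ncol(mat))
  if (length(column_map) != ncol(mat))
    stop2("column_map length must equal alignment width")
  mapped <- column_map[!is.na(column_map)]
  if (is.unsorted(mapped, strictly = TRUE))
    stop2("column_map must be strictly increasing over mapped columns")
  structure(list(mat = mat, labels = labels,
                 column_map = as.integer(column_map)),
            class = "kinase_alignment")
}

#' @export
print.kinase_alignment <- function(x, ...) {
  cat("kinase_alignment:", nrow(x$mat), "sequences x", ncol(x$mat),
      "columns (", sum(!is.na(x$column_map)), "mapped )\n")
  invisible(x)
}

#' Read a labelled protein alignment from FASTA + labels TSV
#'
#' @param path FASTA file of aligned sequences.
#' @param labels_path TSV with header and columns `id`, `species`, `group`,
#'   `family`, `subfamily` (the last two may be empty).
#' @param column_map_path optional TSV with header and columns `column`
#'   (1-based alignment column) and `domain_position`; unlisted columns are
#'   unmapped. Without it, columns map to positions `1:width`.
#' @return [kinase_alignment()] object.
#' @export
read_alignment <- function(path, labels_path, column_map_path = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  lens <- Biostrings::width(aa)
  if (length(unique(lens)) != 1L) {
    bad <- names(aa)[which(lens != lens[1])[1]]
    stop2("ragged alignment in '", path, "': sequence '", bad, "'")
  }
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  labels <- utils::read.delim(labels_path, stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))
  cmap <- NULL
  if (!is.null(column_map_path)) {
    tab <- utils::read.delim(column_map_path, stringsAsFactors = FALSE)
    cmap <- rep(NA_integer_, nchar(seqs[[1]]))
    cmap[tab$column] <- tab$domain_position
  }
  kinase_alignment(seqs, labels, cmap)
}

#' Write a kinase alignment to FASTA + labels TSV (+ column map TSV)
#'
#' @param aln a `kinase_alignment`.
#' @param path,labels_path,column_map_path output files; the column map is
#'   only written when `column_map_path` is given.
#' @export
write_alignment <- function(aln, path, labels_path,
                            column_map_path = NULL) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  utils::write.table(aln$labels, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(column_map_path)) {
    keep <- !is.na(aln$column_map)
    utils::write.table(
      data.frame(column = which(keep),
                 domain_position = aln$column_map[keep]),
      column_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(aln)
}

#' Apply the alignment quality filters
#'
#' Three filters, applied in order: (1) drop sequences lacking a required
#' residue at any of the given domain positions (pseudokinase filter);
#' (2) drop columns whose gap fraction is `>= max_gap_fraction`; (3) drop
#' sequences with fewer than `min_mapped_positions` non-gap residues at
#' mapped columns. The default required residues are the canonical catalytic
#' residues of the VAIK/alphaC-Glu/HRD/catalytic-loop-Asn/DFG motifs at
#' domain positions 30, 48, 123, 128 and 141.
#'
#' @param aln a `kinase_alignment`.
#' @param required_residues named list: names are domain positions, values
#'   character vectors of allowed residues.
#' @param max_gap_fraction columns with at least this gap fraction are
#'   dropped (closed threshold: exactly 20% is dropped by default).
#' @param min_mapped_positions minimum non-gap mapped positions per sequence.
#' @return filtered `kinase_alignment`; attribute `filter_log` records counts.
#' @export
filter_alignment <- function(aln,
                             required_residues = list(
                               `30` = "K", `48` = "E", `123` = "D",
                               `128` = "N", `141` = "D"),
                             max_gap_fraction = 0.20,
                             min_mapped_positions = 190) {
  mat <- aln$mat
  cmap <- aln$column_map
  log <- list()

  ## 1: pseudokinase filter
  keep_seq <- rep(TRUE, nrow(mat))
  for (pos in names(required_residues)) {
    col <- match(as.integer(pos), cmap)
    if (is.na(col))
      stop2("required-residue domain position ", pos, " is not mapped")
    keep_seq <- keep_seq & mat[, col] %in% required_residues[[pos]]
  }
  log$sequences_dropped_required_residue <- sum(!keep_seq)
  mat <- mat[keep_seq, , drop = FALSE]
  if (nrow(mat) == 0L) stop2("all sequences filtered")

  ## 2: gappy columns
  gap_frac <- colMeans(mat == "-")
  keep_col <- gap_frac < max_gap_fraction
  log$columns_dropped_gap <- sum(!keep_col)
  mat <- mat[, keep_col, drop = FALSE]
  cmap <- cmap[keep_col]

  ## 3: truncated sequences
  n_mapped <- rowSums(mat[, !is.na(cmap), drop = FALSE] != "-")
  keep_seq2 <- n_mapped >= min_mapped_positions
  log$sequences_dropped_truncated <- sum(!keep_seq2)
  mat <- mat[keep_seq2, , drop = FALSE]
  if (nrow(mat) == 0L) stop2("all sequences filtered")

  out <- kinase_alignment(apply(mat, 1, paste, collapse = ""),
                          aln$labels[aln$labels$id %in% rownames(mat), ,
                                     drop = FALSE],
                          cmap)
  attr(out, "filter_log") <- log
  out
}

#' Read a rooted phylogeny from Newick
#'
#' Polytomies are preserved; unnamed internal nodes are auto-named
#' deterministically (`N<node number>`).
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object with unique node labels.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop2("cannot parse Newick '", path,
                                             "': ", conditionMessage(e)))
  if (is.null(tree)) stop2("cannot parse Newick '", path, "'")
  if (anyDuplicated(tree$tip.label)) stop2("duplicate leaf names in tree")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop2("negative branch lengths")
  name_nodes(tree)
}

#' A collection of 15-mer phosphosites for one species
#'
#' @param species species name.
#' @param sites character vector of 15-mers (centre S/T; padding `_`).
#' @param unique_sites deduplicate the peptides.
#' @param rejected number of rejected input rows (centre not S/T).
#' @export
phosphosite_set <- function(species, sites, unique_sites = TRUE,
                            rejected = 0L) {
  sites <- toupper(sites)
  if (length(sites) && any(nchar(sites) != 15L))
    stop2("all peptides must have length 15")
  centre <- substr(sites, 8, 8)
  if (length(sites) && !all(centre %in% c("S", "T")))
    stop2("all peptide centres must be S or T")
  if (unique_sites) sites <- unique(sites)
  structure(list(species = species, sites = sites,
                 unique_sites = unique_sites, rejected = rejected),
            class = "phosphosite_set")
}

#' @export
print.phosphosite_set <- function(x, ...) {
  cat("phosphosite_set:", x$species, "-", length(x$sites), "sites (",
      x$rejected, "rejected )\n")
  invisible(x)
}

#' Read phosphosite 15-mers from TSV
#'
#' Rows whose centre residue is not S/T are rejected and counted. Peptides
#' shorter than 15 are padded symmetrically with `pad_char`; within a
#' species duplicates are removed.
#'
#' @param path TSV with header and columns `species`, `peptide`.
#' @param pad_char terminal-padding character (default `_`).
#' @return named list of [phosphosite_set()], one per species.
#' @export
read_phosphosites <- function(path, pad_char = PAD_CHAR) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$peptide <- toupper(tab$peptide)
  tab$peptide <- vapply(tab$peptide, pad_site, "", pad_char = pad_char)
  lapply(split(tab, tab$species), function(d) {
    ok <- substr(d$peptide, 8, 8) %in% c("S", "T")
    phosphosite_set(d$species[1], d$peptide[ok], unique_sites = TRUE,
                    rejected = sum(!ok))
  })
}

## Pad a peptide to 15 characters, keeping the acceptor centred. Peptides
## must have odd length <= 15 so a centre exists.
pad_site <- function(peptide, pad_char = PAD_CHAR) {
  n <- nchar(peptide)
  if (n == 15L) return(peptide)
  if (n > 15L || n %% 2L == 0L)
    stop2("peptide '", peptide, "' cannot be centred in a 15-mer")
  pad <- strrep(pad_char, (15L - n) / 2L)
  paste0(pad, peptide, pad)
}

#' Write phosphosites to TSV
#' @param sets list of `phosphosite_set` (or a single one).
#' @param path output TSV.
#' @export
write_phosphosites <- function(sets, path) {
  if (inherits(sets, "phosphosite_set")) sets <- list(sets)
  tab <- do.call(rbind, lapply(sets, function(s)
    data.frame(species = s$species, peptide = s$sites)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sets)
}

#' Construct an ancestral-state table
#'
#' Per internal node and alignment column: the most probable residue and the
#' full posterior vector over the 20 residues (order ACDEFGHIKLMNPQRSTVWY).
#'
#' @param post named list: per node, a 20 x n_columns matrix of posteriors
#'   (rows AA20, columns alignment columns).
#' @param state optional named list of predicted residues per node; defaults
#'   to the column argmax with alphabetical tie-break.
#' @export
ancestral_states <- function(post, state = NULL) {
  for (nd in names(post)) {
    p <- post[[nd]]
    if (!is.matrix(p) || nrow(p) != 20L)
      stop2("posterior for node '", nd, "' must be a 20-row matrix")
    rownames(p) <- AA20
    sums <- colSums(p)
    if (any(abs(sums - 1) > 1e-6))
      stop2("posteriors for node '", nd, "' do not sum to 1")
    post[[nd]] <- p
  }
  if (is.null(state))
    state <- lapply(post, function(p) AA20[apply(p, 2, which.max)])
  for (nd in names(post)) {
    idx <- cbind(match(state[[nd]], AA20), seq_along(state[[nd]]))
    mx <- apply(post[[nd]], 2, max)
    if (any(post[[nd]][idx] < mx - 1e-9))
      stop2("predicted residue is not an argmax for node '", nd, "'")
  }
  structure(list(post = post, state = state), class = "ancestral_states")
}

#' Read an ancestral-state table from TSV
#'
#' Columns: `node`, `column`, `residue`, then 20 posterior columns in the
#' order ACDEFGHIKLMNPQRSTVWY.
#' @param path TSV file.
#' @export
read_ancestral_states <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node", "column", "residue", AA20)
  if (!all(need %in% names(tab)))
    stop2("ancestral-state TSV must have columns: ",
          paste(need, collapse = ", "))
  post <- list(); state <- list()
  for (d in split(tab, tab$node)) {
    d <- d[order(d$column), , drop = FALSE]
    p <- t(as.matrix(d[, AA20]))
    colnames(p) <- d$column
    post[[d$node[1]]] <- p
    state[[d$node[1]]] <- d$residue
  }
  ancestral_states(post, state)
}

#' Write an ancestral-state table to TSV
#' @param anc `ancestral_states` object.
#' @param path output TSV.
#' @export
write_ancestral_states <- function(anc, path) {
  rows <- lapply(names(anc$post), function(nd) {
    p <- anc$post[[nd]]
    cols <- colnames(p) %||% as.character(seq_len(ncol(p)))
    data.frame(node = nd, column = as.integer(cols),
               residue = anc$state[[nd]], t(p), check.names = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(anc)
}

#' Read a binary kinase-unit presence/absence matrix
#'
#' Long-format TSV with header and columns `taxon`, `unit`, `level`
#' (`group`/`family`/`subfamily`) and `present` (0/1).
#' @param path TSV file.
#' @return list with `matrix` (taxa x units, 0/1), `levels` (named vector
#'   unit -> level).
#' @export
read_presence_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(tab$present %in% 0:1)) stop2("presence values must be 0/1")
  taxa <- unique(tab$taxon); units <- unique(tab$unit)
  m <- matrix(0L, length(taxa), length(units),
              dimnames = list(taxa, units))
  m[cbind(match(tab$taxon, taxa), match(tab$unit, units))] <-
    as.integer(tab$present)
  lev <- tab$level[match(units, tab$unit)]
  names(lev) <- units
  list(matrix = m, levels = lev)
}

#' Write a presence/absence matrix (long format TSV)
#' @param pres list as returned by [read_presence_matrix()].
#' @param path output TSV.
#' @export
write_presence_matrix <- function(pres, path) {
  m <- pres$matrix
  tab <- data.frame(taxon = rep(rownames(m), ncol(m)),
                    unit = rep(colnames(m), each = nrow(m)),
                    level = rep(unname(pres$levels[colnames(m)]),
                                each = nrow(m)),
                    present = as.integer(m))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pres)
}

#' Read a divergence-time table
#' @param path TSV with header and columns `node`, `age_mya`.
#' @return named numeric vector node -> age (million years).
#' @export
read_divergence_times <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$age_mya), tab$node)
}

#' Read a functional-category map for the 246 kinase-domain positions
#'
#' @param path TSV with header and columns `domain_position`, `category`
#'   (one of catalytic, proximal, distal_SDR, regulatory, interaction,
#'   other); every position 1..246 must appear exactly once.
#' @return character vector of length 246 (names = positions).
#' @export
read_category_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  functional_categories(tab$domain_position, tab$category)
}

#' Construct and validate a functional-category map
#' @param positions integer domain positions.
#' @param categories category per position.
#' @param n_positions domain length (default 246).
#' @export
functional_categories <- function(positions, categories,
                                  n_positions = 246L) {
  allowed <- c("catalytic", "proximal", "distal_SDR", "regulatory",
               "interaction", "other")
  if (!all(categories %in% allowed))
    stop2("unknown category; allowed: ", paste(allowed, collapse = ", "))
  if (!setequal(positions, seq_len(n_positions)) ||
      anyDuplicated(positions))
    stop2("every domain position 1..", n_positions,
          " must have exactly one category")
  out <- character(n_positions)
  out[positions] <- categories
  names(out) <- seq_len(n_positions)
  out
}
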
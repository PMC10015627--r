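#' Read a rooted phylogeny from Newick text or file
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is a
#' standard `phylo` object; polytomies are preserved. Missing branch lengths
#' are set to 0 with a warning so downstream likelihood code (which treats
#' zero-length branches as identity transitions) can proceed.
#'
#' @param text Newick string (quoted labels and scientific-notation lengths
#'   are accepted). Exactly one of `text`/`file` must be given.
#' @param file path to a `.nwk` file containing a single tree.
#' @return a rooted `phylo` object satisfying the package's tree invariants
#'   (unique tip labels, non-negative branch lengths, single root).
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  offset <- newick_balance_offset(text)
  if (!is.na(offset))
    stop(sprintf("Newick parse error: unbalanced parenthesis near character %d", offset))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ", conditionMessage(e)),
                   warning = function(w) stop("Newick parse error: ", conditionMessage(w)))
  if (is.null(tree)) stop("Newick parse error: no tree could be read")
  validate_phylogeny(tree, fix_lengths = TRUE)
}

# first character position at which the parenthesis depth goes negative, or
# NA if balanced; gives read_newick a character offset for its error message
newick_balance_offset <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  if (depth != 0L) return(length(chars))
  NA_integer_
}

#' Validate (and lightly repair) a phylogeny
#'
#' Checks the package's tree invariants: unique tip labels, non-negative
#' branch lengths, exactly one root. With `fix_lengths = TRUE`, absent or NA
#' branch lengths are replaced by 0 with a warning.
#'
#' @param tree a `phylo` object.
#' @param fix_lengths replace missing lengths by 0 instead of erroring.
#' @return the validated `phylo` object.
#' @export
validate_phylogeny <- function(tree, fix_lengths = FALSE) {
  stopifnot_phylo(tree)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (!fix_lengths) stop("tree has no branch lengths")
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (!fix_lengths) stop("tree has NA branch lengths")
    warning("missing branch lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  # connected + acyclic + single root <=> #edges = #nodes - 1 with one parent each
  if (nrow(tree$edge) != ape::Ntip(tree) + tree$Nnode - 1L ||
      anyDuplicated(tree$edge[, 2L]))
    stop("tree is not singly rooted / connected")
  tree
}

#' Write a phylogeny as Newick
#'
#' Emits 12 significant digits so that write/read round trips are lossless at
#' double precision.
#'
#' @param tree a `phylo` object.
#' @param file optional output path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot_phylo(tree)
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Depth of every node from the root
#'
#' @param tree a `phylo` object.
#' @return numeric vector over node ids (tips first, then internal nodes).
#' @export
node_depths <- function(tree) {
  stopifnot_phylo(tree)
  ape::node.depth.edgelength(tree)
}

#' Is the tree ultrametric?
#'
#' @param tree a `phylo` object.
#' @param tol absolute tolerance on the spread of root-to-tip depths.
#' @return logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-9) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol
}

#' Graft strain tips onto an existing tip as a polytomy
#'
#' Converts tip `at` into an internal node whose children are the original
#' tip (retained with branch length `at_length`, default 0) and the new tips.
#' With `length = 0` all pairwise patristic distances among pre-existing tips
#' are unchanged, which is how within-species strains are added to a
#' species-level phylogeny without inventing divergence times.
#'
#' @param tree a `phylo` object.
#' @param at label of an existing tip.
#' @param new_tips character vector of new, unique tip labels.
#' @param length branch length for each grafted tip (default 0).
#' @param at_length branch length retained for the original tip (default 0).
#' @return a `phylo` object with `length(new_tips)` extra tips.
#' @export
graft_tips_as_polytomy <- function(tree, at, new_tips, length = 0, at_length = 0) {
  stopifnot_phylo(tree)
  n <- ape::Ntip(tree)
  i_at <- match(at, tree$tip.label)
  if (is.na(i_at)) stop("unknown taxon: ", at)
  if (any(new_tips %in% tree$tip.label) || anyDuplicated(new_tips))
    stop("duplicate tip label(s) in graft")
  if (length < 0 || at_length < 0) stop("branch lengths must be >= 0")
  m <- base::length(new_tips)
  M <- tree$Nnode
  # new ids: old tips keep 1..n, new tips n+1..n+m, old internals shift by m,
  # the inserted node becomes the last internal id
  shift <- function(v) ifelse(v > n, v + m, v)
  new_node <- n + m + M + 1L
  edge <- cbind(shift(tree$edge[, 1L]), shift(tree$edge[, 2L]))
  len <- tree$edge.length
  edge[tree$edge[, 2L] == i_at, 2L] <- new_node
  edge <- rbind(edge,
                cbind(new_node, i_at),
                cbind(new_node, n + seq_len(m)))
  len <- c(len, at_length, rep(length, m))
  out <- list(edge = edge, edge.length = len,
              tip.label = c(tree$tip.label, new_tips),
              Nnode = M + 1L)
  if (!is.null(tree$node.label)) out$node.label <- c(tree$node.label, "")
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  validate_phylogeny(out)
}

#' Resolve polytomies deterministically with zero-length branches
#'
#' Children of each polytomy are resolved left-to-right in input order via
#' [ape::multi2di()] with `random = FALSE`; inserted branches have length 0,
#' so all trait covariance matrices and likelihoods are unchanged.
#'
#' @param tree a `phylo` object.
#' @return a strictly bifurcating `phylo` object.
#' @export
resolve_polytomies <- function(tree) {
  stopifnot_phylo(tree)
  if (is_binary_rooted(tree)) return(tree)
  ape::multi2di(tree, random = FALSE)
}

#' Make a binary tree ultrametric by extending terminal branches
#'
#' Every tip branch is lengthened so that all root-to-tip depths equal the
#' maximum input depth. Only terminal branches change and no branch is ever
#' shortened, so the relative topology/ordering of divergences is preserved.
#'
#' @param tree a binary `phylo` object.
#' @param method only `"extend"` is implemented.
#' @return an ultrametric `phylo` object of the same height.
#' @export
make_ultrametric <- function(tree, method = "extend") {
  stopifnot_phylo(tree)
  method <- match.arg(method, "extend")
  if (!is_binary_rooted(tree)) stop("make_ultrametric requires a binary tree; resolve polytomies first")
  d <- node_depths(tree)
  n <- ape::Ntip(tree)
  h <- max(d[seq_len(n)])
  ei <- edge_into(tree)
  for (tip in seq_len(n))
    tree$edge.length[ei[tip]] <- tree$edge.length[ei[tip]] + (h - d[tip])
  tree
}

#' Decompose a root-to-tip path into regime-labelled segments
#'
#' Each branch on the path from the root to `tip` becomes one segment with
#' its depth interval and the regime state painted on that branch. Segments
#' are contiguous and their lengths sum to the tip depth; they are the
#' weights carrier for Ornstein-Uhlenbeck expectations under a regime
#' painting.
#'
#' @param tree a `phylo` object.
#' @param painting a [regime_painting] covering every branch.
#' @param tip tip label or tip id.
#' @return a data.frame with columns `node`, `parent`, `start`, `end`,
#'   `length`, `state`, ordered from the root.
#' @export
root_to_tip_segments <- function(tree, painting, tip) {
  stopifnot_phylo(tree)
  if (is.character(tip)) {
    tip <- match(tip, tree$tip.label)
    if (is.na(tip)) stop("unknown tip")
  }
  st <- painting$node_state
  if (is.null(st) || length(st) != ape::Ntip(tree) + tree$Nnode)
    stop("painting does not cover this tree")
  par <- parent_of(tree)
  ei <- edge_into(tree)
  d <- node_depths(tree)
  path <- integer(0)
  v <- as.integer(tip)
  while (par[v] != 0L) {
    path <- c(v, path)
    v <- par[v]
  }
  if (anyNA(st[path])) stop("unpainted branch on path")
  data.frame(node = path,
             parent = par[path],
             start = d[par[path]],
             end = d[path],
             length = tree$edge.length[ei[path]],
             state = st[path])
}

#' One-line JSON-able summary of a tree
#'
#' @param tree a `phylo` object.
#' @return list with `tips`, `height`, `ultrametric`, `binary`.
#' @export
tree_summary <- function(tree) {
  stopifnot_phylo(tree)
  list(tips = ape::Ntip(tree),
       height = max(node_depths(tree)[seq_len(ape::Ntip(tree))]),
       ultrametric = is_ultrametric(tree),
       binary = is_binary_rooted(tree))
}
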
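#' Regime paintings: a discrete state on every branch
#'
#' A regime painting assigns each branch of a tree a reproductive-mode state
#' (0 = outcrosser, 1 = selfer). A branch is identified by its child node, so
#' the painting is stored as an integer vector over all node ids; the root's
#' entry is the state at the root itself. Paintings arise either from
#' simulation ([simulate_regime_history()]), from observed tip states plus
#' marginal ancestral-state discretization ([paint_regimes()]), or by manual
#' construction.
#'
#' @param tree the `phylo` object the painting refers to.
#' @param node_state integer vector (0/1) over `Ntip + Nnode` node ids giving
#'   the state at the child end of the branch above each node (root entry =
#'   root state).
#' @param tie logical vector flagging nodes whose state was an exact tie.
#' @param provenance one of `"observed"`, `"argmax"`, `"simulated"`,
#'   `"manual"`.
#' @return an object of class `regime_painting`.
#' @export
regime_painting <- function(tree, node_state, tie = NULL, provenance = "manual") {
  stopifnot_phylo(tree)
  n <- ape::Ntip(tree) + tree$Nnode
  node_state <- as.integer(node_state)
  if (length(node_state) != n) stop("node_state must cover every node")
  if (!all(node_state %in% c(0L, 1L))) stop("states must be 0 (outcrosser) or 1 (selfer)")
  structure(list(node_state = node_state,
                 tie = tie %||% rep(FALSE, n),
                 provenance = provenance),
            class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  cat(sprintf("Regime painting (%s): %d branches selfer, %d outcrosser%s\n",
              x$provenance, sum(x$node_state == 1L), sum(x$node_state == 0L),
              if (any(x$tie)) sprintf(", %d tie(s)", sum(x$tie)) else ""))
  invisible(x)
}

# per-edge state vector (indexed like tree$edge rows)
edge_states <- function(tree, painting) painting$node_state[tree$edge[, 2L]]

#' Export a painting as a branch table
#'
#' @param x a `regime_painting`.
#' @param tree the tree it was painted on.
#' @return data.frame with one row per branch: child node id, parent/child
#'   labels (empty for unlabelled internals), state name, tie flag.
#' @export
painting_table <- function(x, tree) {
  stopifnot_phylo(tree)
  labs <- node_labels_all(tree)
  child <- tree$edge[, 2L]
  parent <- tree$edge[, 1L]
  data.frame(branch = child,
             parent_label = labs[parent],
             child_label = labs[child],
             state = c("outcrosser", "selfer")[x$node_state[child] + 1L],
             tie = x$tie[child])
}

#' Write / read a painting table (TSV)
#'
#' Branches are keyed by child node id, so the reader requires the same tree
#' (same node numbering) the painting was written from.
#'
#' @param x a `regime_painting`.
#' @param tree the tree.
#' @param file output/input path.
#' @export
write_painting <- function(x, tree, file) {
  utils::write.table(painting_table(x, tree), file = file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_painting
#' @export
read_painting <- function(tree, file) {
  stopifnot_phylo(tree)
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  n <- ape::Ntip(tree) + tree$Nnode
  st <- rep(NA_integer_, n)
  tie <- rep(FALSE, n)
  st[d$branch] <- match(d$state, c("outcrosser", "selfer")) - 1L
  tie[d$branch] <- as.logical(d$tie)
  r <- root_node(tree)
  if (is.na(st[r])) st[r] <- st[children_of(tree)[[r]][1L]]
  if (anyNA(st)) stop("painting file does not cover every branch of this tree")
  regime_painting(tree, st, tie, provenance = "manual")
}
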
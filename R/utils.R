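# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Every stochastic entry point funnels
# through here so simulations are reproducible and side-effect free.
with_seed <- function(seed, code) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer `seed` is required for stochastic simulation")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a `phylo` object")
  invisible(tree)
}

# postorder edge indices (children before parents)
postorder_edges <- function(tree) rev(preorder_edges(tree))

# preorder edge indices (parents before children)
preorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  tr
}

# children list indexed by node id
children_of <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    out[[p]] <- c(out[[p]], tree$edge[i, 2L])
  }
  out
}

# parent vector indexed by child node id (0 for root)
parent_of <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  out <- integer(n)
  out[tree$edge[, 2L]] <- tree$edge[, 1L]
  out
}

# edge index leading into each node (NA for root)
edge_into <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  out <- rep(NA_integer_, n)
  out[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  out
}

root_node <- function(tree) ape::Ntip(tree) + 1L

# strictly bifurcating as a *rooted* tree (ape::is.binary treats a basal
# trifurcation as an unrooted binary tree)
is_binary_rooted <- function(tree) tree$Nnode == ape::Ntip(tree) - 1L

node_labels_all <- function(tree) {
  nl <- tree$node.label %||% rep("", tree$Nnode)
  c(tree$tip.label, nl)
}

fmt_num <- function(x) formatC(x, digits = 10, format = "g")
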
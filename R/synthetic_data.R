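# Seeded simulators for every layer of the analysis: regime histories on
# branches, continuous traits under exact BM/OU transition densities, gene
# family counts under the critical per-gene birth-death process, and an
# 11-taxon study fixture shaped like the Elegans-group design (three
# independent selfing origins, strains grafted as a shallow split).

#' Simulate a two-state regime history along a tree
#'
#' A continuous-time two-state Markov chain (rates `q01`, `q10` per unit
#' branch length) is run down every branch with exponential waiting times;
#' each branch records the state at its child end, matching the convention
#' that a branch's regime is what the lineage is by the time it ends.
#'
#' @param tree a `phylo` object.
#' @param q01 rate outcrosser -> selfer (>= 0).
#' @param q10 rate selfer -> outcrosser (>= 0).
#' @param root_state state at the root (0 or 1).
#' @param seed RNG seed (required).
#' @return a [regime_painting] with provenance `"simulated"`.
#' @export
simulate_regime_history <- function(tree, q01, q10, root_state = 0L, seed) {
  stopifnot_phylo(tree)
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
  with_seed(seed, {
    N <- ape::Ntip(tree) + tree$Nnode
    st <- rep(NA_integer_, N)
    st[root_node(tree)] <- as.integer(root_state)
    for (i in preorder_edges(tree)) {
      p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
      s <- st[p]
      remaining <- tree$edge.length[i]
      repeat {
        rate <- if (s == 0L) q01 else q10
        if (rate == 0) break
        w <- stats::rexp(1L, rate)
        if (w >= remaining) break
        remaining <- remaining - w
        s <- 1L - s
      }
      st[v] <- s
    }
    regime_painting(tree, st, provenance = "simulated")
  })
}

#' Simulate a continuous trait under BM or OU on a painted tree
#'
#' Exact per-branch transition densities (no Euler discretization): under
#' Brownian motion a child is `Normal(parent, sigma2 * t)`; under the OU
#' process with the branch's regime optimum `theta`,
#' `Normal(parent e^{-a t} + theta (1 - e^{-a t}),
#' (sigma2 / 2a)(1 - e^{-2 a t}))`. Zero-length branches copy the parent
#' value exactly.
#'
#' @param tree a `phylo` object.
#' @param painting a [regime_painting] (ignored for BM).
#' @param model `"BM"` or `"OU"`.
#' @param y0 root trait value.
#' @param sigma2 diffusion variance per unit branch length (> 0).
#' @param alpha OU rate of adaptation (> 0; ignored for BM).
#' @param theta named optima `c(outcrosser =, selfer =)` (ignored for BM).
#' @param seed RNG seed (required).
#' @return named tip-value vector; the full node-value vector is attached as
#'   attribute `"node_values"` (simulated truth for coverage checks).
#' @export
simulate_trait <- function(tree, painting = NULL, model = c("BM", "OU"),
                           y0, sigma2, alpha = NULL, theta = NULL, seed) {
  stopifnot_phylo(tree)
  model <- match.arg(model)
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (model == "OU") {
    if (is.null(alpha) || alpha <= 0) stop("OU requires alpha > 0")
    if (is.null(painting) || is.null(theta)) stop("OU requires a painting and optima")
  }
  with_seed(seed, {
    N <- ape::Ntip(tree) + tree$Nnode
    val <- rep(NA_real_, N)
    val[root_node(tree)] <- y0
    for (i in preorder_edges(tree)) {
      p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
      t <- tree$edge.length[i]
      if (t == 0) { val[v] <- val[p]; next }
      if (model == "BM") {
        val[v] <- stats::rnorm(1L, val[p], sqrt(sigma2 * t))
      } else {
        th <- theta[[c("outcrosser", "selfer")[painting$node_state[v] + 1L]]]
        e <- exp(-alpha * t)
        val[v] <- stats::rnorm(1L, val[p] * e + th * (1 - e),
                               sqrt(sigma2 / (2 * alpha) * (1 - e^2)))
      }
    }
    tips <- stats::setNames(val[seq_len(ape::Ntip(tree))], tree$tip.label)
    attr(tips, "node_values") <- val
    tips
  })
}

# per-gene Gillespie simulation of the critical linear birth-death process
# (birth rate lambda*n, death rate lambda*n) along one branch
bd_branch_sim <- function(n0, t, lambda) {
  n <- n0
  if (lambda == 0 || t == 0) return(n)
  elapsed <- 0
  repeat {
    if (n == 0L) return(0L)
    w <- stats::rexp(1L, 2 * lambda * n)
    elapsed <- elapsed + w
    if (elapsed > t) return(n)
    n <- n + sample(c(-1L, 1L), 1L)
  }
}

#' Simulate a gene-family count matrix on a tree
#'
#' Each family starts from a root count drawn from `root_prior` (a shifted
#' geometric on `{1, 2, ...}` with the given mean by default) and evolves
#' along every branch by the critical per-gene birth-death process at the
#' branch's rate. Tip counts are then perturbed by the symmetric +/-1
#' misobservation model with probability `eps`. Families extinct at every
#' tip are retained and flagged.
#'
#' @param tree a `phylo` object (ultrametric binary for downstream
#'   inference).
#' @param lambda per-gene rate; scalar, or one per class with
#'   `class_of_edge`.
#' @param class_of_edge optional integer class per edge.
#' @param n_families number of families.
#' @param eps misobservation probability in `[0, 0.5)`.
#' @param root_mean mean of the shifted-geometric root-count prior.
#' @param root_counts optional explicit root counts (overrides the prior).
#' @param seed RNG seed (required).
#' @return family x taxon integer matrix with attributes `root_counts` and
#'   `extinct` (logical per family).
#' @export
simulate_gene_families <- function(tree, lambda, class_of_edge = NULL,
                                   n_families = 100L, eps = 0,
                                   root_mean = 5, root_counts = NULL, seed) {
  stopifnot_phylo(tree)
  if (eps < 0 || eps >= 0.5) stop("eps must lie in [0, 0.5)")
  lam_e <- lambda_per_edge(tree, lambda, class_of_edge)
  with_seed(seed, {
    n <- ape::Ntip(tree)
    N <- n + tree$Nnode
    roots <- root_counts %||%
      (1L + stats::rgeom(n_families, prob = 1 / root_mean))
    out <- matrix(0L, n_families, n,
                  dimnames = list(paste0("fam", seq_len(n_families)),
                                  tree$tip.label))
    pre <- preorder_edges(tree)
    nodes <- matrix(0L, n_families, N)
    for (f in seq_len(n_families)) {
      st <- integer(N)
      st[root_node(tree)] <- roots[f]
      for (i in pre) {
        p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
        st[v] <- bd_branch_sim(st[p], tree$edge.length[i], lam_e[i])
      }
      nodes[f, ] <- st
      out[f, ] <- st[seq_len(n)]
    }
    if (eps > 0) {
      flip <- matrix(stats::runif(length(out)) < eps, nrow(out))
      dir <- matrix(sample(c(-1L, 1L), length(out), replace = TRUE), nrow(out))
      out <- pmax(out + flip * dir, 0L)
    }
    attr(out, "root_counts") <- roots
    attr(out, "node_counts") <- nodes
    attr(out, "extinct") <- rowSums(out) == 0L
    out
  })
}

#' The 11-taxon Elegans-like study fixture
#'
#' A fixed binary ultrametric tree of height 1 with eleven in-group genomes:
#' four selfing tips (C. elegans, C. briggsae and two C. tropicalis strains)
#' in three independent selfing origins, the rest outcrossing. On it the
#' fixture simulates (i) a genome-size-like trait in Mb under Brownian
#' motion, (ii) a Mutator-like percent-of-genome trait under the
#' two-optimum OU process with selfer optimum 2.97, outcrosser optimum 6.19,
#' half-life 0.05 of tree height and stationary variance 1.35, and (iii) a
#' gene-family matrix under the birth-death process at rate 0.43. Percent
#' traits are simulated untruncated (the inference model is Gaussian); set
#' `truncate = TRUE` for a display-only floor at 0.
#'
#' @param seed RNG seed (required).
#' @param n_families number of gene families.
#' @param lambda gene birth/death rate.
#' @param theta_self,theta_out regime optima for the percent trait.
#' @param t_half OU half-life as a fraction of tree height.
#' @param v OU stationary variance.
#' @param gs_root,gs_sigma2 root value and BM rate of the genome-size trait.
#' @param truncate floor the percent trait at 0 (display only).
#' @return list with `tree`, `painting` (true regime painting), `traits`
#'   (data.frame: taxon, genome_size_mb, mutator_pct), `families`,
#'   `true` (list of the generating parameter values and node-level truths),
#'   `seed`.
#' @export
make_study_fixture <- function(seed, n_families = 1000L, lambda = 0.43,
                               theta_self = 2.97, theta_out = 6.19,
                               t_half = 0.05, v = 1.35,
                               gs_root = 150, gs_sigma2 = 4000,
                               truncate = FALSE) {
  tree <- fixture_tree()
  painting <- fixture_painting(tree)
  alpha <- log(2) / t_half
  sigma2_ou <- 2 * alpha * v
  theta <- c(outcrosser = theta_out, selfer = theta_self)
  gs <- simulate_trait(tree, model = "BM", y0 = gs_root, sigma2 = gs_sigma2,
                       seed = seed)
  te <- simulate_trait(tree, painting, model = "OU", y0 = theta_out,
                       sigma2 = sigma2_ou, alpha = alpha, theta = theta,
                       seed = seed + 1L)
  fams <- simulate_gene_families(tree, lambda, n_families = n_families,
                                 seed = seed + 2L)
  te_out <- if (truncate) pmax(te, 0) else as.numeric(te)
  traits <- data.frame(taxon = tree$tip.label,
                       genome_size_mb = as.numeric(gs),
                       mutator_pct = te_out)
  list(tree = tree, painting = painting, traits = traits, families = fams,
       true = list(lambda = lambda, theta = theta, alpha = alpha, v = v,
                   t_half = t_half, gs_root = gs_root, gs_sigma2 = gs_sigma2,
                   gs_nodes = attr(gs, "node_values"),
                   te_nodes = attr(te, "node_values")),
       seed = seed)
}

# fixed Elegans-like topology, ultrametric, height exactly 1
fixture_tree <- function() {
  read_newick(text = paste0(
    "((((C_elegans:0.3,C_inopinata:0.3):0.3,((C_briggsae:0.25,C_nigoni:0.25):0.2,",
    "C_sinica:0.45):0.15):0.15,((C_tropicalis_JU1373:0.02,C_tropicalis_NIC58:0.02):0.43,",
    "C_wallacei:0.45):0.3):0.25,((C_remanei:0.25,C_latens:0.25):0.4,C_brenneri:0.65):0.35);"))
}

# true painting: selfer terminal branches for C. elegans, C. briggsae and
# both C. tropicalis strains, plus the tropicalis stem (the selfing origin
# predates the strain split); everything else outcrosser
fixture_painting <- function(tree) {
  N <- ape::Ntip(tree) + tree$Nnode
  st <- rep(0L, N)
  selfers <- c("C_elegans", "C_briggsae", "C_tropicalis_JU1373", "C_tropicalis_NIC58")
  st[match(selfers, tree$tip.label)] <- 1L
  trop_mrca <- ape::getMRCA(tree, c("C_tropicalis_JU1373", "C_tropicalis_NIC58"))
  st[trop_mrca] <- 1L
  regime_painting(tree, st, provenance = "simulated")
}

#' Write a fixture bundle to a directory
#'
#' Emits `tree.nwk`, `regimes.tsv` (taxon, state), `traits.tsv`,
#' `families.tsv` (CAFE-like layout) and `manifest.json` (generating
#' parameters + seed), all plain text.
#'
#' @param fixture output of [make_study_fixture()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(fixture$tree, file.path(dir, "tree.nwk"))
  tips <- fixture$tree$tip.label
  st <- fixture$painting$node_state[seq_along(tips)]
  utils::write.table(
    data.frame(taxon = tips, state = c("outcrosser", "selfer")[st + 1L]),
    file.path(dir, "regimes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$traits, file.path(dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_families(fixture$families, file.path(dir, "families.tsv"))
  jsonlite::write_json(
    list(seed = fixture$seed,
         parameters = fixture$true[c("lambda", "theta", "alpha", "v", "t_half",
                                     "gs_root", "gs_sigma2")]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
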
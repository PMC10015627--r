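# Two-state Mk models for reproductive mode: pruning likelihood, ER/SYM/ARD
# fits compared by AICc, marginal ancestral states, and argmax discretization
# of branch regimes.

# closed-form 2x2 transition probability matrix; rows = from-state 0,1
mk_transition <- function(q01, q10, t) {
  s <- q01 + q10
  if (s == 0 || t == 0) return(diag(2))
  p1 <- q01 / s
  p0 <- q10 / s
  e <- exp(-s * t)
  matrix(c(p0 + p1 * e, p1 - p1 * e,
           p0 - p0 * e, p1 + p0 * e), 2L, 2L, byrow = TRUE)
}

# tip partial likelihood rows: observed state -> unit vector, NA -> (1,1)
mk_tip_partials <- function(tree, tip_states) {
  n <- ape::Ntip(tree)
  st <- tip_states[tree$tip.label]
  if (length(st) != n || (anyNA(names(tip_states)) && is.null(names(tip_states))))
    stop("tip_states must be a named vector covering the tree's tips")
  L <- matrix(1, n, 2L)
  obs <- which(!is.na(st))
  L[obs, ] <- 0
  L[cbind(obs, st[obs] + 1L)] <- 1
  L
}

#' Log-likelihood of a 2-state Mk model by pruning
#'
#' Felsenstein pruning with the closed-form two-state transition
#' probabilities. Missing tip states contribute a flat partial likelihood
#' `(1, 1)`. An impossible data pattern (e.g. both rates 0 with discordant
#' tips) yields `-Inf`.
#'
#' @param tree a `phylo` object (polytomies allowed).
#' @param tip_states named vector over tip labels with values 0 (outcrosser),
#'   1 (selfer) or `NA` (missing).
#' @param q01,q10 transition rates (per unit branch length, >= 0).
#' @param root_prior `"flat"` (0.5, 0.5), `"stationary"`, or a numeric
#'   probability pair.
#' @return the log-likelihood (scalar; may be `-Inf`).
#' @export
mk_loglik <- function(tree, tip_states, q01, q10, root_prior = "flat") {
  stopifnot_phylo(tree)
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
  pr <- mk_root_prior(root_prior, q01, q10)
  part <- mk_partials(tree, tip_states, q01, q10)
  r <- root_node(tree)
  lik <- sum(pr * part$L[r, ])
  if (lik <= 0) return(-Inf)
  log(lik) + part$logscale[r]
}

mk_root_prior <- function(root_prior, q01, q10) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == 2L, all(root_prior >= 0))
    return(root_prior / sum(root_prior))
  }
  switch(match.arg(root_prior, c("flat", "stationary")),
         flat = c(0.5, 0.5),
         stationary = if (q01 + q10 == 0) c(0.5, 0.5)
                      else c(q10, q01) / (q01 + q10))
}

# postorder pruning; returns per-node partial likelihoods with accumulated
# log scaling factors (logscale[v] applies to row v of L)
mk_partials <- function(tree, tip_states, q01, q10) {
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  L <- matrix(1, N, 2L)
  L[seq_len(n), ] <- mk_tip_partials(tree, tip_states)
  logscale <- numeric(N)
  ord <- postorder_edges(tree)
  for (i in ord) {
    p <- tree$edge[i, 1L]
    v <- tree$edge[i, 2L]
    P <- mk_transition(q01, q10, tree$edge.length[i])
    contrib <- as.vector(P %*% L[v, ])
    L[p, ] <- L[p, ] * contrib
    logscale[p] <- logscale[p] + logscale[v]
    m <- max(L[p, ])
    if (m > 0 && (m < 1e-100 || m > 1e100)) {
      L[p, ] <- L[p, ] / m
      logscale[p] <- logscale[p] + log(m)
    }
  }
  list(L = L, logscale = logscale)
}

#' Fit a 2-state Mk model (ER, SYM or ARD) by maximum likelihood
#'
#' Rates are optimized on the log scale within `[1e-8, 1e3]` from three
#' deterministic start points (0.1, 1 and 10 transitions per tree height) to
#' guard against flat likelihood surfaces. For a binary character the ER and
#' SYM constraints coincide, so their fits are identical -- the package keeps
#' both names because the model-selection ladder is conventionally reported
#' over all three.
#'
#' @inheritParams mk_loglik
#' @param model `"ER"`, `"SYM"` or `"ARD"`.
#' @param root_prior as in [mk_loglik()].
#' @return an object of class `mk_fit`: rates, log-likelihood, `k`, AICc
#'   (with `n` = number of tips), and node marginal state probabilities.
#' @export
fit_mk <- function(tree, tip_states, model = c("ER", "SYM", "ARD"),
                   root_prior = "flat") {
  stopifnot_phylo(tree)
  model <- match.arg(model)
  n <- ape::Ntip(tree)
  st <- tip_states[tree$tip.label]
  if (length(unique(stats::na.omit(st))) < 2L)
    warning("all observed tip states identical; rate estimate lies at the lower bound")
  lb <- log(1e-8); ub <- log(1e3)
  h <- max(node_depths(tree))
  starts <- log(c(0.1, 1, 10) / max(h, .Machine$double.eps))
  starts <- pmin(pmax(starts, lb), ub)
  npar <- if (model == "ARD") 2L else 1L
  nll <- function(lq) {
    q <- exp(lq)
    if (npar == 1L) -mk_loglik(tree, tip_states, q[1L], q[1L], root_prior)
    else -mk_loglik(tree, tip_states, q[1L], q[2L], root_prior)
  }
  best <- NULL
  for (s0 in starts) {
    par0 <- rep(s0, npar)
    fit <- tryCatch(
      stats::optim(par0, nll, method = "L-BFGS-B",
                   lower = rep(lb, npar), upper = rep(ub, npar)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("Mk optimization failed")
  q <- exp(best$par)
  q01 <- q[1L]; q10 <- q[length(q)]
  ll <- -best$value
  k <- npar
  ac <- if (n > k + 1L) aicc(ll, k, n) else {
    warning("too few tips for AICc (n <= k + 1); reporting NA")
    NA_real_
  }
  out <- structure(list(model = model, q01 = q01, q10 = q10,
                        loglik = ll, k = k, n = n,
                        aicc = ac,
                        root_prior = root_prior),
                   class = "mk_fit")
  out$marginals <- marginal_ancestral_states(out, tree, tip_states)
  out
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk fit [%s]: q01=%.5g q10=%.5g  lnL=%.4f  k=%d  AICc=%.4f (n=%d)\n",
              x$model, x$q01, x$q10, x$loglik, x$k, x$aicc, x$n))
  invisible(x)
}

#' Marginal ancestral state probabilities for every node
#'
#' Combined upward/downward (re-rooting) pass: the marginal posterior of each
#' node's state given all tip data and the fitted rates. Tips with observed
#' states return a point mass; missing-data tips get a genuine marginal.
#'
#' @param fit an `mk_fit`, or a list with elements `q01`, `q10`,
#'   `root_prior`.
#' @param tree the tree used in the fit.
#' @param tip_states tip state vector as in [mk_loglik()].
#' @return matrix `(Ntip + Nnode) x 2` of probabilities, columns
#'   `P0` (outcrosser) and `P1` (selfer); rows sum to 1.
#' @export
marginal_ancestral_states <- function(fit, tree, tip_states) {
  stopifnot_phylo(tree)
  q01 <- fit$q01; q10 <- fit$q10
  pr <- mk_root_prior(fit$root_prior %||% "flat", q01, q10)
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  part <- mk_partials(tree, tip_states, q01, q10)
  L <- part$L
  ei <- edge_into(tree)
  kids <- children_of(tree)
  # S[v, ] = message from subtree v to its parent: row s_p -> P(t_v) %*% L_v
  S <- matrix(1, N, 2L)
  for (v in seq_len(N)) {
    if (is.na(ei[v])) next
    P <- mk_transition(q01, q10, tree$edge.length[ei[v]])
    S[v, ] <- as.vector(P %*% L[v, ])
  }
  U <- matrix(0, N, 2L)
  r <- root_node(tree)
  U[r, ] <- pr
  for (i in preorder_edges(tree)) {
    p <- tree$edge[i, 1L]
    v <- tree$edge[i, 2L]
    sib <- setdiff(kids[[p]], v)
    up <- U[p, ]
    for (w in sib) up <- up * S[w, ]
    P <- mk_transition(q01, q10, tree$edge.length[i])
    uv <- as.vector(up %*% P)   # sum over parent state
    tot <- sum(uv)
    U[v, ] <- if (tot > 0) uv / tot else uv
  }
  M <- L * U
  rs <- rowSums(M)
  bad <- rs <= 0
  M[!bad, ] <- M[!bad, ] / rs[!bad]
  M[bad, ] <- 0.5
  # observed tips: exact point mass
  st <- tip_states[tree$tip.label]
  obs <- which(!is.na(st))
  M[obs, ] <- 0
  M[cbind(obs, st[obs] + 1L)] <- 1
  colnames(M) <- c("P0", "P1")
  M
}

#' Discretize marginal states into a branch regime painting
#'
#' Each branch takes the argmax state of its child node's marginal
#' probabilities (a branch's regime is what the lineage is by the time it
#' ends). Exact ties are resolved by `tie_rule` (default: inherit the
#' parent's already-resolved state; a root tie falls back to outcrosser) and
#' flagged. Tip branches always match observed tip states.
#'
#' @param marginals matrix from [marginal_ancestral_states()].
#' @param tree the tree.
#' @param tip_states observed tip states (enforced on tip branches).
#' @param tie_rule `"parent"`, `"outcrosser"` or `"selfer"`.
#' @return a [regime_painting] with provenance `"argmax"`.
#' @export
paint_regimes <- function(marginals, tree, tip_states,
                          tie_rule = c("parent", "outcrosser", "selfer")) {
  stopifnot_phylo(tree)
  tie_rule <- match.arg(tie_rule)
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  st <- rep(NA_integer_, N)
  tie <- rep(FALSE, N)
  par <- parent_of(tree)
  fallback <- switch(tie_rule, parent = NA_integer_, outcrosser = 0L, selfer = 1L)
  r <- root_node(tree)
  assign_state <- function(v) {
    d <- marginals[v, 2L] - marginals[v, 1L]
    if (d > 0) return(1L)
    if (d < 0) return(0L)
    tie[v] <<- TRUE
    if (!is.na(fallback)) return(fallback)
    if (v == r) return(0L)          # root tie: outcrosser, flagged
    st[par[v]]                       # parent already resolved (preorder)
  }
  st[r] <- assign_state(r)
  for (i in preorder_edges(tree)) st[tree$edge[i, 2L]] <- assign_state(tree$edge[i, 2L])
  obs_tips <- tip_states[tree$tip.label]
  obs <- which(!is.na(obs_tips))
  st[obs] <- as.integer(obs_tips[obs])
  regime_painting(tree, st, tie, provenance = "argmax")
}

#' Fit the ER/SYM/ARD model ladder and select by AICc
#'
#' @inheritParams fit_mk
#' @param models character vector of models to fit.
#' @return list with `fits` (named list of `mk_fit`), `table` (model, k,
#'   lnL, AICc, delta), and `best` (name of the lowest-AICc model; ties go to
#'   the fewest parameters).
#' @export
fit_mk_ladder <- function(tree, tip_states, models = c("ER", "SYM", "ARD"),
                          root_prior = "flat") {
  fits <- lapply(models, function(m) fit_mk(tree, tip_states, m, root_prior))
  names(fits) <- models
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  k <- vapply(fits, `[[`, numeric(1), "k")
  ord <- order(a, k)
  tab <- data.frame(model = models[ord], k = k[ord],
                    loglik = vapply(fits, `[[`, numeric(1), "loglik")[ord],
                    aicc = a[ord], delta_aicc = a[ord] - min(a))
  list(fits = fits, table = tab, best = tab$model[1L])
}
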
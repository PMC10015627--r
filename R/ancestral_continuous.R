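# Brownian-motion ancestral reconstruction of a continuous trait (genome
# size) with the rate estimated by restricted maximum likelihood and 95%
# confidence intervals on every internal node.

# tip covariance with a guard for zero-distance sister tips (grafted strains
# at branch length 0): their shared-depth matrix is singular, so the
# offending terminal depths are floored apart by 1e-12 and flagged
bm_tip_covariance_guarded <- function(tree) {
  V <- bm_tip_covariance(tree)
  ok <- !inherits(tryCatch(chol(V), error = function(e) e), "error")
  floored <- FALSE
  if (!ok) {
    diag(V) <- diag(V) + 1e-12
    floored <- TRUE
    warning("zero-distance tips detected; terminal variances floored by 1e-12")
  }
  attr(V, "floored") <- floored
  V
}

#' REML estimate of the Brownian-motion rate
#'
#' The restricted-likelihood maximizer has the closed form
#' `sigma2 = (y - mu)' V0^-1 (y - mu) / (n - 1)` with `mu` the GLS mean and
#' `V0` the shared-depth matrix -- equivalently the mean of squared
#' standardized phylogenetically independent contrasts. REML (rather than
#' ML) removes the downward bias from estimating the ancestral mean.
#'
#' @param tree a `phylo` object (need not be ultrametric; polytomies and
#'   zero-length branches allowed).
#' @param trait named numeric vector over tip labels.
#' @return list with `sigma2`, `log_restricted_lik`, `mu` (GLS root mean).
#' @export
bm_sigma2_reml <- function(tree, trait) {
  stopifnot_phylo(tree)
  y <- trait[tree$tip.label]
  if (anyNA(y)) stop("trait missing for some tips")
  n <- length(y)
  if (n < 2L) stop("at least 2 tips with data required")
  V0 <- bm_tip_covariance_guarded(tree)
  R <- chol(V0)
  yt <- backsolve(R, y, transpose = TRUE)
  ot <- backsolve(R, rep(1, n), transpose = TRUE)
  oo <- sum(ot * ot)
  mu <- sum(ot * yt) / oo
  rss <- sum((yt - ot * mu)^2)
  sigma2 <- rss / (n - 1)
  if (all(y == y[1L])) sigma2 <- rss <- 0
  if (sigma2 == 0) warning("trait is constant; sigma2 = 0")
  llr <- if (sigma2 > 0)
    -0.5 * ((n - 1) * log(2 * pi * sigma2) + 2 * sum(log(diag(R))) +
              log(oo) + rss / sigma2)
  else Inf
  list(sigma2 = sigma2, log_restricted_lik = llr, mu = mu)
}

#' Ancestral state reconstruction under Brownian motion
#'
#' Node means are the best linear unbiased predictions under BM with the
#' REML rate: the joint tip+node Gaussian is conditioned on the tips, with
#' the unknown root mean handled by GLS (its estimation variance propagates
#' into every node's conditional variance, so the root CI is
#' `mu +/- 1.96 sigma / sqrt(1' V^-1 1)` rather than degenerate). Tip nodes
#' are returned with variance 0. The 95% interval uses the normal 1.96
#' multiplier, conditioning on the estimated rate.
#'
#' @inheritParams bm_sigma2_reml
#' @param conf_mult CI half-width multiplier (default `qnorm(0.975)`).
#' @return an object of class `ancestral_estimate`: a data.frame with one
#'   row per node (`node`, `label`, `mean`, `var`, `ci_low`, `ci_high`) and
#'   attributes `sigma2` and `log_restricted_lik`.
#' @export
reconstruct_ancestral_bm <- function(tree, trait, conf_mult = stats::qnorm(0.975)) {
  stopifnot_phylo(tree)
  y <- trait[tree$tip.label]
  if (anyNA(y)) stop("trait missing for some tips")
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  reml <- bm_sigma2_reml(tree, trait)
  s2 <- reml$sigma2
  d <- node_depths(tree)
  mfull <- ape::mrca(tree, full = TRUE)
  Vall <- matrix(d[mfull], N, N)
  tips <- seq_len(n)
  nodes <- setdiff(seq_len(N), tips)
  Vtt <- bm_tip_covariance_guarded(tree)
  R <- chol(Vtt)
  solve_V <- function(B) backsolve(R, backsolve(R, B, transpose = TRUE))
  one <- rep(1, n)
  Vi1 <- solve_V(one)
  oo <- sum(Vi1)
  mu <- sum(Vi1 * y) / oo
  H <- Vall[nodes, tips, drop = FALSE] %*% solve_V(diag(n))
  mean_n <- mu + as.vector(H %*% (y - mu))
  cond <- diag(Vall[nodes, nodes, drop = FALSE] -
                 H %*% t(Vall[nodes, tips, drop = FALSE]))
  hslack <- 1 - as.vector(H %*% one)
  var_n <- s2 * (pmax(cond, 0) + hslack^2 / oo)
  means <- c(y, mean_n)
  vars <- c(rep(0, n), pmax(var_n, 0))
  out <- data.frame(node = seq_len(N),
                    label = node_labels_all(tree),
                    mean = means, var = vars,
                    ci_low = means - conf_mult * sqrt(vars),
                    ci_high = means + conf_mult * sqrt(vars))
  attr(out, "sigma2") <- s2
  attr(out, "log_restricted_lik") <- reml$log_restricted_lik
  class(out) <- c("ancestral_estimate", "data.frame")
  out
}
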
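## Joint prior on node ages under two constructions, sampled by MCMC
## without sequence data. The conditional construction multiplies the
## calibration densities by a tree-prior kernel for the *uncalibrated*
## nodes only (truncation-based, MCMCTree-style); the multiplicative
## construction multiplies the calibration densities by the tree-prior
## kernel over *all* non-root nodes (BEAST-style). Both are truncated to
## the region where every ancestor is older than its descendants.

#' Tree-prior kernel parameters
#'
#' @param kernel `"uniform"` (uniform order statistics on `(0, t_root)`,
#'   the default) or `"birth-death"`.
#' @param birth per-lineage speciation rate (per Ma), > 0.
#' @param death per-lineage extinction rate (per Ma), >= 0.
#' @param sampling sampling fraction in `[0, 1]`.
#' @return a `tree_prior_params` list.
#' @export
tree_prior_params <- function(kernel = c("uniform", "birth-death"),
                              birth = 1, death = 1, sampling = 0.1) {
  kernel <- match.arg(kernel)
  if (birth <= 0 || death < 0 || sampling < 0 || sampling > 1) {
    stop("require birth > 0, death >= 0, 0 <= sampling <= 1")
  }
  structure(list(kernel = kernel, birth = birth, death = death,
                 sampling = sampling),
            class = "tree_prior_params")
}

#' MCMC settings
#'
#' Defaults give desk-scale runs with effective sample sizes comfortably
#' above 200 on trees of a few dozen nodes. Multiplier step widths are
#' auto-tuned towards acceptance 0.2-0.5 during burn-in only.
#'
#' @param n_iter total sweeps (one sweep updates every node once plus the
#'   root and, for posterior runs, the clock rate).
#' @param burn_in sweeps discarded (default 25% of `n_iter`).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param root_step,rate_step initial log-scale multiplier step widths.
#' @param tune auto-tune step widths during burn-in.
#' @export
mcmc_settings <- function(n_iter = 2e6, burn_in = floor(n_iter / 4),
                          thin = 100, root_step = 0.1, rate_step = 0.2,
                          tune = TRUE) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
       thin = as.integer(thin), root_step = root_step,
       rate_step = rate_step, tune = tune)
}

#' Conditional birth-death node-age kernel density
#'
#' Log density at `age` of an interior node given the root age, under the
#' chosen tree-prior kernel. The uniform kernel is `log(1 / t_root)`; the
#' birth-death kernel is the standard conditional node-age density for a
#' birth-death process with sampling, integrating to 1 on `(0, t_root)`.
#' For `birth == death` the birth-death kernel collapses to the uniform
#' kernel.
#'
#' @param age node age (Ma), must lie in `(0, t_root)` (else `-Inf`).
#' @param t_root root age (Ma).
#' @param params a [tree_prior_params].
#' @return log density (log per-Ma).
#' @export
bd_kernel_logpdf <- function(age, t_root, params = tree_prior_params()) {
  kern <- if (params$kernel == "uniform") 0L else 1L
  vapply(age, bd_kernel_logpdf_cpp, numeric(1), troot = t_root, kern = kern,
         lambda = params$birth, mu = params$death, rho = params$sampling)
}

## internal: shared validation + encoding for both constructions
.prior_setup <- function(tree, cals, params, construction) {
  construction <- match.arg(construction, c("conditional", "multiplicative"))
  stopifnot(inherits(tree, "timetree"))
  if (inherits(cals, "calibration")) cals <- calibration_set(list(cals))
  stopifnot(inherits(cals, "calibration_set"))
  st <- tree_structure(tree)
  cm <- cal_matrix(tree, cals)
  root_lab <- tree$labels[st$root]
  has_root_cal <- !is.na(root_lab) && root_lab %in% names(cals)
  if (!has_root_cal || !cal_has_upper(cals[[root_lab]])) {
    if (construction == "conditional") {
      stop("the conditional construction requires an upper-bounded ",
           "calibration at the root")
    } else {
      stop("the multiplicative construction requires an explicit root ",
           "calibration with an upper bound (no silent default)")
    }
  }
  # infeasibility: a descendant hard minimum at or above an ancestral hard
  # maximum leaves zero support; raise loudly instead of truncating silently
  for (a in names(cals)) {
    amax <- cal_hard_max(cals[[a]])
    if (!is.finite(amax)) next
    anode <- node_by_label(tree, a)
    for (d in names(cals)) {
      if (d == a) next
      dnode <- node_by_label(tree, d)
      if (is_ancestor(tree, anode, dnode) && cals[[d]]$t_l >= amax) {
        stop("infeasible calibration pair: minimum of '", d,
             "' (", cals[[d]]$t_l, " Ma) is not below the hard maximum of ",
             "ancestor '", a, "' (", amax, " Ma)")
      }
    }
  }
  kern <- if (params$kernel == "uniform") 0L else 1L
  list(st = st, cm = cm, kern = kern,
       construction = if (construction == "conditional") 0L else 1L,
       construction_name = construction)
}

## internal: is `anc` an ancestor of `des` (phylo node ids)?
is_ancestor <- function(tree, anc, des) {
  n <- n_tips(tree)
  edge <- tree$phy$edge
  parent_of <- integer(max(edge))
  parent_of[edge[, 2L]] <- edge[, 1L]
  v <- des
  while (v != root_node(tree)) {
    v <- parent_of[v]
    if (v == anc) return(TRUE)
  }
  anc == root_node(tree) && des != root_node(tree)
}

#' Log density of the joint prior on node ages
#'
#' Evaluates the (unnormalised) joint prior at a full internal node-age
#' vector, under the conditional or multiplicative construction. States
#' violating the ancestor-older-than-descendant ordering have density
#' `-Inf` — that is the truncation.
#'
#' @param ages numeric vector of internal node ages in phylo node order
#'   (as returned by [node_ages()]).
#' @param tree a [timetree].
#' @param calibrations a [calibration_set]; at most one per node. Under
#'   either construction the root must carry an upper-bounded calibration.
#' @param params a [tree_prior_params].
#' @param construction `"conditional"` or `"multiplicative"`.
#' @return log density (unnormalised).
#' @export
log_joint_prior <- function(ages, tree, calibrations,
                            params = tree_prior_params(),
                            construction = "conditional") {
  su <- .prior_setup(tree, calibrations, params, construction)
  joint_logprior_cpp(as.numeric(ages), su$st$parent, su$st$ch_int,
                     su$st$ch_tip, su$st$root, su$cm, su$construction,
                     su$kern, params$birth, params$death, params$sampling)
}

## internal: feasible initial ages — bottom-up minimum floors from
## calibration minima, then top-down placement inside each window
init_ages <- function(tree, cals) {
  st <- tree_structure(tree)
  M <- st$M
  cm <- cal_matrix(tree, cals)
  lb <- numeric(M)
  # postorder: children before parents
  ord <- rev(preorder_internal(st))
  for (i in ord) {
    m <- if (cm[i, "fam"] != 0) cm[i, "tL"] else 0
    for (ch in st$ch_int[[i]]) m <- max(m, lb[ch])
    lb[i] <- m + 1e-3
  }
  ages <- numeric(M)
  for (i in preorder_internal(st)) {
    if (i == st$root) {
      up <- if (cm[i, "fam"] == 1 && cm[i, "tU"] > 0) cm[i, "tU"]
            else 1.5 * lb[i] + 1
      ages[i] <- max((lb[i] + up) / 2, lb[i] * 1.05 + 1e-3)
    } else {
      up <- ages[st$parent[i]]
      ages[i] <- lb[i] + 0.5 * (up - lb[i])
    }
  }
  ages
}

preorder_internal <- function(st) {
  out <- integer(0)
  stack <- st$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, st$ch_int[[v]])
  }
  out
}

#' Sample the joint prior on node ages by MCMC
#'
#' Runs a Metropolis-Hastings chain over internal node ages targeting
#' [log_joint_prior()] — an analysis without sequence data, exposing the
#' *effective* marginal priors. Moves are (i) a uniform slide for each
#' non-root node within (oldest child age, parent age) and (ii) a
#' multiplier move on the root age (Jacobian included; the soft upper
#' bound leaves the support unbounded above). Every stored draw satisfies
#' the age ordering by construction.
#'
#' @param tree a [timetree].
#' @param calibrations a [calibration_set].
#' @param params a [tree_prior_params].
#' @param construction `"conditional"` (default) or `"multiplicative"`.
#' @param mcmc an [mcmc_settings()] list.
#' @param seed integer seed; the chain is reproducible given the seed.
#' @return a `prior_samples` object: `draws` (matrix, one column per
#'   internal node, labelled), `ess` per node (flagged if < 200),
#'   `accept`, `settings`, `seed`, `construction`.
#' @export
sample_prior <- function(tree, calibrations, params = tree_prior_params(),
                         construction = "conditional",
                         mcmc = mcmc_settings(), seed = 1L) {
  su <- .prior_setup(tree, calibrations, params, construction)
  set.seed(seed)
  init <- init_ages(tree, calibrations)
  res <- mh_chain_cpp(
    su$st$parent, su$st$ch_int, su$st$ch_tip, su$st$root, su$cm,
    su$construction, su$kern, params$birth, params$death, params$sampling,
    init, mcmc$n_iter, mcmc$burn_in, mcmc$thin,
    FALSE, matrix(0L, 0, 0), numeric(0),
    0, 0, 0, mcmc$root_step, mcmc$rate_step, mcmc$tune
  )
  draws <- res$draws
  colnames(draws) <- names(node_ages(tree))
  ess <- apply(draws, 2, ess_mean)
  if (any(ess < 200)) {
    warning("ESS < 200 at node(s): ",
            paste(colnames(draws)[ess < 200], collapse = ", "))
  }
  structure(
    list(draws = draws, rate_draws = NULL, ess = ess,
         accept = res$accept, settings = mcmc, seed = seed,
         construction = su$construction_name, tree = tree,
         calibrations = calibrations, params = params),
    class = "prior_samples"
  )
}

#' @export
print.prior_samples <- function(x, ...) {
  cat("MCMC sample of node ages:", nrow(x$draws), "stored draws,",
      ncol(x$draws), "nodes (", x$construction, "construction )\n")
  cat("min ESS:", format(round(min(x$ess), 1)), "  seed:", x$seed, "\n")
  invisible(x)
}

#' Effective marginal prior summary at one node
#'
#' @param samples a `prior_samples` object.
#' @param node node label (or column index into the draw matrix).
#' @return list with `mean`, `quantiles` (2.5/50/97.5%, type-7), a
#'   Freedman-Diaconis `histogram`, `n` and `seed`.
#' @export
effective_marginal <- function(samples, node) {
  stopifnot(inherits(samples, "prior_samples"))
  if (nrow(samples$draws) == 0L) stop("empty sample")
  x <- if (is.character(node)) {
    if (!node %in% colnames(samples$draws)) {
      stop("node '", node, "' not in sample")
    }
    samples$draws[, node]
  } else samples$draws[, node]
  if (samples$ess[if (is.character(node)) node else node] < 200) {
    warning("ESS below 200 for node ", node,
            "; summaries may be imprecise")
  }
  brk <- fd_breaks(x)
  list(mean = mean(x),
       quantiles = stats::quantile(x, c(0.025, 0.5, 0.975), type = 7),
       histogram = graphics::hist(x, breaks = brk, plot = FALSE),
       n = length(x), seed = samples$seed)
}

## Freedman-Diaconis breaks, robust to zero-IQR degenerate chains
fd_breaks <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr == 0 || length(unique(x)) < 3L) return(3L)
  w <- 2 * iqr / length(x)^(1 / 3)
  max(3L, ceiling(diff(range(x)) / w))
}

#' Effective sample size of a chain mean
#'
#' Initial positive-sequence estimator: autocorrelations are summed in
#' consecutive pairs until a pair turns negative.
#'
#' @param x numeric chain.
#' @return estimated ESS (capped at `length(x)`).
#' @export
ess_mean <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  lag_max <- min(n - 2L, max(50L, floor(10 * log10(n))), 2000L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    g <- rho[k] + rho[k + 1L]
    if (g < 0) break
    s <- s + g
    k <- k + 2L
  }
  min(n, n / (1 + 2 * s))
}
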
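## Minimal Bayesian dating engine: strict molecular clock, JC69
## substitution model, Felsenstein pruning. Enough machinery to contrast
## posteriors with priors and to drive cross-validation rounds end-to-end
## on synthetic alignments.

#' Nucleotide alignment container
#'
#' @param seqs named character vector of equal-length sequences over
#'   `A,C,G,T` (case-insensitive; other symbols are treated as missing),
#'   or a character matrix with one row per taxon and one column per site.
#' @return a `dna_alignment`: character matrix, rownames are taxa.
#' @export
dna_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("all sequences must have the same length")
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate taxon names")
  structure(m, class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", nrow(x), "taxa x", ncol(x), "sites\n")
  invisible(x)
}

#' Read / write FASTA alignments
#'
#' @param path file path.
#' @param aln a `dna_alignment`.
#' @export
read_fasta <- function(path) {
  dm <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(dm)))
  dna_alignment(m)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(aln, path) {
  db <- ape::as.DNAbin(unclass(aln))
  ape::write.FASTA(db, path)
  invisible(path)
}

## internal: compress an alignment to site patterns in the tip order the
## sampler expects (tree tip order); states 0..3 = A,C,G,T, -1 = missing
site_patterns <- function(aln, tree) {
  taxa <- tree$phy$tip.label
  miss <- setdiff(taxa, rownames(aln))
  if (length(miss)) {
    stop("alignment lacks taxa present in the tree: ",
         paste(miss, collapse = ", "))
  }
  m <- unclass(aln)[taxa, , drop = FALSE]
  if (ncol(m) == 0L) {
    return(list(patterns = matrix(0L, nrow(m), 0), weights = numeric(0)))
  }
  code <- matrix(match(m, c("A", "C", "G", "T")) - 1L, nrow = nrow(m))
  code[is.na(code)] <- -1L
  key <- apply(code, 2, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(patterns = code[, first, drop = FALSE],
       weights = as.numeric(tab))
}

#' JC69 log likelihood under a strict clock
#'
#' Felsenstein pruning with branch expected substitutions
#' `rate * (age(parent) - age(child))`. Deterministic.
#'
#' @param alignment a [dna_alignment]; taxa must cover the tree's tips.
#' @param tree a [timetree].
#' @param rate substitutions per site per Ma, > 0.
#' @return log likelihood (0 for a zero-length alignment).
#' @export
jc69_loglik <- function(alignment, tree, rate) {
  stopifnot(rate > 0)
  sp <- site_patterns(alignment, tree)
  if (ncol(sp$patterns) == 0L) return(0)
  st <- tree_structure(tree)
  jc69_loglik_cpp(st$parent, st$ch_int, st$ch_tip, st$root,
                  node_ages(tree), rate, sp$patterns, sp$weights)
}

#' Strict-clock model with a gamma rate prior
#'
#' @param rate_shape gamma shape of the rate prior (default 2).
#' @param rate_mean gamma mean of the rate prior (substitutions/site/Ma).
#'   If `NULL`, [sample_posterior()] sets it so that the expected
#'   root-to-tip divergence at the root-calibration midpoint is 0.1
#'   substitutions per site — a weak default on the scale of typical
#'   vertebrate nuclear data.
#' @export
clock_model <- function(rate_shape = 2, rate_mean = NULL) {
  stopifnot(rate_shape > 0, is.null(rate_mean) || rate_mean > 0)
  structure(list(rate_shape = rate_shape, rate_mean = rate_mean),
            class = "clock_model")
}

#' Sample the posterior of node ages and clock rate
#'
#' Metropolis-Hastings over node ages and the strict-clock rate targeting
#' `log_joint_prior + jc69_loglik`, with the same move set as
#' [sample_prior()] plus a rate multiplier move. With a zero-site
#' alignment the likelihood is constant and the posterior equals the
#' prior — the package's core sanity law, and the standard prior-check
#' protocol of running a dating analysis without sequence data.
#'
#' @inheritParams sample_prior
#' @param alignment a [dna_alignment].
#' @param clock a [clock_model()].
#' @return a `prior_samples` object carrying, additionally, `rate_draws`
#'   and a per-node `summary` data frame (posterior mean, 95% equal-tail
#'   and HPD intervals).
#' @export
sample_posterior <- function(tree, calibrations, alignment,
                             clock = clock_model(),
                             params = tree_prior_params(),
                             construction = "conditional",
                             mcmc = mcmc_settings(), seed = 1L) {
  su <- .prior_setup(tree, calibrations, params, construction)
  sp <- site_patterns(alignment, tree)
  rate_mean <- clock$rate_mean
  if (is.null(rate_mean)) {
    root_lab <- tree$labels[su$st$root]
    rc <- calibrations[[root_lab]]
    mid <- if (cal_has_upper(rc)) (rc$t_l + rc$t_u) / 2 else 1.5 * rc$t_l
    rate_mean <- 0.1 / mid
  }
  rate_rate <- clock$rate_shape / rate_mean  # gamma rate parameter
  set.seed(seed)
  init <- init_ages(tree, calibrations)
  res <- mh_chain_cpp(
    su$st$parent, su$st$ch_int, su$st$ch_tip, su$st$root, su$cm,
    su$construction, su$kern, params$birth, params$death, params$sampling,
    init, mcmc$n_iter, mcmc$burn_in, mcmc$thin,
    ncol(sp$patterns) > 0L, sp$patterns, sp$weights,
    rate_mean, clock$rate_shape, rate_rate,
    mcmc$root_step, mcmc$rate_step, mcmc$tune
  )
  draws <- res$draws
  colnames(draws) <- names(node_ages(tree))
  ess <- apply(draws, 2, ess_mean)
  if (any(ess < 200)) {
    warning("ESS < 200 at node(s): ",
            paste(colnames(draws)[ess < 200], collapse = ", "))
  }
  eti <- t(apply(draws, 2, stats::quantile, c(0.025, 0.975), type = 7))
  hpd <- t(apply(draws, 2, hpd_interval))
  summ <- data.frame(
    node = colnames(draws), mean = colMeans(draws),
    lower95 = eti[, 1], upper95 = eti[, 2],
    hpd_lower = hpd[, 1], hpd_upper = hpd[, 2], ess = ess,
    row.names = NULL
  )
  rate_draws <- if (ncol(sp$patterns) > 0L) res$rate_draws else NULL
  structure(
    list(draws = draws, rate_draws = rate_draws, ess = ess,
         accept = res$accept, settings = mcmc, seed = seed,
         construction = su$construction_name, tree = tree,
         calibrations = calibrations, params = params, summary = summ),
    class = "prior_samples"
  )
}

#' Highest posterior density interval from draws
#'
#' Shortest interval containing a fraction `prob` of the sorted draws.
#'
#' @param x numeric draws.
#' @param prob interval mass (default 0.95).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, floor(prob * n))
  if (k >= n) return(c(x[1L], x[n]))
  widths <- x[(k + 1L):n] - x[1L:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}
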
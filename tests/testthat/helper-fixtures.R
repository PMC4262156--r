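# Shared fixtures and independent oracles. Oracles are deliberately
# written with different structure (enumeration / direct loops /
# quadrature) from the implementation paths they check.

two_tip_tree <- function() parse_newick("(A:200,B:200)Root;")

three_tip_tree <- function() parse_newick("((A:5,B:5)Inner:5,C:10)Root;")

nested_cals <- function() {
  calibration_set(list(
    calibration("Root", "uniform", t_l = 10, t_u = 20),
    calibration("Inner", "uniform", t_l = 5, t_u = 15)
  ))
}

empty_alignment <- function(taxa) {
  dna_alignment(matrix(character(0), nrow = length(taxa), ncol = 0,
                       dimnames = list(taxa, NULL)))
}

# Brute-force JC69 likelihood by exhaustive summation over internal-state
# assignments (only feasible for tiny trees). `tree` must be the 3-tip
# fixture shape ((A,B)Inner,C)Root.
jc69_brute_three_tip <- function(aln, t_inner, t_root, rate) {
  p_same <- function(v) 0.25 + 0.75 * exp(-4 * v / 3)
  p_diff <- function(v) 0.25 - 0.25 * exp(-4 * v / 3)
  trans <- function(x, y, v) if (x == y) p_same(v) else p_diff(v)
  m <- unclass(aln)
  states <- c("A", "C", "G", "T")
  total <- 0
  for (site in seq_len(ncol(m))) {
    a <- m["A", site]; b <- m["B", site]; c <- m["C", site]
    site_lik <- 0
    for (r in states) for (i in states) {
      site_lik <- site_lik + 0.25 *
        trans(r, i, rate * (t_root - t_inner)) *
        trans(i, a, rate * t_inner) *
        trans(i, b, rate * t_inner) *
        trans(r, c, rate * t_root)
    }
    total <- total + log(site_lik)
  }
  total
}

# Brute-force cross-validation statistics from a stub table: independent
# loop structure over data-frame rows.
xval_brute <- function(stub, minima, maxima = NULL) {
  focals <- unique(stub$focal_node)
  out <- list()
  for (x in focals) {
    dsum <- 0; ssq <- 0; dsum_mm <- 0; ssq_mm <- 0; k <- 0
    for (row in seq_len(nrow(stub))) {
      if (stub$focal_node[row] != x) next
      tgt <- stub$target_node[row]
      ma <- stub$mean_age[row]
      k <- k + 1
      dsum <- dsum + (ma - minima[[tgt]])
      ssq <- ssq + (ma - minima[[tgt]])^2
      if (!is.null(maxima)) {
        d <- 0
        if (ma > maxima[[tgt]]) d <- ma - maxima[[tgt]]
        if (ma < minima[[tgt]]) d <- ma - minima[[tgt]]
        dsum_mm <- dsum_mm + d
        ssq_mm <- ssq_mm + d^2
      }
    }
    out[[x]] <- list(dbar = dsum / k, ss = ssq,
                     dbar_mm = if (is.null(maxima)) NA else dsum_mm / k,
                     ss_mm = if (is.null(maxima)) NA else ssq_mm)
  }
  out
}

# Quadrature marginals of the conditional 3-tip nested joint prior
# f(t_root, t_inner) prop. to f_R(t_root) f_I(t_inner) 1(t_inner < t_root),
# evaluated through log_joint_prior itself (used for sampler-vs-density
# equivalence) on a fixed grid.
three_tip_quadrature <- function(tree, cals, construction = "conditional",
                                 upper = 80, n = 400) {
  tt <- seq(1e-3, upper, length.out = n)
  h <- tt[2] - tt[1]
  grid <- outer(tt, tt, Vectorize(function(t2, t1) {
    exp(log_joint_prior(c(t2, t1), tree, cals,
                        construction = construction))
  }))
  grid[!is.finite(grid)] <- 0
  Z <- sum(grid) * h * h
  list(t = tt, root = rowSums(grid) * h / Z, inner = colSums(grid) * h / Z)
}

# TV distance between sampled draws and a density tabulated on the
# quadrature grid, using the grid cells as bins.
tv_draws_vs_grid <- function(draws, t, dens) {
  h <- t[2] - t[1]
  edges <- c(t[1] - h / 2, t + h / 2)
  iv <- findInterval(draws, edges)
  emp <- tabulate(iv, nbins = length(t)) / length(draws)
  outside <- mean(iv == 0 | iv > length(t))
  th <- dens * h
  th <- th / sum(th)
  0.5 * (sum(abs(emp - th)) + outside)
}
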
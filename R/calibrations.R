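## Calibration prior density families for node ages: uniform with hard
## minimum and soft maximum, and the truncated Cauchy anchored on a minimum.
## All ages in Ma before present; densities per Ma.

#' Create a node-age calibration
#'
#' A calibration attaches a prior density for the age of one clade. Two
#' families are supported:
#'
#' * `"uniform"`: uniform between a minimum `t_L` and a maximum `t_U`; the
#'   minimum is hard by default (`tail_l = 0`, no mass below) and the
#'   maximum soft, with a fixed probability mass `tail_r` (default 2.5%)
#'   above `t_U` carried by an exponential tail whose density is continuous
#'   at the bound.
#' * `"cauchy"`: a Cauchy density with location \eqn{t_L(1 + p)} and scale
#'   \eqn{c\,t_L}, renormalised on \eqn{[t_L, \infty)} (hard minimum). The
#'   location offset `p` and scale factor `c` are dimensionless and control
#'   how far the divergence is expected to predate its oldest fossil.
#'
#' @param node clade (node) label the calibration attaches to.
#' @param family `"uniform"` or `"cauchy"`.
#' @param t_l minimum age (Ma), > 0.
#' @param t_u maximum age (Ma), required for `"uniform"`, ignored for
#'   `"cauchy"`.
#' @param tail_l probability mass below `t_l` (default 0: hard minimum).
#' @param tail_r probability mass above `t_u` (default 0.025: soft maximum).
#' @param p,c truncated-Cauchy location and scale parameters (dimensionless,
#'   > 0); defaults 0.1 and 1.
#' @return an object of class `calibration`.
#' @examples
#' root <- calibration("Testudines", "uniform", t_l = 155.6, t_u = 251.4)
#' dcal(200, root)              # 0.975 / 95.8
#' 1 - pcal(251.4, root)        # soft-maximum tail mass, 0.025
#' @export
calibration <- function(node, family = c("uniform", "cauchy"),
                        t_l, t_u = NA_real_, tail_l = 0, tail_r = 0.025,
                        p = 0.1, c = 1) {
  family <- match.arg(family)
  if (!is.finite(t_l) || t_l <= 0) stop("t_l must be a positive age (Ma)")
  if (family == "uniform") {
    if (!is.finite(t_u)) stop("a uniform calibration requires a maximum t_u")
    if (t_u <= t_l) stop("t_u must exceed t_l")
    if (tail_l < 0 || tail_l >= 0.5 || tail_r < 0 || tail_r >= 0.5) {
      stop("tail masses must lie in [0, 0.5)")
    }
  } else {
    if (!is.finite(p) || p <= 0 || !is.finite(c) || c <= 0) {
      stop("truncated Cauchy requires p > 0 and c > 0")
    }
    t_u <- NA_real_
    tail_l <- 0
  }
  structure(
    list(node = as.character(node), family = family,
         t_l = t_l, t_u = t_u, tail_l = tail_l, tail_r = tail_r,
         p = p, c = c),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  if (x$family == "uniform") {
    cat(sprintf("Calibration [%s]: uniform(%g, %g) Ma, tails (%g, %g)\n",
                x$node, x$t_l, x$t_u, x$tail_l, x$tail_r))
  } else {
    cat(sprintf(
      "Calibration [%s]: truncated Cauchy, min %g Ma, p = %g, c = %g\n",
      x$node, x$t_l, x$p, x$c))
  }
  invisible(x)
}

## shared tail geometry for the soft-bounded uniform
.unif_soft_pars <- function(cal) {
  core <- 1 - cal$tail_l - cal$tail_r
  h <- core / (cal$t_u - cal$t_l)
  list(h = h,
       lam_l = if (cal$tail_l > 0) h / cal$tail_l else Inf,
       lam_r = if (cal$tail_r > 0) h / cal$tail_r else Inf)
}

#' Calibration density, distribution, quantile and sampling functions
#'
#' `dcal`, `pcal`, `qcal` and `rcal` follow the usual d/p/q/r convention for
#' a [calibration] object. All forms are closed-form: the uniform family is
#' piecewise (exponential tails), the truncated Cauchy uses the arctangent.
#'
#' @param t ages in Ma.
#' @param q probabilities in `[0, 1]`.
#' @param n number of draws.
#' @param cal a [calibration].
#' @return `dcal`: densities per Ma; `pcal`: cumulative probabilities;
#'   `qcal`: ages in Ma; `rcal`: `n` i.i.d. ages drawn by inverse-cdf.
#' @export
dcal <- function(t, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (cal$family == "uniform") {
    pr <- .unif_soft_pars(cal)
    out <- numeric(length(t))
    below <- t < cal$t_l
    mid <- t >= cal$t_l & t <= cal$t_u
    above <- t > cal$t_u
    out[mid] <- pr$h
    out[above] <- pr$h * exp(-pr$lam_r * (t[above] - cal$t_u))
    if (cal$tail_l > 0) {
      out[below] <- pr$h * exp(-pr$lam_l * (cal$t_l - t[below]))
    }
    out
  } else {
    A <- cal$t_l * (1 + cal$p)
    s <- cal$c * cal$t_l
    mass <- 0.5 + atan(cal$p / cal$c) / pi
    ifelse(t < cal$t_l, 0, stats::dcauchy(t, A, s) / mass)
  }
}

#' @rdname dcal
#' @export
pcal <- function(t, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (cal$family == "uniform") {
    pr <- .unif_soft_pars(cal)
    out <- numeric(length(t))
    below <- t < cal$t_l
    mid <- t >= cal$t_l & t <= cal$t_u
    above <- t > cal$t_u
    out[mid] <- cal$tail_l + pr$h * (t[mid] - cal$t_l)
    out[above] <- 1 - cal$tail_r * exp(-pr$lam_r * (t[above] - cal$t_u))
    if (cal$tail_l > 0) {
      out[below] <- cal$tail_l * exp(-pr$lam_l * (cal$t_l - t[below]))
    }
    out
  } else {
    A <- cal$t_l * (1 + cal$p)
    s <- cal$c * cal$t_l
    f0 <- stats::pcauchy(cal$t_l, A, s)
    mass <- 1 - f0
    pmin(pmax((stats::pcauchy(t, A, s) - f0) / mass, 0), 1)
  }
}

#' @rdname dcal
#' @export
qcal <- function(q, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (any(q < 0 | q > 1)) stop("quantile probabilities must lie in [0, 1]")
  if (cal$family == "uniform") {
    pr <- .unif_soft_pars(cal)
    out <- numeric(length(q))
    lo <- q < cal$tail_l
    hi <- q > 1 - cal$tail_r
    mid <- !lo & !hi
    out[mid] <- cal$t_l + (q[mid] - cal$tail_l) / pr$h
    out[hi] <- cal$t_u - log((1 - q[hi]) / cal$tail_r) / pr$lam_r
    if (cal$tail_l > 0) {
      out[lo] <- cal$t_l + log(q[lo] / cal$tail_l) / pr$lam_l
    }
    out
  } else {
    A <- cal$t_l * (1 + cal$p)
    s <- cal$c * cal$t_l
    f0 <- stats::pcauchy(cal$t_l, A, s)
    stats::qcauchy(f0 + q * (1 - f0), A, s)
  }
}

#' @rdname dcal
#' @export
rcal <- function(n, cal) {
  stopifnot(n >= 1)
  qcal(stats::runif(n), cal)
}

## ------------------------------------------------------------ calibration sets

#' Bundle calibrations into a set
#'
#' @param ... [calibration] objects, or a single list of them.
#' @return an object of class `calibration_set` (a named list, names are
#'   node labels). At most one calibration per node is allowed.
#' @export
calibration_set <- function(...) {
  cals <- list(...)
  if (length(cals) == 1L && !inherits(cals[[1L]], "calibration")) {
    cals <- cals[[1L]]
  }
  ok <- vapply(cals, inherits, logical(1), "calibration")
  if (!all(ok)) stop("all elements must be calibration objects")
  nodes <- vapply(cals, `[[`, character(1), "node")
  if (anyDuplicated(nodes)) {
    stop("two calibrations attach to node(s): ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  structure(stats::setNames(cals, nodes), class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("Calibration set with", length(x), "calibrations:\n")
  for (cal in x) print(cal)
  invisible(x)
}

#' @export
`[.calibration_set` <- function(x, i) {
  calibration_set(unclass(x)[i])
}

#' Read and write calibration tables
#'
#' The on-disk format is a TSV with columns `node_label`, `family`, `t_L`,
#' `t_U`, `tail_L`, `tail_R`, `p`, `c` (missing values empty or NA).
#'
#' @param path file path.
#' @param cals a `calibration_set`.
#' @return `read_calibration_table`: a `calibration_set`.
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_label", "family", "t_L", "t_U", "tail_L", "tail_R", "p", "c")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cals <- lapply(seq_len(nrow(df)), function(i) {
    calibration(
      node = df$node_label[i], family = df$family[i],
      t_l = df$t_L[i], t_u = df$t_U[i],
      tail_l = ifelse(is.na(df$tail_L[i]), 0, df$tail_L[i]),
      tail_r = ifelse(is.na(df$tail_R[i]), 0.025, df$tail_R[i]),
      p = ifelse(is.na(df$p[i]), 0.1, df$p[i]),
      c = ifelse(is.na(df$c[i]), 1, df$c[i])
    )
  })
  calibration_set(cals)
}

#' @rdname read_calibration_table
#' @export
write_calibration_table <- function(cals, path) {
  df <- do.call(rbind, lapply(cals, function(cal) {
    data.frame(node_label = cal$node, family = cal$family,
               t_L = cal$t_l, t_U = cal$t_u, tail_L = cal$tail_l,
               tail_R = cal$tail_r, p = cal$p, c = cal$c)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## internal: encode a calibration set as the matrix consumed by the C++ core.
## Row i describes internal node i (1..M); fam 0 = uncalibrated.
cal_matrix <- function(tree, cals) {
  M <- n_internal(tree)
  m <- matrix(0, nrow = M, ncol = 7,
              dimnames = list(NULL, c("fam", "tL", "tU", "tailL", "tailR",
                                      "p", "c")))
  for (cal in cals) {
    i <- node_by_label(tree, cal$node) - n_tips(tree)
    if (m[i, "fam"] != 0) stop("two calibrations on node ", cal$node)
    m[i, ] <- c(if (cal$family == "uniform") 1 else 2,
                cal$t_l, ifelse(is.na(cal$t_u), 0, cal$t_u),
                cal$tail_l, cal$tail_r, cal$p, cal$c)
  }
  m
}

## internal: does the calibration impose a hard maximum? (uniform with
## tail_r = 0); used by the feasibility check
cal_hard_max <- function(cal) {
  if (cal$family == "uniform" && cal$tail_r == 0) cal$t_u else Inf
}

## internal: does the calibration bound the node above (even softly)?
cal_has_upper <- function(cal) {
  cal$family == "uniform" && is.finite(cal$t_u)
}
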
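# Spatial accuracy assessment: time-ROI power distributions, the
# 1-Wasserstein (earth mover's) distance between estimated and ground
# truth source power, percent-reduction summaries and paired tests.

#' Normalized source-power distribution over a time ROI
#'
#' Per-vertex mean squared amplitude over the ROI samples, normalized
#' to unit total mass.
#'
#' @param est a `source_estimate`, a `source_activity`, or an n x T
#'   matrix (then `fs` and `t0` must be given).
#' @param roi numeric length-2 window `c(t_min, t_max)` in seconds,
#'   inclusive; must lie within the segment.
#' @param coords n x 3 vertex coordinates (mm); taken from `head` of
#'   the producing model, so must be supplied explicitly.
#' @param fs,t0 sampling metadata for matrix input.
#' @return object of class `power_distribution`: `mass` (sums to 1),
#'   `coords`, `roi`.
#' @export
roi_power <- function(est, roi, coords, fs = NULL, t0 = NULL) {
  if (inherits(est, "source_estimate")) {
    x <- est$xhat; fs <- est$fs; t0 <- est$t0
  } else if (inherits(est, "source_activity")) {
    x <- est$x; fs <- est$fs; t0 <- est$t0
  } else {
    x <- as.matrix(est)
    if (is.null(fs)) stop("fs required for matrix input")
    if (is.null(t0)) t0 <- 0
  }
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(x)) stop("coords must have one row per vertex")
  stopifnot(length(roi) == 2L, roi[2L] > roi[1L])
  tt <- t0 + (seq_len(ncol(x)) - 1L) / fs
  sel <- which(tt >= roi[1L] & tt <= roi[2L])
  if (!length(sel)) stop("ROI contains no samples")
  pw <- rowMeans(x[, sel, drop = FALSE]^2)
  tot <- sum(pw)
  if (tot == 0) stop("no activity in the ROI: power distribution undefined")
  structure(list(mass = pw / tot, coords = coords, roi = roi),
            class = "power_distribution")
}

#' Exact transportation plan between two discrete measures
#'
#' Solves the balanced transportation linear program
#' `min sum_ij f_ij C_ij` subject to row sums `a` and column sums `b`
#' with the transportation-simplex method (north-west-corner start,
#' dual-based pivoting; degeneracy handled by a tiny mass
#' perturbation).
#'
#' @param a,b non-negative masses with equal totals.
#' @param cost m x n cost matrix.
#' @return list with `cost` (optimal objective) and `plan` (m x n flow
#'   matrix).
#' @export
transport_plan <- function(a, b, cost) {
  m <- length(a)
  n <- length(b)
  cost <- as.matrix(cost)
  stopifnot(nrow(cost) == m, ncol(cost) == n, all(a >= 0), all(b >= 0))
  if (abs(sum(a) - sum(b)) > 1e-9 * max(sum(a), sum(b)))
    stop("masses must balance")
  scale <- sum(a)
  if (scale == 0) return(list(cost = 0, plan = matrix(0, m, n)))
  eps <- 1e-10 * scale
  ap <- a + eps
  bp <- b
  bp[n] <- bp[n] + (sum(ap) - sum(b))
  nb <- m + n - 1L
  bi <- integer(nb); bj <- integer(nb); fl <- numeric(nb)
  # north-west corner start
  i <- 1L; j <- 1L; k <- 0L
  ar <- ap; br <- bp
  while (k < nb) {
    k <- k + 1L
    bi[k] <- i; bj[k] <- j
    f <- min(ar[i], br[j])
    fl[k] <- f
    ar[i] <- ar[i] - f
    br[j] <- br[j] - f
    if (i < m && (ar[i] <= br[j] || j == n)) i <- i + 1L else j <- j + 1L
  }
  ctol <- 1e-11 * max(abs(cost), 1)
  max_iter <- 100L * (m + n)
  for (iter in seq_len(max_iter)) {
    # duals from the basis tree (nodes: rows 1..m, cols m+1..m+n)
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1L] <- 0
    adj_from <- c(bi, bj + m)
    adj_to <- c(bj + m, bi)
    adj_edge <- c(seq_len(nb), seq_len(nb))
    ord <- order(adj_from)
    af <- adj_from[ord]; at <- adj_to[ord]; ae <- adj_edge[ord]
    starts <- c(match(seq_len(m + n), af), length(af) + 1L)
    queue <- 1L; head <- 1L
    seen <- logical(m + n); seen[1L] <- TRUE
    parent_edge <- integer(m + n); parent_node <- integer(m + n)
    while (head <= length(queue)) {
      node <- queue[head]; head <- head + 1L
      s <- starts[node]
      if (!is.na(s)) {
        e <- s
        while (e <= length(af) && af[e] == node) {
          nb2 <- at[e]
          if (!seen[nb2]) {
            seen[nb2] <- TRUE
            parent_edge[nb2] <- ae[e]
            parent_node[nb2] <- node
            queue <- c(queue, nb2)
          }
          e <- e + 1L
        }
      }
    }
    # resolve duals in BFS order
    for (node in queue[-1L]) {
      ed <- parent_edge[node]
      if (node <= m) u[node] <- cost[bi[ed], bj[ed]] - v[bj[ed]]
      else v[node - m] <- cost[bi[ed], bj[ed]] - u[bi[ed]]
    }
    red <- cost - outer(u, rep(1, n)) - outer(rep(1, m), v)
    ent <- arrayInd(which.min(red), dim(red))
    if (red[ent] >= -ctol) break
    ei <- ent[1L]; ej <- ent[2L]
    # cycle: tree path between row node ei and col node ej + m, spliced
    # at their lowest common ancestor
    chain_e <- integer(0)
    node <- ei
    while (node != 0L) {
      chain_e <- c(chain_e, node)
      node <- parent_node[node]
      if (node == 0L) break
      if (length(chain_e) > m + n) stop("internal error: basis tree cycle")
    }
    onpath <- logical(m + n)
    onpath[chain_e] <- TRUE
    edges1 <- integer(0)
    node <- ej + m
    while (!onpath[node]) {
      edges1 <- c(edges1, parent_edge[node])
      node <- parent_node[node]
      if (node == 0L) stop("internal error: disconnected basis tree")
    }
    lca <- node
    edges2 <- integer(0)
    node <- ei
    while (node != lca) {
      edges2 <- c(edges2, parent_edge[node])
      node <- parent_node[node]
    }
    # edge sequence from the ej side to the ei side; signs alternate
    # starting with - next to the entering edge
    path_edges <- c(edges1, rev(edges2))
    sgn <- -1
    theta <- Inf
    leave <- NA_integer_
    edge_sign <- numeric(nb)
    for (ed in path_edges) {
      edge_sign[ed] <- sgn
      if (sgn < 0 && fl[ed] < theta) {
        theta <- fl[ed]
        leave <- ed
      }
      sgn <- -sgn
    }
    fl <- fl + edge_sign * theta
    bi[leave] <- ei; bj[leave] <- ej; fl[leave] <- theta
  }
  plan <- matrix(0, m, n)
  plan[cbind(bi, bj)] <- fl
  list(cost = sum(fl * cost[cbind(bi, bj)]), plan = plan)
}

.sinkhorn_cost <- function(a, b, C, epsilon, max_iter = 5000L, tol = 1e-9) {
  # log-domain Sinkhorn iterations for the entropic-regularized plan
  f <- numeric(length(a))
  g <- numeric(length(b))
  la <- log(a)
  lb <- log(b)
  for (it in seq_len(max_iter)) {
    Mx <- (-C + outer(f, g, "+")) / epsilon
    f <- f + epsilon * (la - apply(Mx, 1L, function(r) {
      mx <- max(r); mx + log(sum(exp(r - mx)))
    }))
    Mx <- (-C + outer(f, g, "+")) / epsilon
    colls <- apply(Mx, 2L, function(r) {
      mx <- max(r); mx + log(sum(exp(r - mx)))
    })
    g <- g + epsilon * (lb - colls)
    if (max(abs(colls - lb)) < tol && it > 1L) break
  }
  P <- exp((-C + outer(f, g, "+")) / epsilon)
  sum(P * C)
}

#' 1-Wasserstein distance between source power distributions
#'
#' Earth mover's distance under the Euclidean ground metric between
#' vertex coordinates (units: mm).  Vertices with negligible mass
#' (<= 1e-12) are dropped from the support before solving; the exact
#' method solves the transportation LP, the `"sinkhorn"` method is an
#' entropic-regularized fast path (epsilon in mm) that upper-bounds the
#' exact value.
#'
#' @param p,q `power_distribution` objects in the same coordinate frame.
#' @param method `"exact"` (default) or `"sinkhorn"`.
#' @param epsilon entropic regularization scale in mm.
#' @return non-negative scalar distance in mm.
#' @export
wasserstein <- function(p, q, method = c("exact", "sinkhorn"), epsilon = 1) {
  stopifnot(inherits(p, "power_distribution"),
            inherits(q, "power_distribution"))
  method <- match.arg(method)
  for (z in list(p, q))
    if (abs(sum(z$mass) - 1) > 1e-6 || any(z$mass < 0))
      stop("power distributions must be normalized and non-negative")
  ip <- which(p$mass > 1e-12)
  iq <- which(q$mass > 1e-12)
  a <- p$mass[ip] / sum(p$mass[ip])
  b <- q$mass[iq] / sum(q$mass[iq])
  pc <- p$coords[ip, , drop = FALSE]
  qc <- q$coords[iq, , drop = FALSE]
  C <- sqrt(pmax(outer(rowSums(pc^2), rowSums(qc^2), "+") - 2 * pc %*% t(qc),
                 0))
  if (method == "exact") transport_plan(a, b, C)$cost
  else .sinkhorn_cost(a, b, C, epsilon)
}

#' Percent reduction of the Wasserstein error
#'
#' `100 * (wm_raw - wm_memd) / wm_raw`: how much of the raw
#' reconstruction error the preprocessed pipeline removes.
#'
#' @param wm_raw reference (raw pipeline) Wasserstein value, > 0.
#' @param wm_memd comparison (preprocessed pipeline) value.
#' @return percentage.
#' @export
percent_reduction <- function(wm_raw, wm_memd) {
  if (any(wm_raw <= 0)) stop("reference Wm must be positive")
  100 * (wm_raw - wm_memd) / wm_raw
}

#' Paired comparison of two matched error vectors
#'
#' Two-sided paired t-test with Bonferroni adjustment for a family of
#' comparisons: the significance threshold is alpha / n_comparisons.
#'
#' @param x,y matched numeric vectors (length >= 3).
#' @param n_comparisons family size for the Bonferroni adjustment.
#' @param alpha family-wise error level.
#' @return list of class `paired_comparison`: `t`, `df`, `p`,
#'   `p_bonferroni` (capped at 1), `significant`, `mean_difference`,
#'   `degenerate` (TRUE when the differences have zero variance).
#' @export
compare_conditions <- function(x, y, n_comparisons = 1L, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  d <- x - y
  if (stats::sd(d) == 0) {
    return(structure(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                          p_bonferroni = NA_real_, significant = FALSE,
                          mean_difference = mean(d), degenerate = TRUE),
                     class = "paired_comparison"))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  p <- ht$p.value
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter), p = p,
                 p_bonferroni = min(1, p * n_comparisons),
                 significant = p < alpha / n_comparisons,
                 mean_difference = mean(d), degenerate = FALSE),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("<paired_comparison> degenerate (zero-variance differences)\n")
  } else {
    cat(sprintf("<paired_comparison> t(%g) = %.3f, p = %.3g%s\n",
                x$df, x$t, x$p,
                if (x$significant) " *" else ""))
  }
  invisible(x)
}
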
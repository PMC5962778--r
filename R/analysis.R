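#' Detect cell assemblies in the recurrent weight matrix
#'
#' A cell assembly, in Hebb's sense, is a group of units strongly coupled by
#' mutual excitation. The detector builds an undirected graph with an edge
#' between hidden units i and j iff both `W[i, j] > threshold` and
#' `W[j, i] > threshold` (reciprocal excitation) and returns all maximal
#' cliques of size >= 2, each with its mean coupling weight. Assemblies may
#' overlap (maximal-clique semantics).
#'
#' @param W square recurrent weight matrix (`W[m, j]` = weight m -> j).
#' @param threshold minimum weight for an excitatory edge (default 0: any
#'   mutual positive coupling).
#' @return an `"hr_assemblies"` list: `assemblies` (list of integer unit-index
#'   vectors) and `mean_weight` (numeric, per assembly).
#' @export
detect_assemblies <- function(W, threshold = 0) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be square")
  adj <- (W > threshold) & (t(W) > threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g, min = 2)
  assemblies <- lapply(cliques, function(cl) sort(as.integer(cl)))
  mean_weight <- vapply(assemblies, function(a) {
    pr <- utils::combn(a, 2)
    mean((W[t(pr)] + W[t(pr[2:1, , drop = FALSE])]) / 2)
  }, numeric(1))
  structure(list(assemblies = assemblies, mean_weight = mean_weight),
            class = "hr_assemblies")
}

#' @export
print.hr_assemblies <- function(x, ...) {
  n <- length(x$assemblies)
  cat(sprintf("%d cell assembl%s (reciprocal-excitation maximal cliques)\n",
              n, if (n == 1) "y" else "ies"))
  for (i in seq_len(n))
    cat(sprintf("  {%s}  mean coupling %+.3f\n",
                paste(x$assemblies[[i]], collapse = ", "), x$mean_weight[i]))
  invisible(x)
}

#' Assembly turnover between two checkpoints
#'
#' For each assembly in the earlier set, the best-matching Jaccard
#' similarity with any assembly in the later set; the summary turnover score
#' is one minus the mean best similarity (0 = identical configuration,
#' 1 = completely replaced). The configuration of assemblies is expected to
#' change with each U-shaped developmental episode.
#'
#' @param a,b `"hr_assemblies"` objects (or plain lists of index vectors)
#'   at consecutive checkpoints.
#' @return list `similarity` (per assembly of `a`) and `turnover` (scalar).
#'   With both sets empty the configuration is unchanged (turnover 0); with
#'   exactly one empty it is fully replaced (turnover 1).
#' @export
assembly_turnover <- function(a, b) {
  sets_a <- if (inherits(a, "hr_assemblies")) a$assemblies else a
  sets_b <- if (inherits(b, "hr_assemblies")) b$assemblies else b
  if (length(sets_a) == 0 && length(sets_b) == 0)
    return(list(similarity = numeric(0), turnover = 0))
  if (length(sets_a) == 0 || length(sets_b) == 0)
    return(list(similarity = numeric(0), turnover = 1))
  jac <- function(u, v) length(intersect(u, v)) / length(union(u, v))
  sim <- vapply(sets_a, function(u)
    max(vapply(sets_b, function(v) jac(u, v), numeric(1))), numeric(1))
  list(similarity = sim, turnover = 1 - mean(sim))
}

#' Detect U-shaped episodes in a success-rate series
#'
#' After moving-average smoothing, finds local maximum -> local minimum ->
#' local maximum triples whose drop (lower flanking peak minus trough)
#' reaches `min_depth`. Events are returned sorted and non-overlapping in
#' step range. U-shaped development -- performance rising, dipping and
#' recovering, repeatedly -- is the developmental signature the trained
#' model exhibits.
#'
#' @param series data.frame with columns `step` and `rate` (>= 5 rows).
#' @param min_depth minimum peak-to-trough drop (default 0.05).
#' @param smooth odd moving-average window in points (default 3; 1 = none).
#' @return data.frame with one row per episode: `start`, `trough`, `end`
#'   (steps), `depth`, `recovery` (the recovery peak's rate).
#' @export
detect_u_shapes <- function(series, min_depth = 0.05, smooth = 3L) {
  if (nrow(series) < 5L) stop("series too short (need >= 5 points)")
  r <- series$rate
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    r <- stats::filter(r, k, sides = 2)
    half <- smooth %/% 2L
    r[seq_len(half)] <- r[half + 1L]
    r[(length(r) - half + 1L):length(r)] <- r[length(r) - half]
    r <- as.numeric(r)
  }
  n <- length(r)
  ## a point is a local max (min) over its immediate neighbours;
  ## endpoints count as peaks
  lmax <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) r[i - 1] else -Inf
    right <- if (i < n) r[i + 1] else -Inf
    r[i] >= left && r[i] >= right
  }, logical(1))
  lmin <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) r[i - 1] else Inf
    right <- if (i < n) r[i + 1] else Inf
    r[i] <= left && r[i] <= right
  }, logical(1))
  events <- list()
  last_end <- 0L
  for (i in which(lmin)) {
    peaks_before <- which(lmax[seq_len(max(i - 1L, 0L))])
    peaks_after <- which(lmax)
    peaks_after <- peaks_after[peaks_after > i]
    if (!length(peaks_before) || !length(peaks_after)) next
    pb <- max(peaks_before)
    pa <- min(peaks_after)
    depth <- min(r[pb], r[pa]) - r[i]
    if (depth < min_depth) next
    if (pb <= last_end) next
    events[[length(events) + 1L]] <- data.frame(
      start = series$step[pb], trough = series$step[i],
      end = series$step[pa], depth = depth, recovery = r[pa])
    last_end <- pa
  }
  if (!length(events))
    return(data.frame(start = numeric(0), trough = numeric(0),
                      end = numeric(0), depth = numeric(0),
                      recovery = numeric(0)))
  do.call(rbind, events)
}

#' Trajectory metrics over a movement window
#'
#' Describes the character of a hand's path over a window (default use: the
#' 100-step windows in which the trained model shows circular, zig-zag,
#' general-movement-like trajectories). Turning angles are measured between
#' consecutive nonzero displacement vectors; a reversal is a 180-degree
#' turn; the net-to-gross ratio is the straight-line displacement divided by
#' the path length (1 = straight, 0 = closed or fully back-and-forth).
#'
#' @param pos numeric matrix (n x 2) of positions over the window.
#' @return list `mean_turning_angle` (degrees), `reversals` (count),
#'   `net_gross_ratio`. An all-stationary window returns `(0, 0, 1)` by
#'   convention.
#' @export
trajectory_metrics <- function(pos) {
  if (!is.matrix(pos) || ncol(pos) != 2 || nrow(pos) < 2)
    stop("pos must be an n x 2 matrix with n >= 2")
  d <- diff(pos)
  lens <- sqrt(rowSums(d^2))
  gross <- sum(lens)
  if (gross == 0)
    return(list(mean_turning_angle = 0, reversals = 0L, net_gross_ratio = 1))
  net <- sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2))
  nz <- d[lens > 0, , drop = FALSE]
  nzl <- lens[lens > 0]
  angles <- numeric(0)
  if (nrow(nz) >= 2) {
    ca <- rowSums(nz[-nrow(nz), , drop = FALSE] * nz[-1, , drop = FALSE]) /
      (nzl[-length(nzl)] * nzl[-1])
    ca <- pmin(pmax(ca, -1), 1)
    angles <- acos(ca) * 180 / pi
  }
  list(mean_turning_angle = if (length(angles)) mean(angles) else 0,
       reversals = sum(angles > 179.999),
       net_gross_ratio = net / gross)
}

#' Per-unit activation fluctuation index
#'
#' Mean absolute step-to-step activation change per hidden unit over a
#' logged window; large values flag the strongly fluctuating units seen
#' while assemblies reorganise during U-shaped episodes.
#'
#' @param act numeric matrix (steps x units) of logged activations.
#' @return numeric vector, one index per unit.
#' @export
fluctuation_index <- function(act) {
  if (!is.matrix(act) || nrow(act) < 2) stop("need >= 2 logged steps")
  colMeans(abs(diff(act)))
}
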
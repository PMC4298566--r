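# Morphological thinning (Zhang & Suen 1984), spur pruning and path walking
# on binary matrices [y, x]. The skeleton is 8-connected and 1 px wide.

shift_mat <- function(M, dy, dx) {
  h <- nrow(M); w <- ncol(M)
  out <- matrix(FALSE, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- M[ys - dy, xs - dx]
  out
}

# One Zhang-Suen sub-iteration; `step` is 1 or 2. Returns pixels to delete.
zs_deletable <- function(S, step) {
  P2 <- shift_mat(S, 1, 0)   # value of northern neighbour at each pixel
  P3 <- shift_mat(S, 1, -1)
  P4 <- shift_mat(S, 0, -1)  # east
  P5 <- shift_mat(S, -1, -1)
  P6 <- shift_mat(S, -1, 0)  # south
  P7 <- shift_mat(S, -1, 1)
  P8 <- shift_mat(S, 0, 1)   # west
  P9 <- shift_mat(S, 1, 1)
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
       (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
  cond <- S & B >= 2 & B <= 6 & A == 1
  if (step == 1)
    cond & !(P2 & P4 & P6) & !(P4 & P6 & P8)
  else
    cond & !(P2 & P4 & P8) & !(P2 & P6 & P8)
}

#' Skeletonize a binary image
#'
#' Zhang-Suen thinning to a 1-px-wide, 8-connected medial curve.
#'
#' @param S logical matrix `[y, x]`.
#' @return logical matrix of the same dimensions.
#' @export
skeletonize <- function(S) {
  S <- S > 0
  repeat {
    d1 <- zs_deletable(S, 1)
    S[d1] <- FALSE
    d2 <- zs_deletable(S, 2)
    S[d2] <- FALSE
    if (!any(d1) && !any(d2)) break
  }
  S
}

# Number of 8-neighbours of each skeleton pixel.
neighbor_count <- function(S) {
  shift_mat(S, 1, 0) + shift_mat(S, -1, 0) + shift_mat(S, 0, 1) +
    shift_mat(S, 0, -1) + shift_mat(S, 1, 1) + shift_mat(S, 1, -1) +
    shift_mat(S, -1, 1) + shift_mat(S, -1, -1)
}

skeleton_endpoints <- function(S) {
  nb <- neighbor_count(S)
  which(S & nb == 1, arr.ind = TRUE)
}

# 8-neighbour coordinates of (y, x) that are TRUE in S.
true_neighbors <- function(S, y, x) {
  h <- nrow(S); w <- ncol(S)
  ys <- max(1, y - 1):min(h, y + 1)
  xs <- max(1, x - 1):min(w, x + 1)
  sub <- which(S[ys, xs, drop = FALSE], arr.ind = TRUE)
  out <- cbind(ys[sub[, 1]], xs[sub[, 2]])
  out[!(out[, 1] == y & out[, 2] == x), , drop = FALSE]
}

#' Prune short skeleton spurs
#'
#' Branches shorter than `prune_len` px (from an endpoint to the first
#' junction) are removed iteratively until stable.
#'
#' @param S logical skeleton matrix.
#' @param prune_len minimum branch length to keep (px).
#' @return pruned logical matrix.
#' @export
prune_spurs <- function(S, prune_len = 5) {
  # walk from an endpoint to the first junction; returns the leaf pixels
  # (junction excluded) or NULL when the walk runs past max_len or reaches
  # another endpoint (a junction-free path, never pruned)
  leaf_of <- function(S, y, x, max_len) {
    nb <- neighbor_count(S)
    path <- matrix(c(y, x), ncol = 2)
    prev <- c(NA, NA)
    while (nrow(path) <= max_len) {
      nbs <- true_neighbors(S, y, x)
      if (nrow(path) > 1)
        nbs <- nbs[!(nbs[, 1] == prev[1] & nbs[, 2] == prev[2]), ,
                   drop = FALSE]
      if (nrow(nbs) == 0) return(NULL)          # reached the far endpoint
      if (nrow(nbs) >= 2 || nb[nbs[1, 1], nbs[1, 2]] >= 3)
        return(path)                            # next pixel is a junction
      prev <- c(y, x)
      y <- nbs[1, 1]; x <- nbs[1, 2]
      path <- rbind(path, c(y, x))
    }
    NULL
  }
  # only leaves beyond the first two count as spurs: the two real ends of
  # the flagellum path are never pruned away
  repeat {
    nb <- neighbor_count(S)
    eps <- which(S & nb == 1, arr.ind = TRUE)
    if (nrow(eps) <= 2) break
    leaves <- lapply(seq_len(nrow(eps)), function(i)
      leaf_of(S, eps[i, 1], eps[i, 2], prune_len))
    lens <- vapply(leaves, function(l) if (is.null(l)) Inf else nrow(l),
                   numeric(1))
    if (all(is.infinite(lens))) break
    shortest <- which.min(lens)
    S[leaves[[shortest]]] <- FALSE
  }
  S
}

# Regrow the tip end of a traced path (y, x rows) while the binary
# foreground continues in the path's local direction (max 10 steps).
extend_tip <- function(path, B) {
  n <- nrow(path)
  if (n < 3) return(path)
  ref <- path[max(1, n - 3), ]
  d <- path[n, ] - ref
  len <- sqrt(sum(d^2))
  if (len == 0) return(path)
  step <- round(d / max(abs(d)))
  h <- nrow(B); w <- ncol(B)
  cur <- path[n, ]
  for (i in 1:10) {
    nxt <- cur + step
    if (nxt[1] < 1 || nxt[1] > h || nxt[2] < 1 || nxt[2] > w) break
    if (!B[nxt[1], nxt[2]]) break
    path <- rbind(path, nxt)
    cur <- nxt
  }
  path
}

# Centered moving average of path coordinates (window k, shrinking at the
# ends so the endpoints stay put).
smooth_path <- function(pts, k = 5) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  h <- (k - 1) %/% 2
  out <- pts
  for (i in seq_len(n)) {
    hh <- min(h, i - 1, n - i)
    idx <- (i - hh):(i + hh)
    out[i, ] <- colMeans(pts[idx, , drop = FALSE])
  }
  out
}

# Ordered path from `start` (y, x) to `goal` through the 8-connected
# skeleton graph: breadth-first shortest path, which traverses simple paths
# in order and cuts through 1-2 px junction knots without detouring into
# residual spur stubs.
walk_path <- function(S, start, goal) {
  h <- nrow(S); w <- ncol(S)
  prev <- matrix(NA_integer_, h, w)
  startl <- (start[2] - 1L) * h + start[1]
  goall <- (goal[2] - 1L) * h + goal[1]
  prev[startl] <- 0L
  queue <- startl
  while (length(queue) > 0 && is.na(prev[goall])) {
    nxt <- integer(0)
    for (q in queue) {
      y <- (q - 1L) %% h + 1L; x <- (q - 1L) %/% h + 1L
      nbs <- true_neighbors(S, y, x)
      for (j in seq_len(nrow(nbs))) {
        l <- (nbs[j, 2] - 1L) * h + nbs[j, 1]
        if (is.na(prev[l])) { prev[l] <- q; nxt <- c(nxt, l) }
      }
    }
    queue <- nxt
  }
  if (is.na(prev[goall]))
    stop("tracing error: skeleton endpoints are not connected")
  path <- integer(0)
  l <- goall
  while (l != 0L) { path <- c(l, path); l <- prev[l] }
  cbind((path - 1L) %% h + 1L, (path - 1L) %/% h + 1L)
}
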
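# Linear assignment by shortest augmenting paths (Jonker-Volgenant style,
# O(n^3)). Used for frame-to-frame linking and gap closing; forbidden
# assignments are encoded as a large finite cost by the callers.

#' Solve a square linear assignment problem
#' @param cost square numeric cost matrix (finite).
#' @return integer vector `a` with `a[i]` the column assigned to row `i`,
#'   minimizing total cost.
#' @keywords internal
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), all(is.finite(cost)))
  if (n == 0L) return(integer(0))
  # column index 1 is the virtual column; real columns are 2..n+1
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # row assigned to each column (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  a <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0L) a[p[j]] <- j - 1L
  a
}

#' Sparse one-to-one assignment with alternative (no-link) cost
#'
#' Solves min-cost one-to-one matching between `n1` left and `n2` right
#' nodes given feasible edges only; any node may stay unmatched at cost
#' `alt`. The feasibility graph is split into connected components and each
#' component is solved with the dense augmenting-path LAP, so sparse
#' problems (the common case in particle linking) stay fast.
#'
#' @param n1,n2 node counts.
#' @param edges data.frame with columns `i`, `j`, `cost`.
#' @param alt alternative cost for leaving a node unmatched.
#' @return integer vector of length `n1`: matched right index or `NA`.
#' @keywords internal
sparse_assign <- function(n1, n2, edges, alt) {
  match1 <- rep(NA_integer_, n1)
  if (is.null(edges) || nrow(edges) == 0L) return(match1)
  # drop edges that can never beat the alternative costs
  edges <- edges[edges$cost < 2 * alt, , drop = FALSE]
  if (nrow(edges) == 0L) return(match1)
  parent <- seq_len(n1 + n2)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$i[k]); rb <- find(n1 + edges$j[k])
    if (ra != rb) parent[rb] <- ra
  }
  comp_of_edge <- vapply(seq_len(nrow(edges)), function(k)
    find(edges$i[k]), 0L)
  for (cc in unique(comp_of_edge)) {
    sub <- edges[comp_of_edge == cc, , drop = FALSE]
    is_ <- sort(unique(sub$i)); js <- sort(unique(sub$j))
    m1 <- length(is_); m2 <- length(js)
    if (m1 == 1L && m2 == 1L) {
      if (sub$cost[which.min(sub$cost)] <= 2 * alt)
        match1[is_] <- js
      next
    }
    cost <- matrix(.LAP_BIG, m1 + m2, m1 + m2)
    cost[cbind(match(sub$i, is_), match(sub$j, js))] <- sub$cost
    cost[cbind(seq_len(m1), m2 + seq_len(m1))] <- alt
    cost[cbind(m1 + seq_len(m2), seq_len(m2))] <- alt
    cost[m1 + seq_len(m2), m2 + seq_len(m1)] <- 0
    a <- solve_lap(cost)
    for (k in seq_len(m1)) {
      j <- a[k]
      if (j <= m2 && cost[k, j] < .LAP_BIG) match1[is_[k]] <- js[j]
    }
  }
  match1
}
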
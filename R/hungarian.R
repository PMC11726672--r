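#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Jonker-Volgenant style shortest-augmenting-path solver with dual
#' potentials, O(n^3). Written in-package because no assignment solver
#' is among the package's dependencies; the problem sizes here (atoms
#' of one element within a ligand) are tiny.
#'
#' @param cost square numeric cost matrix.
#' @return integer vector \code{p} with \code{p[i]} the column assigned
#'   to row \code{i}; the minimised total cost is attached as
#'   \code{attr(, "cost")}.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  if (n == 0) return(integer(0))
  n1 <- n + 1L  # virtual column
  u <- numeric(n); v <- numeric(n1)
  p <- integer(n1)          # p[j]: row matched to column j (0 = free)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[n1] <- i
    j0 <- n1
    minv <- rep(Inf, n)
    used <- logical(n1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= n) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == n1) i else p[j1]
      j0 <- j1
      if (j0 == n1) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) ans[p[j]] <- j
  attr(ans, "cost") <- sum(cost[cbind(seq_len(n), ans)])
  ans
}
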
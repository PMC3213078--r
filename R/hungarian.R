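# Optimal one-to-one assignment (Hungarian algorithm, O(n^3) shortest
# augmenting path formulation with row/column potentials). Used by the
# tracker's gated matching; verified against a brute-force permutation
# oracle in the test suite.

# cost: n x m matrix (finite). Returns integer vector a of length n with
# a[i] = column assigned to row i (every row assigned; pad the matrix to
# taste for unbalanced problems).
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)        # p[j + 1]: row matched to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      free <- which(!used[-1])
      if (length(free)) {
        cur <- cost[i0, free] - u[i0] - v[free + 1]
        upd <- cur < minv[free]
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1] <- j0
        k <- which.min(minv[free])
        delta <- minv[free[k]]
        j1 <- free[k]
      }
      usedj <- which(used) - 1L
      u[p[usedj + 1]] <- u[p[usedj + 1]] + delta
      v[usedj + 1] <- v[usedj + 1] - delta
      minv[!used[-1]] <- minv[!used[-1]] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) a[p[j + 1]] <- j
  a
}

# Gated minimum-cost one-to-one matching between two point sets given their
# pairwise cost matrix. Pairs with cost > gate are never matched; each
# unmatched object carries a cost of gate / 2, so a pair is matched exactly
# when doing so is cheaper than leaving both ends free (cost < gate).
# Returns list(pairs = 2-column matrix of (i, j), unmatched1, unmatched2).
gated_match <- function(cost, gate) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  if (n1 == 0 || n2 == 0)
    return(list(pairs = matrix(integer(0), ncol = 2),
                unmatched1 = seq_len(n1), unmatched2 = seq_len(n2)))
  big <- max(gate * (n1 + n2 + 2), 1) * 1e3
  N <- n1 + n2
  M <- matrix(0, N, N)
  cm <- cost
  cm[cm > gate] <- big
  M[seq_len(n1), seq_len(n2)] <- cm
  M[seq_len(n1), n2 + seq_len(n1)] <- {
    blk <- matrix(big, n1, n1); diag(blk) <- gate / 2; blk
  }
  M[n1 + seq_len(n2), seq_len(n2)] <- {
    blk <- matrix(big, n2, n2); diag(blk) <- gate / 2; blk
  }
  a <- solve_assignment(M)
  pairs <- cbind(i = seq_len(n1), j = a[seq_len(n1)])
  keep <- pairs[, 2] <= n2
  keep[keep] <- cost[pairs[keep, , drop = FALSE]] <= gate
  list(pairs = pairs[keep, , drop = FALSE],
       unmatched1 = setdiff(seq_len(n1), pairs[keep, 1]),
       unmatched2 = setdiff(seq_len(n2), pairs[keep, 2]))
}
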
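# shared fixtures and independent oracles

two_reporters <- function() default_reporters()[c("bARG560", "bARG710")]

# dense nonnegative grid search oracle for min || c1 a1 + c2 a2 - b ||
nnls_grid_oracle <- function(A, b, step = 0.01, cmax = 3) {
  grid <- seq(0, cmax, by = step)
  G <- crossprod(A); h <- crossprod(A, b); b2 <- sum(b^2)
  # residual^2 = c' G c - 2 c' h + b' b evaluated on the full grid
  r2 <- outer(grid, grid, function(c1, c2)
    G[1, 1] * c1^2 + 2 * G[1, 2] * c1 * c2 + G[2, 2] * c2^2 -
      2 * (c1 * h[1] + c2 * h[2]) + b2)
  idx <- arrayInd(which.min(r2), dim(r2))
  list(x = c(grid[idx[1]], grid[idx[2]]), resid = sqrt(max(min(r2), 0)))
}

# exhaustive enumeration of all global alignments, scored with affine gaps
# (first gap residue gap_open, extensions gap_extend); independent of the
# dynamic-programming implementation
brute_force_alignment_score <- function(a, b, sub, gap_open = -10,
                                        gap_extend = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, acc, gap_state) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1, j + 1, acc + sub[A[i], B[j]], "")
    if (i <= length(A))
      rec(i + 1, j,
          acc + if (gap_state == "a") gap_extend else gap_open, "a")
    if (j <= length(B))
      rec(i, j + 1,
          acc + if (gap_state == "b") gap_extend else gap_open, "b")
  }
  rec(1, 1, 0, "")
  best
}

make_test_bmode <- function(Z = 40, X = 20, edge_row = 20, depth = 12,
                            level = 300) {
  m <- matrix(5, Z, X)
  m[edge_row, ] <- 3 * level
  rows <- seq(edge_row, min(edge_row + depth, Z))
  m[rows, ] <- pmax(m[rows, ], level)
  m
}
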
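# Independent oracles used by the tests. Everything here is deliberately
# naive (enumeration, double loops, closed forms) and never calls the code
# path it checks.

# Horn's quaternion characteristic-polynomial superposition: optimal RMSD
# from the largest eigenvalue of the 4x4 key matrix.
quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- t(A) %*% B
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)))
}

# exhaustive Viterbi: enumerate every state path, score it, keep the best
# (paths visited in lexicographic order of letter indices, so ties resolve
# toward lower indices exactly as the decoder specifies)
brute_viterbi <- function(obs, model) {
  n <- nrow(obs)
  L <- length(model$letters)
  logdens <- function(x, j) {
    S <- model$covariances[, , j]
    -0.5 * (4 * log(2 * pi) + determinant(S)$modulus[1] +
              t(x - model$means[j, ]) %*% solve(S) %*% (x - model$means[j, ]))
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(L)), n))[, n:1, drop = FALSE])
  # expand.grid varies the first factor fastest; reversed columns give
  # lexicographic order over (s1, ..., sn)
  grid <- grid[do.call(order, as.data.frame(grid)), , drop = FALSE]
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(grid))) {
    path <- grid[r, ]
    lp <- log(model$initial[path[1]]) + logdens(obs[1, ], path[1])
    if (n > 1) {
      for (t in 2:n) {
        lp <- lp + log(model$transitions[path[t - 1], path[t]]) +
          logdens(obs[t, ], path[t])
      }
    }
    if (lp > best) { best <- lp; best_path <- path }
  }
  model$letters[best_path]
}

# all set partitions of 1..n into exactly k non-empty blocks
# (restricted-growth-string enumeration; fine for n <= 10)
set_partitions_k <- function(n, k) {
  out <- list()
  recurse <- function(assign, next_block) {
    i <- length(assign) + 1L
    if (i > n) {
      if (next_block - 1L == k) out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (b in seq_len(min(next_block, k))) {
      recurse(c(assign, b), max(next_block, b + 1L))
    }
  }
  recurse(integer(), 1L)
  out
}

# best k-partition under the Ward objective on a dissimilarity matrix:
# sum over blocks of (sum of squared within-block dissimilarities) / size
best_ward_partition <- function(D, k) {
  n <- nrow(D)
  parts <- set_partitions_k(n, k)
  scores <- vapply(parts, function(p) {
    s <- 0
    for (b in unique(p)) {
      idx <- which(p == b)
      if (length(idx) > 1) {
        s <- s + sum(D[idx, idx]^2) / (2 * length(idx))
      }
    }
    s
  }, numeric(1))
  parts[[which.min(scores)]]
}

# fixed-width PDB record writer for hand-built parser fixtures
pdb_line <- function(type = "ATOM", eleno = 1, name = "CA", alt = "",
                     resid = "ALA", chain = "A", resno = 1, icode = "",
                     x = 0, y = 0, z = 0, occ = 1, b = 10, elem = "C") {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, eleno, name4, alt, resid, chain, resno, icode,
          x, y, z, occ, b, elem)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a straight-chain toy protein: n residues along z, one CA per residue
toy_chain_lines <- function(n = 5, chain = "A", resid = "ALA", b = NULL,
                            start_resno = 1, eleno_start = 1) {
  if (is.null(b)) b <- seq(10, by = 5, length.out = n)
  vapply(seq_len(n), function(i) {
    pdb_line(eleno = eleno_start + i - 1L, chain = chain, resid = resid,
             resno = start_resno + i - 1L, x = 0, y = 0, z = 3.8 * (i - 1),
             b = b[i])
  }, character(1))
}

# random letter-count distributions for entropy property tests
random_distribution <- function(max_letters = 8, max_count = 200) {
  k <- sample(1:max_letters, 1)
  counts <- sample(1:max_count, k, replace = TRUE)
  stats::setNames(counts, sample(c(letters, LETTERS), k))
}
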
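# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive results by brute force / closed form, separately
# from the package's implementation paths.

# ---- affine-gap alignment oracle (plain-R Gotoh recursion) -----------------
# Gap of length L costs open + L * ext (matching the package's convention).
# Returns the optimal score only.
oracle_align_score <- function(a, b, mat, open = 11, ext = 1,
                               type = c("global", "local")) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # last move: match/mismatch
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  if (type == "global") {
    for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      best_prev <- max(M[i, j], Ix[i, j], Iy[i, j])
      M[i + 1, j + 1] <- best_prev + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext)
      if (type == "local") {
        M[i + 1, j + 1] <- max(M[i + 1, j + 1], 0)
      }
    }
  }
  if (type == "global") {
    max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  } else {
    max(M)
  }
}

# ---- motif-scan oracle: exhaustive sliding window --------------------------
oracle_scan_motifs <- function(seq, max_dfgwg_mismatch = 1L) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  rows <- list()
  if (n >= 5) {
    for (s in 1:(n - 4)) {
      w <- chars[s:(s + 4)]
      if (w[1] == "H" && w[5] == "D") {
        rows[[length(rows) + 1]] <- data.frame(
          motif = "HXXXD", start = s,
          matched = paste(w, collapse = ""), mismatches = 0L)
      }
      mm <- sum(w != c("D", "F", "G", "W", "G") | w == "X")
      if (mm <= max_dfgwg_mismatch) {
        rows[[length(rows) + 1]] <- data.frame(
          motif = "DFGWG", start = s,
          matched = paste(w, collapse = ""), mismatches = mm)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(motif = character(), start = integer(),
                      matched = character(), mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif), ]
  rownames(out) <- NULL
  out
}

# ---- greedy redundancy-collapse replay -------------------------------------
oracle_greedy_collapse <- function(records, threshold, params) {
  reps <- integer()
  assign <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    joined <- FALSE
    for (r in reps) {
      idv <- global_align(records[r, ], records[i, ], params)$identity
      if (idv >= threshold) { assign[i] <- r; joined <- TRUE; break }
    }
    if (!joined) { reps <- c(reps, i); assign[i] <- i }
  }
  split(records$id, records$id[assign])
}

# ---- connected components by boolean transitive closure --------------------
oracle_components <- function(ids, edges_from, edges_to) {
  n <- length(ids)
  A <- diag(TRUE, n)
  rownames(A) <- colnames(A) <- ids
  if (length(edges_from)) {
    for (k in seq_along(edges_from)) {
      A[edges_from[k], edges_to[k]] <- TRUE
      A[edges_to[k], edges_from[k]] <- TRUE
    }
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  # canonical membership: index of first reachable id
  apply(A, 1, function(r) which(r)[1])
}

# ---- random additive distance matrix from a random unrooted tree -----------
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.1, 2))
  tr$tip.label <- sort(tr$tip.label)
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# Robinson-Foulds distance == 0 means identical unrooted topology
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# ---- rotation-parametrized numerical RMSD minimizer ------------------------
# Independent route to the optimal superposed RMSD: minimize over an
# Euler-angle parametrization of the rotation, multiple starts.
oracle_min_rmsd <- function(P, Q, n_starts = 8) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((Pc %*% rotmat(ang) - Qc)^2)))
  best <- Inf
  starts <- rbind(c(0, 0, 0),
                  matrix(stats::runif(3 * (n_starts - 1), -pi, pi),
                         ncol = 3))
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[k, ], obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 2000))
    best <- min(best, fit$value)
  }
  best
}

# ---- misc ------------------------------------------------------------------
random_protein <- function(n, alphabet = AA_ALPHABET_20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})
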
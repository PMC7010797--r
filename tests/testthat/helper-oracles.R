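# Independent score oracle for local alignment with affine gaps.
#
# A local alignment is fully determined by its chain of aligned residue
# pairs (i1,j1) < (i2,j2) < ... (strictly increasing in both coordinates):
# the columns between consecutive pairs are one gap run in each sequence
# whose unmatched residues cost open + (len-1) * extend. This oracle
# searches over ALL such chains (exhaustively, via tabulation of the best
# chain starting at each pair) and never touches the package's DP code.
sw_oracle_score <- function(q, h, S, gap_open = 10, gap_extend = 0.5) {
  qc <- strsplit(q, "")[[1]]
  hc <- strsplit(h, "")[[1]]
  n <- length(qc)
  m <- length(hc)
  s <- matrix(S[cbind(rep(qc, m), rep(hc, each = n))], n, m)
  gapc <- function(d) ifelse(d > 0, gap_open + (d - 1) * gap_extend, 0)
  best_from <- matrix(0, n, m)
  for (i in n:1) {
    for (j in m:1) {
      cont <- 0
      if (i < n && j < m) {
        sub <- best_from[(i + 1):n, (j + 1):m, drop = FALSE]
        gi <- gapc(seq(i + 1, n) - i - 1)
        gj <- gapc(seq(j + 1, m) - j - 1)
        cont <- max(0, sub - outer(gi, gj, "+"))
      }
      best_from[i, j] <- s[i, j] + cont
    }
  }
  max(0, best_from)
}

# Fully recursive, memo-free enumeration of every chain of aligned pairs;
# only usable for tiny sequences. Guards the tabulated oracle above.
sw_enum_score <- function(q, h, S, gap_open = 10, gap_extend = 0.5) {
  qc <- strsplit(q, "")[[1]]
  hc <- strsplit(h, "")[[1]]
  n <- length(qc)
  m <- length(hc)
  gapc <- function(d) if (d > 0) gap_open + (d - 1) * gap_extend else 0
  extend <- function(i, j) {
    sc <- S[qc[i], hc[j]]
    best <- sc
    if (i < n && j < m) {
      for (i2 in (i + 1):n) {
        for (j2 in (j + 1):m) {
          best <- max(best, sc - gapc(i2 - i - 1) - gapc(j2 - j - 1) +
                        extend(i2, j2))
        }
      }
    }
    best
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) best <- max(best, extend(i, j))
  }
  best
}

# Brute-force connected components from the pairwise minimum-distance
# matrix (label propagation until fixpoint), independent of igraph.
contact_components_oracle <- function(pts, cutoff) {
  n <- length(pts)
  lab <- seq_len(n)
  touch <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    sqrt(max(0, min(d2))) < cutoff
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && touch(pts[[i]], pts[[j]]) && lab[j] != lab[i]) {
          new <- min(lab[i], lab[j])
          lab[lab == lab[i] | lab == lab[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}
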
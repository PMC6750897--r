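# Independent oracles, deliberately written with no reference to the
# package internals they check.

# Full-matrix affine-gap global alignment score (textbook three-state DP,
# score only). Gap of length k costs go + k * ge.
oracle_affine_score <- function(a, b, smat, go, ge) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(go + ge * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(go + ge * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- smat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge, Y[i - 1, j] - go - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, X[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive maximum edge-disjoint pairing on a tree: enumerate every set
# of candidate pairs recursively and keep the largest edge-disjoint one.
oracle_max_disjoint_pairs <- function(tree, window, times = NULL) {
  labs <- tree$tip.label
  if (is.null(times)) times <- ape::cophenetic.phylo(tree) / 2
  times <- times[labs, labs]
  idx <- utils::combn(length(labs), 2)
  keep <- apply(idx, 2, function(ij) {
    tt <- times[ij[1], ij[2]]
    tt >= window[1] && tt <= window[2]
  })
  idx <- idx[, keep, drop = FALSE]
  if (ncol(idx) == 0) return(0L)
  edge_sets <- lapply(seq_len(ncol(idx)), function(k) {
    nodes <- ape::nodepath(tree, idx[1, k], idx[2, k])
    paste(pmin(nodes[-length(nodes)], nodes[-1]),
          pmax(nodes[-length(nodes)], nodes[-1]), sep = "-")
  })
  best <- 0L
  recurse <- function(k, used, count) {
    if (count + (ncol(idx) - k + 1) <= best) return()
    if (k > ncol(idx)) {
      best <<- max(best, count)
      return()
    }
    if (length(intersect(edge_sets[[k]], used)) == 0) {
      recurse(k + 1, c(used, edge_sets[[k]]), count + 1L)
    }
    recurse(k + 1, used, count)
  }
  recurse(1L, character(0), 0L)
  best
}

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments (no ties assumed).
oracle_mann_whitney_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_vals <- c(x, y)
  u_obs <- sum(outer(x, y, ">")) # U statistic for x
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(ix) {
    xx <- all_vals[ix]; yy <- all_vals[-ix]
    sum(outer(xx, yy, ">"))
  })
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# identity curve of the finite-alphabet back-substitution model (percent)
oracle_alphabet_identity <- function(a, lam, t) {
  100 * (1 / a + (1 - 1 / a) * exp(-2 * lam * a / (a - 1) * t))
}

# small aligned toy MSA as a named character vector
toy_msa <- function(...) {
  seqs <- c(...)
  stopifnot(length(unique(nchar(seqs))) == 1)
  seqs
}

# hand-rolled per-site conservation counting for toy MSAs
oracle_site_profile <- function(msa, pairs, reference_id) {
  chars <- strsplit(msa, "")
  ref <- chars[[reference_id]]
  cols <- which(ref != "-")
  sapply(cols, function(cl) {
    vals <- sapply(seq_len(nrow(pairs)), function(i) {
      x <- chars[[pairs$a[i]]][cl]
      y <- chars[[pairs$b[i]]][cl]
      if (x == "-" || y == "-") return(NA)
      x == y
    })
    mean(vals, na.rm = TRUE)
  })
}

# minimal MAGE count table built by hand
toy_mage_counts <- function() {
  tibble::tibble(
    mutant_id = c("m1", "m2", "m3", "WT"),
    position = c(1L, 1L, 2L, NA),
    codon = c("GCA", "GCC", "TGG", NA),
    aa = c("A", "A", "W", NA),
    wt_aa = c("V", "V", "C", NA),
    batch = c(1L, 1L, 1L, NA),
    `0` = c(1000, 800, 500, 10000),
    `2` = c(900, 850, 450, 10000),
    `4` = c(800, 820, 400, 10000),
    `6` = c(700, 830, 350, 10000),
    `8` = c(600, 810, 300, 10000)
  )
}
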
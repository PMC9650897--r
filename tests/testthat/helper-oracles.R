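# Independent oracles used to check the package's implementations.
# Each is deliberately naive (enumeration / exhaustive sliding / path sums)
# and shares no code with the functions it checks.

# Maximum end-overlap by exhaustively sliding one equal-length string over
# the other and checking that every aligned position matches.
oracle_max_overlap <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  L1 <- length(a)
  L2 <- length(b)
  best <- 0L
  for (d in seq(-(L2 - 1L), L1 - 1L)) {   # d = start of s2 relative to s1
    i <- max(1L, d + 1L):min(L1, d + L2)  # overlapping positions on s1
    j <- i - d
    if (all(a[i] == b[j])) best <- max(best, length(i))
  }
  best
}

random_seed7 <- function() {
  paste(sample(c("A", "C", "G", "U"), 7L, replace = TRUE), collapse = "")
}

# toy catalog from seeds, one family per seed
toy_catalog <- function(seeds, group = 2L, in_cluster = NULL, n_loci = NULL) {
  n <- length(seeds)
  tibble::tibble(
    mirna_id = sprintf("m%03d", seq_len(n)),
    family_id = sprintf("f%03d", seq_len(n)),
    seed = seeds,
    mature_seq = paste0("U", seeds, strrep("A", 14L)),
    conservation_group = group,
    in_cluster = in_cluster %||% rep(FALSE, n),
    n_loci = n_loci %||% rep(1L, n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# BLS oracle: union of edges on all pairwise tip-to-tip paths.
oracle_bls <- function(tree, tips) {
  tips <- unique(tips)
  if (length(tips) <= 1L) return(0)
  idx <- match(tips, tree$tip.label)
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  used <- character(0)
  for (i in seq_along(idx)) {
    for (j in seq_along(idx)) {
      if (i >= j) next
      path <- ape::nodepath(tree, idx[i], idx[j])
      for (k in seq_len(length(path) - 1L)) {
        used <- c(used,
                  paste(path[k], path[k + 1L]),
                  paste(path[k + 1L], path[k]))
      }
    }
  }
  sum(tree$edge.length[edge_key %in% used])
}

# Exact one-tailed (x shifted downward) rank-sum p by enumerating all
# assignments of the pooled values to the two groups. No ties assumed.
oracle_wilcox_less <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(pooled), length(x))
  stats <- apply(combos, 2L, function(ix) sum(r[ix]))
  mean(stats <= obs)
}

# Exact upper-tail hypergeometric p by direct binomial-coefficient sums:
# P(overlap >= k) drawing n from a universe of N with K marked.
oracle_hyper_upper <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# One-tailed (greater) Fisher p for table rbind(c(a, b), c(c, d)) via the
# hypergeometric tail with fixed margins.
oracle_fisher_greater <- function(a, b, c, d) {
  oracle_hyper_upper(a, a + b, a + b + c + d, a + c)
}
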
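#' Maximum overlap between two site-match sequences
#'
#' Finds the largest block length `k` such that the last `k` characters of one
#' sequence equal the first `k` of the other (both relative orders are tried;
#' `k` may equal the shorter length for full end-containment). Ties between
#' the two orders are broken by reporting the arrangement with `s1` leftmost.
#'
#' The `offset` is the start of `s2` relative to the start of `s1` in the
#' arrangement achieving `k` (positive: `s1` leftmost; negative: `s2`
#' leftmost; `NA` when `k = 0`). `merged` is the merged sequence spanned by
#' the arrangement.
#'
#' @param s1,s2 Non-empty sequences over a common alphabet.
#' @return A one-row tibble with columns `s1`, `s2`, `k`, `offset`, `merged`.
#' @examples
#' # the KLF4 cotarget geometry: miR-128-3p vs miR-148a-3p 7mer-m8 sites
#' max_overlap("CACUGUG", "UGCACUG")  # k = 5, merged UGCACUGUG
#' @export
max_overlap <- function(s1, s2) {
  if (length(s1) != 1L || length(s2) != 1L) {
    stop("max_overlap() takes single sequences; see pair_overlap_distribution() for batches",
         call. = FALSE)
  }
  if (is.na(s1) || is.na(s2) || nchar(s1) == 0L || nchar(s2) == 0L) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  L1 <- nchar(s1)
  L2 <- nchar(s2)
  k <- 0L
  offset <- NA_integer_
  for (n in seq.int(min(L1, L2), 1L)) {
    if (substr(s1, L1 - n + 1L, L1) == substr(s2, 1L, n)) {
      k <- n
      offset <- L1 - n  # s1 leftmost (preferred on ties)
      break
    }
    if (substr(s2, L2 - n + 1L, L2) == substr(s1, 1L, n)) {
      k <- n
      offset <- -(L2 - n)
      break
    }
  }
  merged <- if (k == 0L) {
    NA_character_
  } else if (offset >= 0L) {
    paste0(s1, substr(s2, k + 1L, L2))
  } else {
    paste0(s2, substr(s1, k + 1L, L1))
  }
  tibble::tibble(s1 = s1, s2 = s2, k = k, offset = offset, merged = merged)
}

# Vectorised maximum-overlap length over paired sequence vectors (equal
# lengths within each vector position are assumed, as holds within one site
# type). Hot path of the randomization test.
#' @keywords internal
#' @noRd
overlap_k_vec <- function(sa, sb) {
  L <- nchar(sa[1L])
  k <- integer(length(sa))
  todo <- rep(TRUE, length(sa))
  for (n in seq.int(L, 1L)) {
    hit <- todo &
      (substr(sa, L - n + 1L, L) == substr(sb, 1L, n) |
       substr(sb, L - n + 1L, L) == substr(sa, 1L, n))
    k[hit] <- n
    todo <- todo & !hit
    if (!any(todo)) break
  }
  k
}

# Extensive overlap indicator: maximum overlap k in {L-1, L-2}. Identical
# sequences (k = L) are same-family by definition and never extensive.
#' @keywords internal
#' @noRd
is_extensive_vec <- function(sa, sb) {
  L <- nchar(sa[1L])
  hit <- rep(FALSE, length(sa))
  for (n in c(L - 1L, L - 2L)) {
    hit <- hit |
      substr(sa, L - n + 1L, L) == substr(sb, 1L, n) |
      substr(sb, L - n + 1L, L) == substr(sa, 1L, n)
  }
  hit & sa != sb
}

#' Extensive-overlap thresholds per site type
#'
#' A pair of same-type site-match sequences overlaps "extensively" when the
#' maximum overlap is one or two short of the full site length: 7/6 nt for
#' 8mer sites, 6/5 nt for the 7mer types, 5/4 nt for 6mer sites.
#'
#' @param site_type Character vector of site types.
#' @return Integer vector of minimal extensive overlap lengths (`L - 2`).
#' @export
extensive_threshold <- function(site_type) {
  bad <- !site_type %in% SITE_TYPES
  if (any(bad)) stop(sprintf("unknown site type: %s", site_type[bad][1L]), call. = FALSE)
  unname(SITE_LENGTHS[site_type]) - 2L
}

#' Distribution of pairwise maximum overlap across a miRNA group
#'
#' Computes the maximum overlap of same-type site-match sequences for all
#' unordered pairs of distinct miRNA families in a conservation group and
#' tallies the relative occurrence of each overlap length `k = 0..L`.
#'
#' @param catalog miRNA catalog tibble (see [read_mirna_catalog()]).
#' @param site_type Canonical site type whose site-match sequences are compared.
#' @param group Optional conservation group name (`"broadly_conserved"`,
#'   `"conserved"`, `"poorly_conserved"`); `NULL` uses the whole catalog.
#' @return A tibble with columns `site_type`, `k`, `n_pairs`, `occurrence`
#'   (fractions summing to 1).
#' @export
pair_overlap_distribution <- function(catalog, site_type, group = NULL) {
  site_type <- match.arg(site_type, SITE_TYPES)
  fam <- family_seeds(catalog, group)
  if (nrow(fam) < 2L) {
    stop("need at least 2 distinct miRNA families", call. = FALSE)
  }
  s <- site_match_seq(fam$seed, site_type)
  idx <- utils::combn(length(s), 2L)
  k <- overlap_k_vec(s[idx[1L, ]], s[idx[2L, ]])
  L <- SITE_LENGTHS[[site_type]]
  counts <- tabulate(k + 1L, nbins = L + 1L)
  tibble::tibble(
    site_type = site_type,
    k = 0:L,
    n_pairs = counts,
    occurrence = counts / sum(counts)
  )
}

#' GC-matched random seed sequences
#'
#' Generates one random seed per input seed, preserving each seed's G+C
#' count exactly: the G/C positions are chosen uniformly among all position
#' subsets of that size, then each strong position is G or C and each weak
#' position A or U, independently with probability 1/2.
#'
#' @param seeds Character vector of RNA seed sequences (equal lengths).
#' @param rng_seed Optional integer seed for reproducibility.
#' @return Character vector of random seeds, same length and GC multiset.
#' @export
gc_matched_random_seeds <- function(seeds, rng_seed = NULL) {
  seeds <- toupper(seeds)
  assert_rna(seeds, "seeds")
  L <- unique(nchar(seeds))
  if (length(L) != 1L) stop("seeds must share one length", call. = FALSE)
  with_rng(rng_seed, random_seeds_gc(nchar(gsub("[^GC]", "", seeds)), L))
}

# uniform random seeds with prescribed per-seed GC counts; fully vectorised
#' @keywords internal
#' @noRd
random_seeds_gc <- function(gc, L) {
  n <- length(gc)
  combos <- gc_position_subsets(L)
  mask <- matrix(FALSE, n, L)
  for (g in unique(gc)) {
    rows <- which(gc == g)
    cmb <- combos[[g + 1L]]
    pick <- sample.int(nrow(cmb), length(rows), replace = TRUE)
    mask[rows, ] <- cmb[pick, , drop = FALSE]
  }
  u <- matrix(stats::runif(n * L) < 0.5, n, L)
  chars <- matrix("A", n, L)
  chars[mask & u] <- "G"
  chars[mask & !u] <- "C"
  chars[!mask & !u] <- "U"
  do.call(paste0, lapply(seq_len(L), function(j) chars[, j]))
}

# all position subsets of {1..L} by size, as logical matrices (memoised)
.subset_cache <- new.env(parent = emptyenv())
#' @keywords internal
#' @noRd
gc_position_subsets <- function(L) {
  key <- as.character(L)
  if (!is.null(.subset_cache[[key]])) return(.subset_cache[[key]])
  out <- lapply(0:L, function(g) {
    if (g == 0L) return(matrix(FALSE, 1L, L))
    cmb <- utils::combn(L, g)
    m <- matrix(FALSE, ncol(cmb), L)
    for (j in seq_len(ncol(cmb))) m[j, cmb[, j]] <- TRUE
    m
  })
  .subset_cache[[key]] <- out
  out
}

#' Randomization test for enrichment of extensive seed overlap
#'
#' Compares the observed frequency of extensively overlapping site-match
#' pairs among the miRNA families of a conservation group against `B`
#' randomizations in which every seed is replaced by a GC-matched random
#' seed. The empirical p-value uses the add-one estimator
#' `(1 + #[null >= observed]) / (B + 1)`, one-tailed for enrichment.
#'
#' @inheritParams pair_overlap_distribution
#' @param B Number of randomizations (default 1000).
#' @param rng_seed Optional integer seed.
#' @return An object of class `"overlap_test"`: a list with elements
#'   `group`, `site_type`, `n_families`, `n_pairs`, `observed_freq`,
#'   `null_freqs` (length `B`), `B`, `p_emp`, `neg_log10_p`.
#' @seealso [tidy.overlap_test()], [glance.overlap_test()],
#'   [autoplot.overlap_test()]
#' @export
randomization_test <- function(catalog, site_type, group = NULL, B = 1000L,
                               rng_seed = NULL) {
  site_type <- match.arg(site_type, SITE_TYPES)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be a positive integer", call. = FALSE)
  fam <- family_seeds(catalog, group)
  if (nrow(fam) < 2L) stop("need at least 2 distinct miRNA families", call. = FALSE)
  seeds <- fam$seed
  idx <- utils::combn(length(seeds), 2L)
  ia <- idx[1L, ]
  ib <- idx[2L, ]
  s <- site_match_seq(seeds, site_type)
  observed <- mean(is_extensive_vec(s[ia], s[ib]))
  gc <- nchar(gsub("[^GC]", "", seeds))
  L <- unique(nchar(seeds))
  null_freqs <- with_rng(rng_seed, {
    vapply(seq_len(B), function(b) {
      rs <- site_match_seq(random_seeds_gc(gc, L), site_type)
      mean(is_extensive_vec(rs[ia], rs[ib]))
    }, numeric(1))
  })
  p <- (1 + sum(null_freqs >= observed)) / (B + 1)
  structure(
    list(
      group = if (is.null(group)) "all" else group,
      site_type = site_type,
      n_families = length(seeds),
      n_pairs = length(ia),
      observed_freq = observed,
      null_freqs = null_freqs,
      B = B,
      p_emp = p,
      neg_log10_p = -log10(p)
    ),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Seed-overlap randomization test (%s, %s)\n  %d families, %d pairs\n  observed extensive-overlap frequency: %.4g\n  null mean: %.4g (B = %d)\n  empirical p = %.4g (-log10 p = %.3f)\n",
    x$group, x$site_type, x$n_families, x$n_pairs,
    x$observed_freq, mean(x$null_freqs), x$B, x$p_emp, x$neg_log10_p
  ))
  invisible(x)
}

#' Enumerate miRNA family pairs with extensive seed overlap
#'
#' Lists all unordered pairs of distinct miRNA families whose same-type
#' site-match sequences overlap extensively (maximum overlap `L-1` or `L-2`).
#' A pair is reported once per qualifying site type. Pair calling uses the
#' 8mer and the two 7mer site types; identical-seed pairs are excluded as
#' same-family.
#'
#' @inheritParams pair_overlap_distribution
#' @param site_types Site types considered for pair calling.
#' @return A tibble with columns `family_a`, `family_b`, `site_type`, `k`.
#' @export
extensive_pairs <- function(catalog, group = NULL,
                            site_types = c("8mer", "7mer-m8", "7mer-A1")) {
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  fam <- family_seeds(catalog, group)
  if (nrow(fam) < 2L) {
    return(tibble::tibble(
      family_a = character(0), family_b = character(0),
      site_type = character(0), k = integer(0)
    ))
  }
  idx <- utils::combn(nrow(fam), 2L)
  ia <- idx[1L, ]
  ib <- idx[2L, ]
  purrr::map_dfr(site_types, function(st) {
    s <- site_match_seq(fam$seed, st)
    ext <- is_extensive_vec(s[ia], s[ib])
    if (!any(ext)) return(NULL)
    tibble::tibble(
      family_a = fam$family_id[ia[ext]],
      family_b = fam$family_id[ib[ext]],
      site_type = st,
      k = overlap_k_vec(s[ia[ext]], s[ib[ext]])
    )
  })
}

#' Association of extensive-overlap miRNAs with clustering and multi-locus distribution
#'
#' Tests whether miRNAs that belong to at least one extensive-overlap family
#' pair are enriched for (a) membership in a genomic miRNA cluster and (b)
#' distribution across multiple genomic loci, by one-tailed (greater)
#' Fisher's exact tests on 2x2 tables.
#'
#' @param pairs Output of [extensive_pairs()].
#' @param catalog miRNA catalog tibble with `in_cluster` and `n_loci`.
#' @return A tibble with one row per annotation (`cluster`, `multi_locus`):
#'   counts of the 2x2 table, the sample odds ratio, and the Fisher p-value.
#' @export
mirna_gene_association <- function(pairs, catalog) {
  pos_fams <- unique(c(pairs$family_a, pairs$family_b))
  dat <- catalog |>
    dplyr::distinct(.data$mirna_id, .data$family_id, .data$in_cluster, .data$n_loci) |>
    dplyr::mutate(
      positive = .data$family_id %in% pos_fams,
      multi_locus = .data$n_loci >= 2L
    )
  one_test <- function(flag, label) {
    a <- sum(dat$positive & flag)
    b <- sum(dat$positive & !flag)
    c <- sum(!dat$positive & flag)
    d <- sum(!dat$positive & !flag)
    tab <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      warning(sprintf("empty margin for %s association; odds ratio undefined", label),
              call. = FALSE)
      or <- NA_real_
      p <- 1
    } else {
      or <- (a * d) / (b * c)
      p <- stats::fisher.test(tab, alternative = "greater")$p.value
    }
    tibble::tibble(
      annotation = label,
      n_pos_annot = a, n_pos_other = b,
      n_neg_annot = c, n_neg_other = d,
      odds_ratio = or, p_value = p
    )
  }
  dplyr::bind_rows(
    one_test(dat$in_cluster, "cluster"),
    one_test(dat$multi_locus, "multi_locus")
  )
}
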
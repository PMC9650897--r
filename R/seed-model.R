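#' Extract the seed sequence of a mature miRNA
#'
#' The seed is nucleotides 2-8 (1-based) of the mature miRNA sequence; its
#' reverse complement in a 3' UTR defines a canonical target site.
#'
#' @param mature_seq Character vector of mature miRNA sequences, 5'->3', RNA
#'   alphabet (A/C/G/U). Each must be at least 8 nt long.
#' @return Character vector of 7-nt seed sequences.
#' @examples
#' extract_seed("UCACAGUGAACCGGUCUCUUU")   # miR-128-3p seed: CACAGUG
#' extract_seed("UCAGUGCACUACAGAACUUUGU")  # miR-148a-3p seed: CAGUGCA
#' @export
extract_seed <- function(mature_seq) {
  if (length(mature_seq) == 0L) return(character(0))
  mature_seq <- toupper(mature_seq)
  assert_rna(mature_seq, "mature_seq")
  short <- nchar(mature_seq) < 8L
  if (any(short)) {
    stop(sprintf(
      "mature sequence must be >= 8 nt; got %d nt (%s)",
      nchar(mature_seq[short][1L]), mature_seq[short][1L]
    ), call. = FALSE)
  }
  substr(mature_seq, 2L, 8L)
}

#' Canonical site-match sequence for a seed
#'
#' Builds the target-site sequence (written 5'->3' on the mRNA) matched by a
#' miRNA seed for each canonical site type:
#' * `7mer-m8`: reverse complement of the full seed (miRNA positions 2-8);
#' * `8mer`: the 7mer-m8 sequence followed by an A (opposite miRNA position 1);
#' * `6mer`: reverse complement of miRNA positions 2-7 (first 6 seed bases);
#' * `7mer-A1`: the 6mer sequence followed by an A.
#'
#' @param seed Character vector of 7-nt RNA seed sequences.
#' @param site_type One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`.
#' @return A tibble with columns `seed`, `site_type`, `sequence`, `length`.
#' @examples
#' site_match("CACAGUG", "7mer-m8")  # CACUGUG
#' site_match("CACAGUG", "8mer")     # CACUGUGA
#' @export
site_match <- function(seed, site_type) {
  site_type <- match.arg(site_type, SITE_TYPES)
  seq <- site_match_seq(seed, site_type)
  tibble::tibble(
    seed = toupper(seed),
    site_type = site_type,
    sequence = seq,
    length = nchar(seq)
  )
}

# fast path returning plain character; used by the overlap statistics
#' @keywords internal
#' @noRd
site_match_seq <- function(seed, site_type) {
  seed <- toupper(seed)
  assert_rna(seed, "seed")
  if (any(nchar(seed) != 7L)) {
    stop("seed must be exactly 7 nt", call. = FALSE)
  }
  m8 <- rna_revcomp(seed)
  switch(site_type,
    "7mer-m8" = m8,
    "8mer"    = paste0(m8, "A"),
    "6mer"    = substr(m8, 2L, 7L),
    "7mer-A1" = paste0(substr(m8, 2L, 7L), "A"),
    stop(sprintf("unknown site type: %s", site_type), call. = FALSE)
  )
}

#' Read a miRNA catalog table
#'
#' Reads a tab-separated miRNA catalog with header columns `mirna_id`,
#' `mature_seq`, `family_id`, `conservation_group`, `mirbase_accession`,
#' `cluster_id`, `n_loci`. The layout mirrors the TargetScan miRNA family
#' information table but is its own documented dialect. DNA input (T) is
#' transliterated to RNA (U) with a notice. miRNAs lacking a miRBase
#' accession are excluded (isomiR filter) unless `accession_filter = FALSE`.
#'
#' @param path Path to the TSV file.
#' @param accession_filter Drop rows with a missing/empty `mirbase_accession`?
#' @return A tibble with one row per miRNA, plus derived columns `seed`
#'   (nucleotides 2-8) and `in_cluster` (non-empty `cluster_id`).
#' @export
read_mirna_catalog <- function(path, accession_filter = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cat0 <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("mirna_id", "mature_seq", "family_id", "conservation_group",
              "mirbase_accession", "cluster_id", "n_loci")
  missing <- setdiff(needed, names(cat0))
  if (length(missing) > 0L) {
    stop(sprintf("catalog is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  cat0$mature_seq <- as_rna(cat0$mature_seq)
  assert_rna(cat0$mature_seq, "mature_seq")
  if (any(nchar(cat0$mature_seq) < 8L)) {
    stop("catalog contains mature sequences shorter than 8 nt", call. = FALSE)
  }
  if (any(cat0$n_loci < 1L)) stop("n_loci must be >= 1", call. = FALSE)
  if (accession_filter) {
    drop <- is.na(cat0$mirbase_accession) | cat0$mirbase_accession == ""
    if (any(drop)) {
      message(sprintf("excluding %d miRNA(s) with no miRBase accession", sum(drop)))
      cat0 <- cat0[!drop, ]
    }
  }
  cat0 |>
    dplyr::mutate(
      conservation_group = as.integer(.data$conservation_group),
      seed = extract_seed(.data$mature_seq),
      in_cluster = !is.na(.data$cluster_id) & .data$cluster_id != "",
      n_loci = as.integer(.data$n_loci)
    ) |>
    tibble::as_tibble()
}

# Map a human-readable group name to TargetScan conservation_group codes.
#' @keywords internal
#' @noRd
group_codes <- function(group) {
  group <- match.arg(group, names(CONSERVATION_GROUPS))
  CONSERVATION_GROUPS[[group]]
}

# One seed per family within a conservation group. Families sharing an
# identical seed are collapsed (TargetScan families already do this).
#' @keywords internal
#' @noRd
family_seeds <- function(catalog, group = NULL) {
  if (!is.null(group)) {
    catalog <- dplyr::filter(catalog, .data$conservation_group == group_codes(group))
  }
  if (!"seed" %in% names(catalog)) {
    catalog$seed <- extract_seed(catalog$mature_seq)
  }
  fam <- catalog |>
    dplyr::distinct(.data$family_id, .data$seed)
  dup_fam <- fam$family_id[duplicated(fam$family_id)]
  if (length(dup_fam) > 0L) {
    stop(sprintf(
      "family with more than one seed: %s", paste(unique(dup_fam), collapse = ", ")
    ), call. = FALSE)
  }
  dup_seed <- duplicated(fam$seed)
  if (any(dup_seed)) {
    message(sprintf(
      "collapsing %d family(ies) with seeds identical to another family",
      sum(dup_seed)
    ))
    fam <- fam[!dup_seed, ]
  }
  fam
}
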
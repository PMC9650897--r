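# Coordinate-based classification of cotarget sites on 3' UTRs.
# Internal coordinates are 0-based half-open [start, end); the TargetScan
# dialect (1-based inclusive) is converted at I/O (see read_site_table()).

#' @keywords internal
#' @noRd
validate_sites <- function(sites) {
  needed <- c("site_id", "gene_id", "utr_id", "start", "end",
              "family_id", "site_type", "conserved")
  missing <- setdiff(needed, names(sites))
  if (length(missing) > 0L) {
    stop(sprintf("site table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(sites$start < 0L) || any(sites$end <= sites$start)) {
    stop("malformed intervals: need 0 <= start < end", call. = FALSE)
  }
  bad_len <- sites$end - sites$start != SITE_LENGTHS[sites$site_type]
  if (any(bad_len, na.rm = TRUE)) {
    stop("site interval length does not match its site type", call. = FALSE)
  }
  if (anyDuplicated(sites$site_id)) stop("duplicated site_id", call. = FALSE)
  invisible(sites)
}

# unordered same-UTR site pairs with pair metadata
#' @keywords internal
#' @noRd
utr_site_pairs <- function(sites) {
  s <- sites |>
    dplyr::select("site_id", "utr_id", "start", "end", "family_id")
  dplyr::inner_join(s, s, by = "utr_id", suffix = c("_a", "_b"),
                    relationship = "many-to-many") |>
    dplyr::filter(.data$site_id_a < .data$site_id_b) |>
    dplyr::mutate(
      overlap_nt = pmin(.data$end_a, .data$end_b) - pmax(.data$start_a, .data$start_b),
      seed_dist = abs(.data$start_a - .data$start_b),
      same_family = .data$family_id_a == .data$family_id_b
    )
}

# fold pair rows into one annotation row per site
#' @keywords internal
#' @noRd
pairs_to_annotation <- function(sites, pr, colname) {
  long <- dplyr::bind_rows(
    dplyr::transmute(pr, site_id = .data$site_id_a, partner = .data$site_id_b,
                     same_family = .data$same_family),
    dplyr::transmute(pr, site_id = .data$site_id_b, partner = .data$site_id_a,
                     same_family = .data$same_family)
  )
  ann <- long |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      status = ifelse(any(!.data$same_family), "distinct_mirna", "same_mirna"),
      partners = list(sort(.data$partner)),
      .groups = "drop"
    )
  out <- tibble::tibble(site_id = sites$site_id) |>
    dplyr::left_join(ann, by = "site_id") |>
    dplyr::mutate(
      status = factor(
        dplyr::coalesce(.data$status, "none"),
        levels = c("none", "same_mirna", "distinct_mirna")
      ),
      partners = purrr::map(.data$partners, function(p) if (is.null(p)) character(0) else p)
    )
  names(out)[names(out) == "status"] <- colname
  names(out)[names(out) == "partners"] <- paste0(colname, "_partners")
  out
}

#' Seed-overlap cotarget sites ("conserved overlap")
#'
#' Two sites on the same UTR whose `[start, end)` intervals intersect in at
#' least one nucleotide are mutual seed-overlap partners. With
#' `conserved_only = TRUE` (the "conserved overlap" definition) only
#' conserved sites are considered; mixed site types are allowed. A site
#' whose partners include a different miRNA family is annotated
#' `distinct_mirna`, otherwise `same_mirna`.
#'
#' @param sites Site table (see [read_site_table()] for columns).
#' @param conserved_only Restrict to conserved sites ("conserved overlap",
#'   the default) or annotate overlap among all sites.
#' @return A tibble with one row per input site: `site_id`, `seed_overlap`
#'   (factor none/same_mirna/distinct_mirna), `seed_overlap_partners`
#'   (list-column of partner site ids).
#' @export
find_conserved_overlap <- function(sites, conserved_only = TRUE) {
  validate_sites(sites)
  s <- if (conserved_only) dplyr::filter(sites, .data$conserved) else sites
  pr <- utr_site_pairs(s) |>
    dplyr::filter(.data$overlap_nt >= 1L)
  pairs_to_annotation(sites, pr, "seed_overlap")
}

#' Neighborhood cotarget sites
#'
#' Two sites on the same UTR whose seed starts lie `d_min`-`d_max`
#' nucleotides apart (inclusive) are neighborhood partners — the spacing at
#' which closely spaced sites act cooperatively. Pairs whose intervals
#' overlap are never neighborhood pairs. The seed start is the site start in
#' this representation (for 8mer sites the A1 lies at the 3' end of the
#' match written 5'->3' on the mRNA, so the 7-nt seed-match core begins at
#' the site start).
#'
#' @inheritParams find_conserved_overlap
#' @param d_min,d_max Inclusive bounds on the seed-start distance (defaults
#'   15 and 100 nt).
#' @return A tibble with one row per input site: `site_id`, `neighborhood`
#'   (factor none/same_mirna/distinct_mirna), `neighborhood_partners`.
#' @export
find_neighborhood <- function(sites, d_min = 15L, d_max = 100L,
                              conserved_only = FALSE) {
  if (d_min > d_max) stop("d_min must be <= d_max", call. = FALSE)
  validate_sites(sites)
  s <- if (conserved_only) dplyr::filter(sites, .data$conserved) else sites
  pr <- utr_site_pairs(s) |>
    dplyr::filter(
      .data$overlap_nt < 1L,
      .data$seed_dist >= d_min,
      .data$seed_dist <= d_max
    )
  pairs_to_annotation(sites, pr, "neighborhood")
}

#' Combined cotarget annotation
#'
#' Joins [find_conserved_overlap()] and [find_neighborhood()] into one
#' annotation table. A site may carry both annotations (via different
#' partners), but no single pair of sites is both seed-overlap and
#' neighborhood.
#'
#' @inheritParams find_neighborhood
#' @return A tibble with `site_id`, `seed_overlap`, `seed_overlap_partners`,
#'   `neighborhood`, `neighborhood_partners`.
#' @export
annotate_cotargets <- function(sites, d_min = 15L, d_max = 100L,
                               conserved_only = TRUE) {
  dplyr::left_join(
    find_conserved_overlap(sites, conserved_only = conserved_only),
    find_neighborhood(sites, d_min = d_min, d_max = d_max,
                      conserved_only = conserved_only),
    by = "site_id"
  )
}

#' Gene-level target groups per miRNA family
#'
#' Assigns every gene of a universe to a target group for each miRNA family
#' of interest, by the strongest site the gene carries for that family:
#' `conserved_overlap` (a conserved site with a distinct-miRNA seed-overlap
#' partner) > `8mer` > `7mer` > `6mer` (conserved sites) >
#' `nonconserved_only` > `background` (no sites). The strict single-site
#' subset flags genes with exactly one conserved site and no non-conserved
#' sites for that family.
#'
#' @param sites Site table.
#' @param overlap Output of [find_conserved_overlap()] for the same sites.
#' @param families Families to group; default: all families in `sites`.
#' @param genes Gene universe; default: all genes in `sites`. Genes with no
#'   sites for a family form its `background` group.
#' @return A tibble with columns `gene_id`, `family_id`, `group` (factor),
#'   `n_conserved`, `n_nonconserved`, `single_conserved_site` (logical).
#' @export
gene_groups <- function(sites, overlap, families = NULL, genes = NULL) {
  validate_sites(sites)
  if (is.null(families)) families <- unique(sites$family_id)
  if (is.null(genes)) genes <- unique(sites$gene_id)
  ann <- dplyr::left_join(sites, overlap, by = "site_id")
  levels <- c("conserved_overlap", "8mer", "7mer", "6mer",
              "nonconserved_only", "background")
  purrr::map_dfr(families, function(f) {
    sf <- dplyr::filter(ann, .data$family_id == f)
    per_gene <- sf |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        n_conserved = sum(.data$conserved),
        n_nonconserved = sum(!.data$conserved),
        has_overlap = any(.data$conserved & .data$seed_overlap == "distinct_mirna"),
        has_8 = any(.data$conserved & .data$site_type == "8mer"),
        has_7 = any(.data$conserved & .data$site_type %in% c("7mer-m8", "7mer-A1")),
        has_6 = any(.data$conserved & .data$site_type == "6mer"),
        .groups = "drop"
      )
    tibble::tibble(gene_id = genes) |>
      dplyr::left_join(per_gene, by = "gene_id") |>
      dplyr::mutate(
        family_id = f,
        n_conserved = dplyr::coalesce(.data$n_conserved, 0L),
        n_nonconserved = dplyr::coalesce(.data$n_nonconserved, 0L),
        group = factor(dplyr::case_when(
          .data$n_conserved + .data$n_nonconserved == 0L ~ "background",
          dplyr::coalesce(.data$has_overlap, FALSE) ~ "conserved_overlap",
          dplyr::coalesce(.data$has_8, FALSE) ~ "8mer",
          dplyr::coalesce(.data$has_7, FALSE) ~ "7mer",
          dplyr::coalesce(.data$has_6, FALSE) ~ "6mer",
          TRUE ~ "nonconserved_only"
        ), levels = levels),
        single_conserved_site = .data$n_conserved == 1L & .data$n_nonconserved == 0L
      ) |>
      dplyr::select("gene_id", "family_id", "group",
                    "n_conserved", "n_nonconserved", "single_conserved_site")
  })
}
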
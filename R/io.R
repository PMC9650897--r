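# Readers and writers for the tabular dialects, GMT gene sets, Newick
# trees, and BED export. Internal coordinates are 0-based half-open; the
# TargetScan dialect (1-based inclusive) is converted here.

#' Read a target-site table
#'
#' Expected header: `gene_id`, `utr_id`, `start`, `end`, `family_id`,
#' `site_type`, `conserved`, and optionally `bls`, `n_species`, `site_id`.
#' Two coordinate dialects are supported: `"native"` (0-based half-open)
#' and `"targetscan"` (1-based inclusive, converted on read). Rows with
#' invalid intervals are rejected with their line numbers.
#'
#' @param path Path to the TSV file.
#' @param dialect Coordinate dialect of the file.
#' @return A site table tibble in native coordinates.
#' @export
read_site_table <- function(path, dialect = c("native", "targetscan")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("gene_id", "utr_id", "start", "end", "family_id", "site_type",
              "conserved")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0L) {
    stop(sprintf("site table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(x) == 0L) {
    warning("empty site table", call. = FALSE)
    return(tibble::as_tibble(x))
  }
  if (dialect == "targetscan") {
    x$start <- x$start - 1L  # 1-based inclusive -> 0-based half-open
  }
  bad <- which(x$start >= x$end | x$start < 0L)
  if (length(bad) > 0L) {
    stop(sprintf("invalid interval(s) on data line(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (!"site_id" %in% names(x)) {
    x$site_id <- sprintf("site%06d", seq_len(nrow(x)))
  }
  x$conserved <- as.logical(x$conserved)
  message(sprintf("read %d site(s) from %s", nrow(x), path))
  tibble::as_tibble(x)
}

#' Write a site table
#'
#' @param sites Site table tibble (native 0-based half-open coordinates).
#' @param path Output TSV path.
#' @param dialect Coordinate dialect to write.
#' @export
write_site_table <- function(sites, path, dialect = c("native", "targetscan")) {
  dialect <- match.arg(dialect)
  out <- sites
  if (dialect == "targetscan") out$start <- out$start + 1L
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-level expression response table
#'
#' Wide dialect: `gene_id`, then `log2fc_<condition>` / `fdr_<condition>`
#' column pairs plus `mean_cpm`; pivoted to the long form used throughout
#' the package. Genes with `mean_cpm` below `cpm_min` are filtered out
#' (lowly expressed genes), with a notice.
#'
#' @param path Path to the TSV file.
#' @param cpm_min Minimum mean CPM retained (set to 0 to keep everything).
#' @return A long tibble: `gene_id`, `condition`, `log2fc`, `fdr`, `mean_cpm`.
#' @export
read_expression_table <- function(path, cpm_min = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(x)) stop("expression table needs gene_id", call. = FALSE)
  if ("mean_cpm" %in% names(x) && cpm_min > 0) {
    low <- x$mean_cpm < cpm_min
    if (any(low)) {
      message(sprintf("filtering %d gene(s) with mean CPM < %g", sum(low), cpm_min))
      x <- x[!low, ]
    }
  }
  long <- x |>
    tidyr::pivot_longer(
      cols = tidyr::matches("^(log2fc|fdr)_"),
      names_to = c(".value", "condition"),
      names_pattern = "^(log2fc|fdr)_(.+)$"
    )
  message(sprintf("read expression for %d gene(s), %d condition(s)",
                  dplyr::n_distinct(long$gene_id),
                  dplyr::n_distinct(long$condition)))
  long
}

#' Write an expression response table (wide dialect)
#'
#' @param expr Long expression tibble.
#' @param path Output TSV path.
#' @export
write_expression_table <- function(expr, path) {
  wide <- expr |>
    tidyr::pivot_wider(
      id_cols = c("gene_id", dplyr::any_of("mean_cpm")),
      names_from = "condition",
      values_from = c("log2fc", "fdr"),
      names_glue = "{.value}_{condition}"
    )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a haploinsufficiency-probability table
#'
#' @param path TSV with columns `gene_id`, `p_hi`.
#' @return A tibble with `gene_id`, `p_hi` in `[0, 1]`.
#' @export
read_hi_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "p_hi") %in% names(x))) {
    stop("haploinsufficiency table needs gene_id and p_hi", call. = FALSE)
  }
  if (any(x$p_hi < 0 | x$p_hi > 1, na.rm = TRUE)) {
    stop("p_hi must lie in [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Duplicate genes within a set are deduplicated; blank
#' lines are skipped; empty sets are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      warning(sprintf("dropping empty gene set '%s'", f[[1]]), call. = FALSE)
      next
    }
    sets[[f[[1]]]] <- genes
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- purrr::imap_chr(gene_sets, function(genes, name) {
    paste(c(name, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a species-presence table
#'
#' @param path TSV with a `site_id` column followed by one 0/1 column per
#'   panel species (reference species first).
#' @param species Optional panel check: the expected species, in order.
#' @return A tibble.
#' @export
read_species_presence <- function(path, species = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"site_id" %in% names(x)) stop("presence table needs site_id", call. = FALSE)
  if (!is.null(species) && !identical(setdiff(names(x), "site_id"), species)) {
    stop("presence table columns do not match the species panel", call. = FALSE)
  }
  presence_matrix(x)  # validation only
  tibble::as_tibble(x)
}

#' Export sites (and merged cotarget regions) as BED
#'
#' BED is 0-based half-open, matching the internal coordinates, so the
#' export is direct. With `merge_overlaps = TRUE`, overlapping site
#' intervals on a UTR are merged into single regions.
#'
#' @param sites Site table.
#' @param path Output BED path.
#' @param merge_overlaps Write merged overlap regions instead of raw sites.
#' @export
write_sites_bed <- function(sites, path, merge_overlaps = FALSE) {
  if (merge_overlaps) {
    merged <- sites |>
      dplyr::arrange(.data$utr_id, .data$start) |>
      dplyr::group_by(.data$utr_id) |>
      dplyr::mutate(
        gap = .data$start > dplyr::lag(cummax(.data$end), default = -1L),
        block = cumsum(.data$gap)
      ) |>
      dplyr::group_by(.data$utr_id, .data$block) |>
      dplyr::summarise(
        start = min(.data$start), end = max(.data$end),
        name = paste(.data$site_id, collapse = ","), .groups = "drop"
      )
    bed <- merged[, c("utr_id", "start", "end", "name")]
  } else {
    bed <- sites[, c("utr_id", "start", "end", "site_id")]
  }
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
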
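# End-to-end orchestration over synthetic inputs: simulate -> seed overlap
# statistics -> conservation classification -> cotarget geometry ->
# response statistics -> haploinsufficiency -> gene-set enrichment.

#' Run the full cotargeting pipeline on synthetic data
#'
#' Chains every stage of the package on one simulated data set: generates
#' the miRNA catalog, site table, species tree/presence, expression
#' responses, haploinsufficiency probabilities and gene sets from `cfg`;
#' then recovers the planted structure with the analysis stages — extensive
#' seed-overlap pairs and their randomization test, cluster/multi-locus
#' association, conservation classification and the shallow/deep split,
#' cotarget-site annotation, gene grouping for the first planted pair,
#' downregulation and additivity statistics, haploinsufficiency
#' comparisons, and gene-set enrichment of the overlap-target genes.
#'
#' @param cfg A [sim_config()].
#' @param B Randomizations for the seed-overlap test.
#' @param rng_seed Master seed; defaults to `cfg$rng_seed`. Stage seeds are
#'   derived from it, so one seed fixes every output.
#' @param out_dir Optional directory: when given, all simulated inputs and
#'   result tables are written there (TSV/Newick/GMT/JSON) together with a
#'   run manifest.
#' @return A named list of stage results (see Details in the vignette).
#' @export
run_cotarget_pipeline <- function(cfg = sim_config(), B = 1000L,
                                  rng_seed = cfg$rng_seed, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  catalog <- simulate_mirna_catalog(cfg, rng_seed = stage_seed(rng_seed, 1L))
  planted <- attr(catalog, "planted_pairs")
  sim <- simulate_sites_and_conservation(cfg, catalog,
                                         rng_seed = stage_seed(rng_seed, 2L))
  sites <- sim$sites

  # seed-overlap statistics over the miRNA catalog
  pairs <- extensive_pairs(catalog, group = "broadly_conserved")
  overlap_test <- randomization_test(catalog, site_type = "7mer-m8",
                                     group = "broadly_conserved", B = B,
                                     rng_seed = stage_seed(rng_seed, 3L))
  association <- mirna_gene_association(pairs, catalog)

  # conservation classification and the two-class split
  calls <- classify_sites(sites)
  class_split <- two_class_summary(calls)

  # cotarget geometry
  cot <- annotate_cotargets(sites)
  overlap_ann <- cot[, c("site_id", "seed_overlap", "seed_overlap_partners")]
  conserved_ids <- sites$site_id[sites$conserved]
  cotarget_fractions <- tibble::tibble(
    class = c("seed_overlap", "neighborhood"),
    n_sites = c(
      sum(cot$seed_overlap != "none" & cot$site_id %in% conserved_ids),
      sum(cot$neighborhood != "none" & cot$site_id %in% conserved_ids)
    ),
    fraction_of_conserved = n_sites / length(conserved_ids)
  )

  # gene grouping and expression response for the first planted pair
  fam_a <- planted$family_a[1L]
  fam_b <- planted$family_b[1L]
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  groups <- gene_groups(sites, overlap_ann, families = c(fam_a, fam_b),
                        genes = genes)
  groups_a <- dplyr::filter(groups, .data$family_id == fam_a)
  expr <- simulate_expression(cfg, sites, fam_a, fam_b, genes = genes,
                              rng_seed = stage_seed(rng_seed, 4L))
  downreg <- downregulation_summary(expr, groups_a, condition = "both")
  wide <- tidyr::pivot_wider(expr, id_cols = "gene_id",
                             names_from = "condition", values_from = "log2fc")
  additivity <- additivity_test(wide[[fam_a]], wide[[fam_b]], wide[["both"]])

  # haploinsufficiency: the deep-class target genes carry the planted shift
  deep_genes <- unique(sites$gene_id[sites$site_id %in%
                                       calls$site_id[calls$depth_class == "deep"]])
  hi <- simulate_hi(cfg, genes, shifted_genes = deep_genes,
                    rng_seed = stage_seed(rng_seed, 5L))
  depth_groups <- tibble::tibble(
    gene_id = genes,
    group = ifelse(genes %in% deep_genes, "deep_target", "other")
  )
  hi_test <- hi_comparison(depth_groups, hi, focal = "deep_target")

  # gene-set enrichment of conserved-overlap target genes
  overlap_genes <- unique(sites$gene_id[sites$planted_overlap])
  gene_sets <- simulate_gene_sets(genes, overlap_genes,
                                  rng_seed = stage_seed(rng_seed, 6L))
  enrichment <- gene_set_enrichment(overlap_genes, gene_sets, universe = genes)

  res <- list(
    config = cfg,
    catalog = catalog,
    planted_pairs = planted,
    sites = sites,
    presence = sim$presence,
    tree = sim$tree,
    extensive_pairs = pairs,
    overlap_test = overlap_test,
    association = association,
    conservation_calls = calls,
    class_split = class_split,
    cotarget = cot,
    cotarget_fractions = cotarget_fractions,
    gene_groups = groups,
    expression = expr,
    downregulation = downreg,
    additivity = additivity,
    hi = hi,
    hi_test = hi_test,
    enrichment = enrichment
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(res, out_dir, rng_seed = rng_seed, B = B)
  }
  res
}

# a handful of synthetic gene sets, one enriched in the overlap targets
#' @keywords internal
#' @noRd
simulate_gene_sets <- function(genes, overlap_genes, n_sets = 8L,
                               rng_seed = NULL) {
  with_rng(rng_seed, {
    sets <- lapply(seq_len(n_sets - 1L), function(i) {
      sample(genes, sample(30:80, 1L))
    })
    names(sets) <- sprintf("RANDOM_SET_%02d", seq_len(n_sets - 1L))
    n_sig <- max(5L, min(length(overlap_genes), 40L))
    sets[["OVERLAP_TARGET_SET"]] <- unique(c(
      sample(overlap_genes, n_sig),
      sample(genes, 20L)
    ))
    sets
  })
}

#' @keywords internal
#' @noRd
write_pipeline_outputs <- function(res, out_dir, rng_seed, B) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(res$catalog[, c("mirna_id", "mature_seq", "family_id",
                                   "conservation_group", "mirbase_accession",
                                   "cluster_id", "n_loci")],
                   p("mirna_catalog.tsv"), progress = FALSE)
  write_site_table(res$sites, p("sites.tsv"))
  readr::write_tsv(res$presence, p("species_presence.tsv"), progress = FALSE)
  ape::write.tree(res$tree, p("species_tree.nwk"))
  write_expression_table(res$expression, p("expression.tsv"))
  readr::write_tsv(res$hi, p("haploinsufficiency.tsv"), progress = FALSE)
  readr::write_tsv(res$extensive_pairs, p("extensive_pairs.tsv"), progress = FALSE)
  readr::write_tsv(res$class_split, p("class_split.tsv"), progress = FALSE)
  readr::write_tsv(res$downregulation, p("downregulation.tsv"), progress = FALSE)
  readr::write_tsv(
    dplyr::select(res$enrichment, -"overlap_genes"),
    p("enrichment.tsv"), progress = FALSE
  )
  summary <- list(
    observed_freq = res$overlap_test$observed_freq,
    p_emp = res$overlap_test$p_emp,
    neg_log10_p = res$overlap_test$neg_log10_p,
    n_extensive_pairs = nrow(unique(res$extensive_pairs[, c("family_a", "family_b")])),
    additivity_p = res$additivity$p_value
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    tool = "cotargetr",
    version = as.character(utils::packageVersion("cotargetr")),
    subcommand = "full-run",
    rng_seed = if (is.null(rng_seed)) NA else rng_seed,
    B = B,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    n_mirnas = res$config$n_mirnas,
    n_genes = res$config$n_genes,
    input_digests = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                                     pattern = "\\.(tsv|nwk)$")))
  )
  names(manifest$input_digests) <- basename(names(manifest$input_digests))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
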
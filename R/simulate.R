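# Synthetic-data generator: emits every input the pipeline consumes, with
# the statistical structure the downstream analyses assume (planted
# extensive-overlap miRNA pairs, a two-class conservation-depth mixture,
# additive per-site repression, class-shifted haploinsufficiency).

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults encode the study
#' conditions of the analyses: an 84-species panel, a 0.65/0.35
#' shallow/deep mixture among conserved sites split at 62 species, 50
#' planted extensive-overlap miRNA pairs, site-type effect sizes ordered
#' 8mer < 7mer-m8 <= 7mer-A1 < 6mer < 0 on the log2 scale, and additive
#' double-miRNA responses (`delta = 0`).
#'
#' @param rng_seed Master RNG seed (integer or `NULL`).
#' @param n_mirnas Number of miRNAs (>= 2, and >= 2 * planted pairs).
#' @param n_planted_extensive_pairs Disjoint miRNA pairs planted with
#'   extensive seed overlap (partner seed shifted by 1-2 nt).
#' @param n_genes Number of genes.
#' @param sites_per_gene_mean Poisson mean of background sites per gene.
#' @param n_species Species panel size (reference species first).
#' @param w_shallow Mixture weight of the shallow class among conserved sites.
#' @param shallow_range,deep_range,nonconserved_range Inclusive species-count
#'   ranges for the shallow, deep, and non-conserved site classes.
#' @param p_conserved Probability that a background 7mer/8mer site is conserved.
#' @param site_type_probs Named sampling probabilities over the four site types.
#' @param overlap_fraction Target fraction of conserved sites that are planted
#'   seed-overlap cotargets.
#' @param neighborhood_fraction Target fraction of conserved sites that are
#'   planted neighborhood cotargets (seed starts 15-100 nt apart).
#' @param beta Named per-site log2 fold-change effects, one per site type;
#'   must satisfy `beta_8mer < beta_7mer-m8 <= beta_7mer-A1 < beta_6mer < 0`.
#' @param sigma Gaussian noise SD on the log2 scale (> 0).
#' @param delta Cooperativity added to the double-transfection response of
#'   genes with sites for both miRNAs (0 = purely additive).
#' @param hi_mean,hi_shift,hi_concentration Beta-distribution parameters of
#'   the haploinsufficiency probabilities: baseline mean, additive mean shift
#'   of the focal class, and concentration.
#' @param cluster_prob,multilocus_prob Named probabilities (`planted`,
#'   `other`) of miRNA cluster membership and multi-locus distribution.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(rng_seed = NULL,
                       n_mirnas = 120L,
                       n_planted_extensive_pairs = 50L,
                       n_genes = 2000L,
                       sites_per_gene_mean = 3,
                       n_species = 84L,
                       w_shallow = 0.65,
                       shallow_range = c(20L, 61L),
                       deep_range = c(62L, 84L),
                       nonconserved_range = c(1L, 19L),
                       p_conserved = 0.35,
                       site_type_probs = c("8mer" = 0.15, "7mer-m8" = 0.35,
                                           "7mer-A1" = 0.30, "6mer" = 0.20),
                       overlap_fraction = 0.10,
                       neighborhood_fraction = 0.10,
                       beta = c("8mer" = -0.6, "7mer-m8" = -0.4,
                                "7mer-A1" = -0.35, "6mer" = -0.15),
                       sigma = 0.15,
                       delta = 0,
                       hi_mean = 0.3,
                       hi_shift = 0.2,
                       hi_concentration = 10,
                       cluster_prob = c(planted = 0.6, other = 0.2),
                       multilocus_prob = c(planted = 0.6, other = 0.2)) {
  cfg <- list(
    rng_seed = rng_seed,
    n_mirnas = as.integer(n_mirnas),
    n_planted_extensive_pairs = as.integer(n_planted_extensive_pairs),
    n_genes = as.integer(n_genes),
    sites_per_gene_mean = sites_per_gene_mean,
    n_species = as.integer(n_species),
    w_shallow = w_shallow,
    shallow_range = as.integer(shallow_range),
    deep_range = as.integer(deep_range),
    nonconserved_range = as.integer(nonconserved_range),
    p_conserved = p_conserved,
    site_type_probs = site_type_probs,
    overlap_fraction = overlap_fraction,
    neighborhood_fraction = neighborhood_fraction,
    beta = beta,
    sigma = sigma,
    delta = delta,
    hi_mean = hi_mean,
    hi_shift = hi_shift,
    hi_concentration = hi_concentration,
    cluster_prob = cluster_prob,
    multilocus_prob = multilocus_prob
  )
  if (cfg$n_mirnas < 2L) stop("n_mirnas must be >= 2", call. = FALSE)
  if (2L * cfg$n_planted_extensive_pairs > cfg$n_mirnas) {
    stop("infeasible planting: need n_mirnas >= 2 * n_planted_extensive_pairs",
         call. = FALSE)
  }
  if (cfg$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  probs <- c(cfg$w_shallow, cfg$p_conserved, cfg$overlap_fraction,
             cfg$neighborhood_fraction, cfg$hi_mean, cfg$hi_shift,
             cfg$cluster_prob, cfg$multilocus_prob, cfg$site_type_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$overlap_fraction + cfg$neighborhood_fraction >= 1) {
    stop("overlap_fraction + neighborhood_fraction must be < 1", call. = FALSE)
  }
  b <- cfg$beta[SITE_TYPES]
  if (anyNA(b) ||
      !(b[["8mer"]] < b[["7mer-m8"]] && b[["7mer-m8"]] <= b[["7mer-A1"]] &&
        b[["7mer-A1"]] < b[["6mer"]] && b[["6mer"]] < 0)) {
    stop("beta must satisfy 8mer < 7mer-m8 <= 7mer-A1 < 6mer < 0", call. = FALSE)
  }
  if (!setequal(names(cfg$site_type_probs), SITE_TYPES)) {
    stop("site_type_probs must name the four site types", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# extensive overlap (any pair-calling site type) or identity against a seed pool
#' @keywords internal
#' @noRd
seed_conflicts <- function(candidate, pool) {
  if (length(pool) == 0L) return(FALSE)
  if (candidate %in% pool) return(TRUE)
  for (st in c("8mer", "7mer-m8", "7mer-A1")) {
    s <- site_match_seq(c(candidate, pool), st)
    if (any(is_extensive_vec(rep(s[1L], length(pool)), s[-1L]))) return(TRUE)
  }
  FALSE
}

#' @keywords internal
#' @noRd
random_seed7 <- function() {
  paste(sample(RNA_BASES, 7L, replace = TRUE), collapse = "")
}

#' Simulate a miRNA catalog with planted extensive-overlap pairs
#'
#' Draws random 7-nt seeds and plants `n_planted_extensive_pairs` disjoint
#' family pairs whose 7mer-m8 site-match sequences are shifted copies (by 1
#' or 2 nt), guaranteeing a maximum overlap of `L-1` or `L-2`. All other
#' seeds are rejection-sampled so that no unplanted pair overlaps
#' extensively, making the planted pairs the exact ground truth for
#' [extensive_pairs()]. Planted-pair members are preferentially assigned to
#' miRNA clusters and to multiple genomic loci.
#'
#' @param cfg A [sim_config()].
#' @param rng_seed RNG seed; defaults to `cfg$rng_seed`.
#' @return A catalog tibble (columns of [read_mirna_catalog()] plus `seed`,
#'   `in_cluster`, `planted_pair`) with attribute `planted_pairs`: a tibble
#'   of `pair_id`, `family_a`, `family_b`, `shift`.
#' @export
simulate_mirna_catalog <- function(cfg, rng_seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_mirnas
  P <- cfg$n_planted_extensive_pairs
  with_rng(rng_seed, {
    seeds <- character(0)
    shifts <- integer(0)
    planted_pair <- rep(NA_integer_, n)
    for (j in seq_len(P)) {
      found <- FALSE
      for (try in seq_len(1000L)) {
        base <- retry_sample(function() random_seed7(),
                             function(s) !seed_conflicts(s, seeds))
        site1 <- rna_revcomp(base)
        # all shifted-site partners (shift by 1 or 2 nt), in random order
        cand <- tibble::tibble(
          shift = rep(1:2, c(4L, 16L)),
          tail_bases = c(RNA_BASES,
                         apply(expand.grid(RNA_BASES, RNA_BASES), 1L, paste,
                               collapse = ""))
        )
        cand <- cand[sample.int(nrow(cand)), ]
        cand$seed <- rna_revcomp(paste0(substring(site1, cand$shift + 1L, 7L),
                                        cand$tail_bases))
        for (i in seq_len(nrow(cand))) {
          s <- cand$seed[[i]]
          if (s != base && !seed_conflicts(s, seeds)) {
            seeds <- c(seeds, base, s)
            shifts <- c(shifts, cand$shift[[i]])
            planted_pair[c(2L * j - 1L, 2L * j)] <- j
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (!found) {
        stop("could not plant a non-conflicting extensive pair; relax the configuration",
             call. = FALSE)
      }
    }
    for (i in seq_len(n - 2L * P)) {
      seeds <- c(seeds, retry_sample(function() random_seed7(),
                                     function(s) !seed_conflicts(s, seeds)))
    }
    is_planted <- !is.na(planted_pair)
    p_cl <- ifelse(is_planted, cfg$cluster_prob[["planted"]],
                   cfg$cluster_prob[["other"]])
    in_cluster <- stats::runif(n) < p_cl
    cluster_id <- rep(NA_character_, n)
    # planted pair members that are both clustered share one polycistron
    for (j in seq_len(P)) {
      idx <- c(2L * j - 1L, 2L * j)
      cluster_id[idx][in_cluster[idx]] <- sprintf("cluster-p%02d", j)
    }
    solo <- which(in_cluster & is.na(cluster_id))
    cluster_id[solo] <- sprintf("cluster-s%03d", seq_along(solo))
    p_ml <- ifelse(is_planted, cfg$multilocus_prob[["planted"]],
                   cfg$multilocus_prob[["other"]])
    n_loci <- ifelse(stats::runif(n) < p_ml, sample(2:3, n, replace = TRUE), 1L)
    mature <- paste0(
      sample(RNA_BASES, n, replace = TRUE), seeds,
      vapply(seq_len(n),
             function(i) paste(sample(RNA_BASES, 14L, replace = TRUE), collapse = ""),
             character(1))
    )
    fam <- sprintf("fam-%03d", seq_len(n))
    out <- tibble::tibble(
      mirna_id = sprintf("syn-miR-%03d", seq_len(n)),
      mature_seq = mature,
      family_id = fam,
      conservation_group = 2L,
      mirbase_accession = sprintf("MIMAT%07d", seq_len(n)),
      cluster_id = cluster_id,
      n_loci = as.integer(n_loci),
      seed = seeds,
      in_cluster = in_cluster,
      planted_pair = planted_pair
    )
    attr(out, "planted_pairs") <- tibble::tibble(
      pair_id = seq_len(P),
      family_a = fam[2L * seq_len(P) - 1L],
      family_b = fam[2L * seq_len(P)],
      shift = shifts
    )
    out
  })
}

#' @keywords internal
#' @noRd
retry_sample <- function(draw, ok, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    x <- draw()
    if (ok(x)) return(x)
  }
  stop("could not sample a non-conflicting seed; relax the configuration",
       call. = FALSE)
}

# Ladder (pectinate) ultrametric species tree, reference species first.
# Join heights are chosen so that, with nested presence vectors, sites
# present in >= 20 species always exceed the largest BLS conservation
# cutoff and sites present in <= 19 never reach the smallest one.
#' @keywords internal
#' @noRd
simulate_species_tree <- function(n_species) {
  species <- sprintf("s%03d", seq_len(n_species))
  h <- numeric(n_species)
  h[2L] <- stats::runif(1, 0.004, 0.006)
  for (i in 3:19) h[i] <- h[i - 1L] + stats::runif(1, 0.004, 0.006)
  h[20L] <- 1.5 + stats::runif(1, 0, 0.1)
  for (i in 21:n_species) h[i] <- h[i - 1L] + stats::runif(1, 0.01, 0.03)
  nwk <- sprintf("(%s:%.6f,%s:%.6f)", species[1L], h[2L], species[2L], h[2L])
  for (i in 3:n_species) {
    nwk <- sprintf("(%s:%.6f,%s:%.6f)", nwk, h[i] - h[i - 1L], species[i], h[i])
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Simulate target sites, species presence, and a species tree
#'
#' Generates a site table over `n_genes` genes. Background sites are placed
#' far apart (no accidental coordinate overlap or neighborhood spacing);
#' planted seed-overlap cotarget pairs (sites of a planted extensive miRNA
#' pair whose intervals intersect, shifted by the pair's seed shift) and
#' planted neighborhood pairs (seed starts 15-100 nt apart) are added so
#' that the planted geometry is the exact ground truth for
#' [find_conserved_overlap()] and [find_neighborhood()]. Conserved sites
#' draw their species count from the shallow/deep mixture; presence vectors
#' are nested along a divergence-ordered ladder tree, so conservation
#' profiles are monotone and BLS is consistent with the conserved flag.
#'
#' @inheritParams simulate_mirna_catalog
#' @param catalog Output of [simulate_mirna_catalog()].
#' @return A list with elements `sites` (tibble; includes `planted_overlap`
#'   and `planted_neighborhood` flags), `presence` (tibble: `site_id` + one
#'   0/1 column per species), and `tree` (`phylo`).
#' @export
simulate_sites_and_conservation <- function(cfg, catalog, rng_seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "sim_config"))
  pairs <- attr(catalog, "planted_pairs")
  with_rng(rng_seed, {
    tree <- simulate_species_tree(cfg$n_species)
    genes <- sprintf("g%05d", seq_len(cfg$n_genes))
    n_sites <- stats::rpois(cfg$n_genes, cfg$sites_per_gene_mean)
    base <- tibble::tibble(
      gene_id = rep(genes, n_sites),
      slot = sequence(n_sites)
    )
    nb <- nrow(base)
    base$family_id <- sample(catalog$family_id, nb, replace = TRUE)
    base$site_type <- sample(names(cfg$site_type_probs), nb, replace = TRUE,
                             prob = cfg$site_type_probs)
    base$start <- 50L + (base$slot - 1L) * 150L + sample(0:10, nb, replace = TRUE)
    base$conserved <- stats::runif(nb) < cfg$p_conserved & base$site_type != "6mer"
    base$planted_overlap <- FALSE
    base$planted_neighborhood <- FALSE

    # plant cotarget pairs so that planted sites make up the target fractions
    # of all conserved sites
    C0 <- sum(base$conserved)
    total <- C0 / (1 - cfg$overlap_fraction - cfg$neighborhood_fraction)
    n_ov <- round(cfg$overlap_fraction * total / 2)
    n_nb <- round(cfg$neighborhood_fraction * total / 2)
    fams <- unique(catalog$family_id)
    plant_one <- function(i, kind) {
      g <- sample(genes, 1L)
      st <- 100000L + i * 300L
      if (kind == "overlap") {
        pr <- pairs[1L + (i - 1L) %% nrow(pairs), ]
        tibble::tibble(
          gene_id = g, slot = NA_integer_,
          family_id = c(pr$family_a, pr$family_b),
          site_type = "7mer-m8",
          start = c(st, st + pr$shift),
          conserved = TRUE,
          planted_overlap = TRUE, planted_neighborhood = FALSE
        )
      } else {
        tibble::tibble(
          gene_id = g, slot = NA_integer_,
          family_id = sample(fams, 2L, replace = TRUE),
          site_type = sample(c("8mer", "7mer-m8"), 2L, replace = TRUE),
          start = c(st, st + sample(15:100, 1L)),
          conserved = TRUE,
          planted_overlap = FALSE, planted_neighborhood = TRUE
        )
      }
    }
    planted <- dplyr::bind_rows(
      purrr::map_dfr(seq_len(n_ov), plant_one, kind = "overlap"),
      purrr::map_dfr(seq_len(n_nb), plant_one, kind = "neighborhood")
    )
    sites <- dplyr::bind_rows(base, planted)
    sites$site_id <- sprintf("site%06d", seq_len(nrow(sites)))
    sites$utr_id <- paste0(sites$gene_id, ":utr")
    sites$end <- sites$start + unname(SITE_LENGTHS[sites$site_type])

    # two-class conservation depths; non-conserved sites sit below the panel
    # threshold, conserved sites draw from the shallow/deep mixture
    ns <- integer(nrow(sites))
    cons <- sites$conserved
    deep <- cons & (stats::runif(nrow(sites)) >= cfg$w_shallow)
    ns[!cons] <- sample(seq(cfg$nonconserved_range[1L], cfg$nonconserved_range[2L]),
                        sum(!cons), replace = TRUE)
    ns[cons & !deep] <- sample(seq(cfg$shallow_range[1L], cfg$shallow_range[2L]),
                               sum(cons & !deep), replace = TRUE)
    ns[deep] <- sample(seq(cfg$deep_range[1L], cfg$deep_range[2L]),
                       sum(deep), replace = TRUE)
    sites$n_species <- ns
    pres <- matrix(0L, nrow(sites), cfg$n_species,
                   dimnames = list(NULL, tree$tip.label))
    for (i in seq_len(nrow(sites))) pres[i, seq_len(ns[i])] <- 1L
    presence <- dplyr::bind_cols(
      tibble::tibble(site_id = sites$site_id),
      tibble::as_tibble(pres)
    )
    sites$bls <- branch_length_scores(presence, tree)$bls
    sites <- sites |>
      dplyr::select("site_id", "gene_id", "utr_id", "start", "end",
                    "family_id", "site_type", "conserved", "bls", "n_species",
                    "planted_overlap", "planted_neighborhood")
    list(sites = sites, presence = presence, tree = tree)
  })
}

#' Simulate gene-level expression responses
#'
#' Per-gene log2 fold changes for two single-miRNA transfections and the
#' double transfection, under additive per-site repression: each site of
#' the transfected miRNA contributes its site-type effect `beta`, Gaussian
#' noise is added on the log2 scale, and the double response is the sum of
#' the two single responses plus `delta` for genes with sites for both
#' miRNAs (plus noise). FDR flags come from two-sided z-tests against
#' `sigma`, Benjamini-Hochberg corrected within each condition.
#'
#' @inheritParams simulate_mirna_catalog
#' @param sites Site table from [simulate_sites_and_conservation()].
#' @param family_a,family_b The two transfected miRNA families.
#' @param genes Gene universe (default: genes appearing in `sites`).
#' @return A long tibble: `gene_id`, `condition` (`family_a`, `family_b`,
#'   `"both"`), `log2fc`, `fdr`, `mean_cpm`.
#' @export
simulate_expression <- function(cfg, sites, family_a, family_b,
                                genes = NULL, rng_seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(genes)) genes <- unique(sites$gene_id)
  with_rng(rng_seed, {
    sig <- function(fam) {
      s <- dplyr::filter(sites, .data$family_id == fam)
      out <- stats::setNames(rep(0, length(genes)), genes)
      if (nrow(s) > 0L) {
        agg <- tapply(cfg$beta[s$site_type], s$gene_id, sum)
        out[names(agg)] <- agg
      }
      out
    }
    sig_a <- sig(family_a)
    sig_b <- sig(family_b)
    n <- length(genes)
    fc_a <- sig_a + stats::rnorm(n, 0, cfg$sigma)
    fc_b <- sig_b + stats::rnorm(n, 0, cfg$sigma)
    fc_both <- fc_a + fc_b + cfg$delta * (sig_a < 0 & sig_b < 0) +
      stats::rnorm(n, 0, cfg$sigma)
    fdr_of <- function(fc, null_sd) {
      stats::p.adjust(2 * stats::pnorm(-abs(fc) / null_sd), method = "BH")
    }
    mean_cpm <- round(2^stats::rnorm(n, 5, 2), 3)
    tibble::tibble(
      gene_id = rep(genes, 3L),
      condition = rep(c(family_a, family_b, "both"), each = n),
      log2fc = unname(c(fc_a, fc_b, fc_both)),
      fdr = c(fdr_of(fc_a, cfg$sigma), fdr_of(fc_b, cfg$sigma),
              fdr_of(fc_both, sqrt(3) * cfg$sigma)),
      mean_cpm = rep(mean_cpm, 3L)
    )
  })
}

#' Simulate haploinsufficiency probabilities
#'
#' Gene-level haploinsufficiency probabilities drawn from Beta
#' distributions: baseline mean `hi_mean`, with the mean of `shifted_genes`
#' (e.g. the deeply conserved target class) raised by `hi_shift`.
#'
#' @inheritParams simulate_mirna_catalog
#' @param genes Character vector of gene ids.
#' @param shifted_genes Subset of `genes` receiving the shifted mean.
#' @return A tibble with `gene_id`, `p_hi`.
#' @export
simulate_hi <- function(cfg, genes, shifted_genes = character(0),
                        rng_seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "sim_config"))
  with_rng(rng_seed, {
    mu <- ifelse(genes %in% shifted_genes,
                 pmin(cfg$hi_mean + cfg$hi_shift, 0.95), cfg$hi_mean)
    c0 <- cfg$hi_concentration
    tibble::tibble(
      gene_id = genes,
      p_hi = stats::rbeta(length(genes), mu * c0, (1 - mu) * c0)
    )
  })
}
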
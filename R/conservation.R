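# Conservation of target sites: species counting, branch-length scores,
# TargetScan-style conserved calls, and the two-class depth split.

# TargetScan BLS conservation cutoffs by site type. 6mer sites are never
# called conserved (TargetScan assigns no conservation cutoff to them).
BLS_CUTOFFS <- c("8mer" = 1.8, "7mer-m8" = 2.8, "7mer-A1" = 3.6, "6mer" = Inf)

# Default species-count threshold separating the shallow (eutherian-mammal)
# and deep (human-to-Coelacanth) conservation classes; 62 of the 84-species
# panel separates Platypus and birds.
SPECIES_THRESHOLD <- 62L

#' Count species in which each site is present
#'
#' @param presence A species-presence tibble: a `site_id` column followed by
#'   one 0/1 (or logical) column per species of the panel, reference species
#'   (human) first.
#' @return A tibble with columns `site_id`, `n_species`.
#' @export
species_count <- function(presence) {
  mat <- presence_matrix(presence)
  tibble::tibble(
    site_id = presence$site_id,
    n_species = as.integer(rowSums(mat))
  )
}

# presence tibble -> logical matrix (sites x species), with validation
#' @keywords internal
#' @noRd
presence_matrix <- function(presence, species = NULL) {
  if (!"site_id" %in% names(presence)) {
    stop("presence table must have a site_id column", call. = FALSE)
  }
  mat <- as.matrix(presence[setdiff(names(presence), "site_id")])
  if (!is.null(species)) {
    missing <- setdiff(colnames(mat), species)
    if (length(missing) > 0L) {
      stop(sprintf("species not in panel/tree: %s",
                   paste(utils::head(missing, 3L), collapse = ", ")), call. = FALSE)
    }
  }
  storage.mode(mat) <- "logical"
  if (anyNA(mat)) stop("presence table contains missing values", call. = FALSE)
  mat
}

#' Branch length score of a species set on a phylogeny
#'
#' The branch length score (BLS) of a site is the total branch length of the
#' minimal subtree of the species phylogeny connecting all species in which
#' the site is present. A site present in one species (or none) scores 0.
#'
#' @param species Character vector of species (tree tip labels) in which the
#'   site is present.
#' @param tree A phylogeny of class `phylo` (from [ape::read.tree()]) with
#'   branch lengths; every species must be a tip.
#' @return A single numeric BLS value.
#' @examples
#' tree <- ape::read.tree(text = "((A:0.1,B:0.2):0.3,C:0.4);")
#' branch_length_score(c("A", "B"), tree)  # 0.3
#' branch_length_score(c("A", "C"), tree)  # 0.8
#' @export
branch_length_score <- function(species, tree) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0L) {
    stop(sprintf("species missing from tree: %s",
                 paste(utils::head(missing, 3L), collapse = ", ")), call. = FALSE)
  }
  if (length(unique(species)) <= 1L) return(0)
  sub <- ape::keep.tip(tree, unique(species))
  # edge lengths of the pruned tree; any root edge above the MRCA is excluded
  sum(sub$edge.length)
}

#' Branch length scores for a whole species-presence table
#'
#' Vectorised companion of [branch_length_score()]: scores every row of a
#' species-presence table against one phylogeny using an edge-incidence
#' matrix (an edge contributes its length when present species lie on both
#' of its sides).
#'
#' @inheritParams species_count
#' @param tree A `phylo` tree whose tips cover the panel species.
#' @return A tibble with columns `site_id`, `bls`.
#' @export
branch_length_scores <- function(presence, tree) {
  stopifnot(inherits(tree, "phylo"))
  mat <- presence_matrix(presence, species = tree$tip.label)
  inc <- edge_tip_incidence(tree)           # species x edges
  el <- attr(inc, "edge_length")
  inc <- inc[colnames(mat), , drop = FALSE]
  counts <- mat %*% inc                     # sites x edges: present tips below edge
  tot <- rowSums(mat)
  cut <- (counts > 0) & (counts < tot)      # edge separates present species
  tibble::tibble(
    site_id = presence$site_id,
    bls = as.numeric(cut %*% el)
  )
}

# tips-below-edge incidence matrix (tips x edges) via postorder traversal
#' @keywords internal
#' @noRd
edge_tip_incidence <- function(tree) {
  po <- stats::reorder(tree, "postorder")
  ntip <- length(po$tip.label)
  nnode <- ntip + po$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]
    ch <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  inc <- matrix(FALSE, ntip, nrow(po$edge),
                dimnames = list(po$tip.label, NULL))
  for (e in seq_len(nrow(po$edge))) {
    inc[desc[[po$edge[e, 2L]]], e] <- TRUE
  }
  attr(inc, "edge_length") <- po$edge.length
  inc
}

#' Classify target-site conservation
#'
#' Applies the TargetScan BLS cutoffs (1.8 for 8mer, 2.8 for 7mer-m8, 3.6
#' for 7mer-A1) to call each site conserved or non-conserved, and splits
#' conserved sites into two depth classes at a species-count threshold
#' (default 62 of 84, separating Platypus and birds): `shallow` (< threshold,
#' typically eutherian mammals) and `deep` (>= threshold, human to
#' Coelacanth).
#'
#' @param sites A tibble with columns `site_id`, `site_type`, `bls`,
#'   `n_species` (e.g. a site table joined to [species_count()] and
#'   [branch_length_scores()]).
#' @param threshold Species-count threshold for the deep class.
#' @return The input tibble with columns `conserved` (logical) and
#'   `depth_class` (factor: nonconserved/shallow/deep) added or replaced.
#' @export
classify_sites <- function(sites, threshold = SPECIES_THRESHOLD) {
  bad <- !sites$site_type %in% SITE_TYPES
  if (any(bad)) {
    stop(sprintf("unknown site type: %s", sites$site_type[bad][1L]), call. = FALSE)
  }
  if (!all(is.finite(sites$bls)) || !all(is.finite(sites$n_species))) {
    stop("bls and n_species must be finite", call. = FALSE)
  }
  sites |>
    dplyr::mutate(
      conserved = unname(.data$bls >= BLS_CUTOFFS[.data$site_type]),
      depth_class = factor(
        dplyr::case_when(
          !.data$conserved ~ "nonconserved",
          .data$n_species >= threshold ~ "deep",
          TRUE ~ "shallow"
        ),
        levels = c("nonconserved", "shallow", "deep")
      )
    )
}

#' Two-class summary of conserved sites
#'
#' Fractions of conserved sites falling in the shallow (< threshold species)
#' and deep (>= threshold) conservation classes. The two fractions sum to 1.
#'
#' @param calls Output of [classify_sites()].
#' @return A tibble with columns `depth_class`, `n`, `fraction` (rows:
#'   shallow, deep).
#' @export
two_class_summary <- function(calls) {
  cons <- dplyr::filter(calls, .data$conserved)
  if (nrow(cons) == 0L) stop("no conserved sites", call. = FALSE)
  tibble::tibble(
    depth_class = c("shallow", "deep"),
    n = c(sum(cons$depth_class == "shallow"), sum(cons$depth_class == "deep"))
  ) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}

#' Per-species conservation profile of a site class
#'
#' For the sites of one conservation class, the fraction present in each
#' species of the panel, in panel order (reference species first). This is
#' the per-class conservation pattern across the vertebrate panel.
#'
#' @param calls Output of [classify_sites()].
#' @param presence Species-presence tibble for (at least) the same sites.
#' @param class Optional class filter: one of `"nonconserved"`, `"shallow"`,
#'   `"deep"`, or `"conserved"` (shallow + deep); `NULL` profiles all sites
#'   in `calls`.
#' @return A tibble with columns `species`, `panel_rank`, `fraction`.
#' @export
conservation_profile <- function(calls, presence, class = NULL) {
  ids <- calls$site_id
  if (!is.null(class)) {
    class <- match.arg(class, c("nonconserved", "shallow", "deep", "conserved"))
    keep <- if (class == "conserved") calls$conserved else calls$depth_class == class
    ids <- calls$site_id[keep]
  }
  if (length(ids) == 0L) stop("no sites in the requested class", call. = FALSE)
  rows <- presence[match(ids, presence$site_id), ]
  if (anyNA(rows$site_id)) {
    stop("presence table does not cover all sites in the class", call. = FALSE)
  }
  mat <- presence_matrix(rows)
  tibble::tibble(
    species = colnames(mat),
    panel_rank = seq_len(ncol(mat)),
    fraction = as.numeric(colMeans(mat))
  )
}
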
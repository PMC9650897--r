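# Internal helpers shared across modules.

RNA_BASES <- c("A", "C", "G", "U")

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

# length of the site-match sequence on the mRNA for each canonical type
SITE_LENGTHS <- c("8mer" = 8L, "7mer-m8" = 7L, "7mer-A1" = 7L, "6mer" = 6L)

# TargetScan conservation groups, as used in the catalog `conservation_group`
# column: broadly conserved (2), conserved (1), poorly conserved but
# confidently annotated (0), possibly misannotated (-1).
CONSERVATION_GROUPS <- c(
  "broadly_conserved" = 2L,
  "conserved"         = 1L,
  "poorly_conserved"  = 0L,
  "misannotated"      = -1L
)

#' @keywords internal
#' @noRd
assert_rna <- function(x, arg = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(sprintf(
      "%s contains non-RNA characters (allowed: A/C/G/U): %s",
      arg, paste(utils::head(x[bad], 3L), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

# DNA -> RNA transliteration used at every I/O boundary; internal alphabet is RNA.
#' @keywords internal
#' @noRd
as_rna <- function(x, quiet = FALSE) {
  x <- toupper(x)
  has_t <- grepl("T", x, fixed = TRUE)
  if (any(has_t)) {
    if (!quiet) {
      message(sprintf("transliterating %d DNA sequence(s) (T -> U)", sum(has_t)))
    }
    x <- chartr("T", "U", x)
  }
  x
}

# vectorised RNA reverse complement
#' @keywords internal
#' @noRd
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state;
# a NULL seed leaves the RNG stream alone.
#' @keywords internal
#' @noRd
with_rng <- function(rng_seed, expr) {
  if (is.null(rng_seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(rng_seed), expr)
  }
}

# Derive a stage seed from a master seed, staying inside 32-bit integer range.
#' @keywords internal
#' @noRd
stage_seed <- function(rng_seed, k) {
  if (is.null(rng_seed)) return(NULL)
  (as.integer(rng_seed) + 97L * as.integer(k)) %% 2147483647L
}
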
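#' @importFrom stats setNames
NULL

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes in the fixed row order used by
#' all substitution matrices and CSV exports in this package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Average molecular weights of the free amino acids (Da). Only differences
# between residues are ever used, so the +18.02 Da water of the free form
# cancels and residue masses would give identical relative values.
.AA_MW <- c(
  A =  89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16,
  Q = 146.15, E = 147.13, G =  75.07, H = 155.16, I = 131.17,
  L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
  S = 105.09, T = 119.12, W = 204.23, Y = 181.19, V = 117.15
)

# Kyte & Doolittle (1982) hydropathy index; dimensionless, range [-4.5, 4.5].
.AA_KD <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Amino-acid property table
#'
#' Builds the property table used by [relative_mw()], [relative_hs()] and
#' [mean_relative_profile()]: molecular weight of the free amino acid in Da
#' and Kyte-Doolittle hydropathy. Either scale can be overridden, e.g. to use
#' an alternative hydrophobicity scale, as long as all 20 standard residues
#' are covered.
#'
#' @param mw Named numeric vector of molecular weights (Da), one per standard
#'   amino acid. Defaults to the free-amino-acid average masses.
#' @param hs Named numeric vector of hydropathy values. Defaults to the
#'   Kyte-Doolittle index.
#' @return An object of class `aa_property_table`: a list with elements `mw`
#'   and `hs`, each a named numeric vector over [AA_ALPHABET].
#' @examples
#' tab <- aa_property_table()
#' tab$mw[["R"]] - tab$mw[["S"]]  # 69.11
#' @export
aa_property_table <- function(mw = .AA_MW, hs = .AA_KD) {
  mw <- .check_property_vector(mw, "mw")
  hs <- .check_property_vector(hs, "hs")
  if (any(mw <= 0)) stop("all molecular weights must be positive")
  structure(list(mw = mw, hs = hs), class = "aa_property_table")
}

.check_property_vector <- function(x, what) {
  if (is.null(names(x)) || !setequal(names(x), AA_ALPHABET)) {
    stop(sprintf("property vector '%s' must be named with exactly the 20 standard amino acids", what))
  }
  x <- x[AA_ALPHABET]
  if (anyNA(x)) stop(sprintf("property vector '%s' contains NA", what))
  x
}

#' Read or write a single property scale as CSV
#'
#' The interchange format is a two-column CSV `amino_acid,value` covering the
#' 20 standard residues, allowing alternative hydrophobicity (or mass) scales
#' to be supplied from a file.
#'
#' @param path File path.
#' @return `read_property_scale` returns a named numeric vector over
#'   [AA_ALPHABET]; `write_property_scale` returns `path` invisibly.
#' @export
read_property_scale <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("amino_acid", "value") %in% names(df))) {
    stop("property scale CSV must have columns 'amino_acid' and 'value'")
  }
  .check_property_vector(setNames(df$value, df$amino_acid), basename(path))
}

#' @rdname read_property_scale
#' @param scale Named numeric vector over the 20 standard amino acids.
#' @export
write_property_scale <- function(scale, path) {
  scale <- .check_property_vector(scale, "scale")
  utils::write.csv(data.frame(amino_acid = names(scale), value = unname(scale)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.lookup_aa <- function(aa, scale, what) {
  bad <- setdiff(unique(aa), AA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("non-standard amino acid code(s) for %s: %s",
                 what, paste(bad, collapse = ", ")))
  }
  unname(scale[aa])
}

#' Relative molecular weight of a substitution
#'
#' MW(mutant) - MW(wild type) in Da. Positive values mean the substitution
#' tends toward a bulkier residue. Antisymmetric in its arguments.
#'
#' @param wt_aa,mut_aa One-letter codes (vectorised).
#' @param table An [aa_property_table()].
#' @return Numeric vector of Da differences.
#' @examples
#' relative_mw("S", "R")  # +69.11
#' @export
relative_mw <- function(wt_aa, mut_aa, table = aa_property_table()) {
  .lookup_aa(mut_aa, table$mw, "mut_aa") - .lookup_aa(wt_aa, table$mw, "wt_aa")
}

#' Relative hydrophobicity of a substitution
#'
#' HS(mutant) - HS(wild type) on the Kyte-Doolittle scale (or the scale in
#' `table`). Negative values mean the substitution makes the position more
#' hydrophilic. Antisymmetric; bounded by [-9, 9] on the default scale.
#'
#' @inheritParams relative_mw
#' @return Numeric vector of hydropathy differences.
#' @examples
#' relative_hs("L", "R")  # -8.3
#' @export
relative_hs <- function(wt_aa, mut_aa, table = aa_property_table()) {
  .lookup_aa(mut_aa, table$hs, "mut_aa") - .lookup_aa(wt_aa, table$hs, "wt_aa")
}

#' Per-position mean relative property profile
#'
#' For each region position, the arithmetic mean of the relative molecular
#' weight (or relative hydropathy) over all substitutions identified at that
#' position. Positions with no substitutions are reported as `NA` (undefined),
#' never 0, so unmutated positions cannot fake a signal.
#'
#' @param records Substitution records, as returned by
#'   [read_substitution_table()] or [as_substitution_records()].
#' @param region A [region_spec()].
#' @param property `"mw"` or `"hs"`.
#' @param table An [aa_property_table()].
#' @param weight_by_hits If `TRUE`, each record contributes `hit_count` times
#'   (independent revertants); default `FALSE` counts each distinct
#'   substitution once, matching a presence/absence matrix.
#' @return Data frame with columns `position`, `wt_aa`, `n_substitutions`,
#'   `mean_relative` (NA where `n_substitutions == 0`).
#' @export
mean_relative_profile <- function(records, region, property = c("mw", "hs"),
                                  table = aa_property_table(),
                                  weight_by_hits = FALSE) {
  property <- match.arg(property)
  records <- as_substitution_records(records, region)
  positions <- seq(region$start, region$end)
  f <- if (property == "mw") relative_mw else relative_hs
  rel <- f(records$wt_aa, records$mut_aa, table)
  w <- if (weight_by_hits) {
    if (any(records$hit_count == 0)) {
      stop("hit counts unknown (0); cannot weight by hits")
    }
    records$hit_count
  } else {
    rep(1L, nrow(records))
  }
  sums <- tapply(rel * w, factor(records$position, levels = positions),
                 sum, default = 0)
  ns <- tapply(w, factor(records$position, levels = positions),
               sum, default = 0L)
  mean_rel <- ifelse(ns > 0, sums / ns, NA_real_)
  data.frame(
    position = positions,
    wt_aa = region_residues(region),
    n_substitutions = as.integer(ns),
    mean_relative = as.numeric(mean_rel),
    row.names = NULL
  )
}
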
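#' Validate and normalise suppressor substitution records
#'
#' A substitution record is one identified suppressor allele: residue
#' position, wild-type residue, mutant residue and the number of independent
#' revertants it was recovered in (`hit_count`; 0 means unknown). Records are
#' validated against the mutagenised region: positions must fall inside it,
#' the wild-type residue must match the region sequence, identity
#' substitutions and non-standard letters (including stop `*`, since no
#' premature stop codons are recoverable as viable suppressors) are rejected.
#' Duplicate (position, mutant) rows are merged by summing hit counts:
#' multiple isolates of the same allele are independent revertants.
#'
#' @param x Data frame with columns `position`, `wt_aa`, `mut_aa` and
#'   optionally `hit_count`.
#' @param region A [region_spec()].
#' @return Data frame of class `substitution_records` with the four columns,
#'   sorted by position then mutant residue, one row per distinct allele.
#' @export
as_substitution_records <- function(x, region) {
  if (inherits(x, "substitution_records") &&
      identical(attr(x, "region"), region)) {
    return(x)
  }
  req <- c("position", "wt_aa", "mut_aa")
  if (!all(req %in% names(x))) {
    stop("records need columns position, wt_aa, mut_aa")
  }
  n <- nrow(x)
  if (n == 0L) {
    out <- data.frame(position = integer(), wt_aa = character(),
                      mut_aa = character(), hit_count = integer())
    return(.as_records(out, region))
  }
  pos <- as.integer(x$position)
  wt <- toupper(as.character(x$wt_aa))
  mut <- toupper(as.character(x$mut_aa))
  hits <- if ("hit_count" %in% names(x)) as.integer(x$hit_count) else rep(0L, n)
  row_id <- seq_len(n)

  .reject <- function(bad, why) {
    if (any(bad)) {
      stop(sprintf("invalid substitution row(s) %s: %s",
                   paste(row_id[bad], collapse = ", "), why))
    }
  }
  .reject(is.na(pos), "position is not an integer")
  .reject(!(wt %in% AA_ALPHABET),
          "wt_aa is not a standard amino acid (B/Z/X/U/O/* rejected)")
  .reject(!(mut %in% AA_ALPHABET),
          "mut_aa is not a standard amino acid; stop codons are not valid suppressor records")
  .reject(pos < region$start | pos > region$end,
          sprintf("position outside region %s %d-%d", region$protein_name,
                  region$start, region$end))
  .reject(wt != region_wt_at(region, pmax(pmin(pos, region$end), region$start)),
          "wt_aa does not match the region wild-type sequence")
  .reject(wt == mut, "wt_aa equals mut_aa (identity is not a mutation)")
  .reject(is.na(hits) | hits < 0L, "hit_count must be a non-negative integer")

  key <- paste(pos, mut)
  agg <- rowsum(hits, key)
  first <- !duplicated(key)
  out <- data.frame(position = pos[first], wt_aa = wt[first],
                    mut_aa = mut[first],
                    hit_count = as.integer(agg[paste(pos, mut)[first], 1L]))
  out <- out[order(out$position, match(out$mut_aa, AA_ALPHABET)), ]
  rownames(out) <- NULL
  .as_records(out, region)
}

.as_records <- function(df, region) {
  class(df) <- c("substitution_records", "data.frame")
  attr(df, "region") <- region
  df
}

#' Read / write a suppressor substitution table (TSV)
#'
#' The interchange dialect is tab-separated text with a header line
#' `position  wt_aa  mut_aa  [hit_count]`; lines starting with `#` are
#' comments. Rows are validated against `region` exactly as in
#' [as_substitution_records()].
#'
#' @param path TSV file path.
#' @param region A [region_spec()].
#' @return A `substitution_records` data frame.
#' @export
read_substitution_table <- function(path, region) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  as_substitution_records(df, region)
}

#' @rdname read_substitution_table
#' @param records A `substitution_records` data frame.
#' @export
write_substitution_table <- function(records, path) {
  utils::write.table(as.data.frame(records)[, c("position", "wt_aa", "mut_aa", "hit_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Position-by-amino-acid substitution matrix
#'
#' The central screen summary: a 20-row (amino acids, fixed order
#' [AA_ALPHABET]) by region-width grid. In `"presence"` mode (default,
#' matching a boolean hit matrix) each identified allele sets its cell to 1;
#' in `"count"` mode cells carry revertant hit counts, which requires all
#' counts to be known (> 0). Cells at the wild-type residue are structurally
#' zero because identity records are rejected upstream.
#'
#' @param records Substitution records (coerced via
#'   [as_substitution_records()]).
#' @param region A [region_spec()].
#' @param mode `"presence"` or `"count"`.
#' @return Integer matrix of class `substitution_matrix` with `region` and
#'   `mode` attributes; rownames are amino acids, colnames positions.
#' @export
substitution_matrix <- function(records, region, mode = c("presence", "count")) {
  mode <- match.arg(mode)
  records <- as_substitution_records(records, region)
  m <- matrix(0L, nrow = 20L, ncol = region_length(region),
              dimnames = list(AA_ALPHABET, region_positions(region)))
  if (nrow(records) > 0L) {
    val <- if (mode == "count") {
      if (any(records$hit_count == 0L)) {
        stop("hit counts unknown (0); use mode = \"presence\"")
      }
      records$hit_count
    } else {
      rep(1L, nrow(records))
    }
    m[cbind(match(records$mut_aa, AA_ALPHABET),
            records$position - region$start + 1L)] <- val
  }
  structure(m, region = region, mode = mode,
            class = c("substitution_matrix", class(m)))
}

#' Write / read a substitution matrix as CSV
#'
#' Positions are columns (ascending), the 20 amino acids are rows in the
#' fixed order [AA_ALPHABET]; the first CSV column is `mut_aa`.
#'
#' @param mat A [substitution_matrix()].
#' @param path CSV file path.
#' @export
write_substitution_matrix <- function(mat, path) {
  df <- data.frame(mut_aa = rownames(mat), unclass(mat), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_substitution_matrix
#' @param region Region the matrix belongs to (restored as attribute).
#' @export
read_substitution_matrix <- function(path, region) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(df$mut_aa, AA_ALPHABET)) {
    stop("matrix CSV rows must be the 20 amino acids in the canonical order")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- AA_ALPHABET
  if (!identical(as.integer(colnames(m)), region_positions(region))) {
    stop("matrix CSV columns do not match the region positions")
  }
  structure(m, region = region, mode = "unknown",
            class = c("substitution_matrix", class(m)))
}

#' Substitution number per position
#'
#' The number of distinct mutant amino acids recovered as suppressors at each
#' position (0..19); the per-position height of the screen's substitution
#' profile.
#'
#' @param mat A [substitution_matrix()].
#' @return Named integer vector, names are positions.
#' @export
substitution_number_profile <- function(mat) {
  out <- colSums(unclass(mat) > 0L)
  storage.mode(out) <- "integer"
  out
}

#' Wild-type and mutant amino-acid preference counts
#'
#' Tallies, over all identified substitutions, how often each amino acid
#' occurs as the wild-type residue being replaced and how often as the mutant
#' replacement. In this screen leucine dominates the wild-type tally while
#' arginine and glycine are enriched among mutants.
#'
#' @param records Substitution records.
#' @param region A [region_spec()].
#' @return List of class `preference_counts`: `wt_counts` and `mut_counts`
#'   (named integer vectors over [AA_ALPHABET]), `n_records`, and the argmax
#'   residues `top_wt` / `top_mut`.
#' @export
amino_acid_preferences <- function(records, region) {
  records <- as_substitution_records(records, region)
  if (nrow(records) == 0L) stop("no substitution records")
  wt <- table(factor(records$wt_aa, levels = AA_ALPHABET))
  mut <- table(factor(records$mut_aa, levels = AA_ALPHABET))
  structure(list(
    wt_counts = setNames(as.integer(wt), AA_ALPHABET),
    mut_counts = setNames(as.integer(mut), AA_ALPHABET),
    n_records = nrow(records),
    top_wt = AA_ALPHABET[which.max(wt)],
    top_mut = AA_ALPHABET[which.max(mut)]
  ), class = "preference_counts")
}

#' @export
print.preference_counts <- function(x, ...) {
  cat(sprintf("<preference_counts> %d substitutions; wt argmax %s, mutant argmax %s\n",
              x$n_records, x$top_wt, x$top_mut))
  invisible(x)
}

#' Multi-hit saturation statistic
#'
#' Fraction of identified alleles recovered in at least two independent
#' revertants — the screen-saturation proxy: the closer to 1, the closer the
#' screen is to having sampled its recoverable repertoire.
#'
#' @param records Substitution records with known hit counts (all
#'   `hit_count >= 1`).
#' @return Fraction in \[0, 1\].
#' @export
hit_saturation <- function(records) {
  if (nrow(records) == 0L) stop("no substitution records")
  if (any(records$hit_count == 0L)) {
    stop("hit counts unknown (0); saturation is undefined - use presence-only summaries instead")
  }
  mean(records$hit_count >= 2L)
}
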
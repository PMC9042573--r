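.GAP_CHARS <- c("-", ".")
# ambiguity codes in homologue sequences carry no usable residue identity
.AMBIG_CHARS <- c("B", "Z", "X", "J", "U", "O", "*")

#' Read a protein multiple sequence alignment
#'
#' Reads aligned FASTA or Clustal text into a simple alignment object. All
#' sequences must have equal aligned length; a ragged FASTA is rejected with
#' the offending sequence named. Duplicate identifiers are rejected.
#'
#' @param path Alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param reference_id Identifier of the study protein within the alignment
#'   (may be set later; required by [conservation_profile()]).
#' @return Object of class `msa_alignment`: list with `ids`, `seqs`
#'   (uppercase aligned strings), `width`, `reference_id`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           reference_id = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- toupper(as.character(ss))
    widths <- nchar(seqs)
    if (length(unique(widths)) > 1L) {
      off <- ids[widths != widths[1L]][1L]
      stop(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                   off, nchar(seqs[ids == off][1L]), widths[1L]))
    }
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(aln)
    ids <- names(seqs)
    seqs <- toupper(seqs)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence identifier(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(ids) < 2L) stop("an alignment needs at least 2 sequences")
  names(seqs) <- NULL
  if (!is.null(reference_id) && !(reference_id %in% ids)) {
    stop(sprintf("reference_id '%s' not in alignment", reference_id))
  }
  structure(list(ids = ids, seqs = seqs, width = nchar(seqs[1L]),
                 reference_id = reference_id),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("<msa_alignment> %d sequences x %d columns%s\n",
              length(x$ids), x$width,
              if (is.null(x$reference_id)) "" else
                paste0(", reference ", x$reference_id)))
  invisible(x)
}

.alignment_columns <- function(msa) {
  do.call(rbind, strsplit(msa$seqs, ""))
}

#' Shannon entropy of an alignment column
#'
#' H = -sum p_a log2 p_a in bits, with frequencies over the 20 standard
#' amino acids. Under the default `"exclude"` gap policy, gap characters and
#' ambiguity codes (B, Z, X, ...) are dropped before computing frequencies;
#' under `"symbol"` the gap is counted as a 21st symbol. A column with no
#' scorable symbols returns `NA` (undefined), never 0.
#'
#' @param column Character vector of one-letter symbols (one per sequence).
#' @param gap_policy `"exclude"` (default) or `"symbol"`.
#' @return Entropy in bits; `0 <= H <= log2(21)` (log2(20) under the default
#'   policy), or `NA` for an unscorable column.
#' @examples
#' column_entropy(c("L", "L", "R", "R"))  # 1 bit
#' @export
column_entropy <- function(column, gap_policy = c("exclude", "symbol")) {
  gap_policy <- match.arg(gap_policy)
  column <- toupper(column)
  is_gap <- column %in% c(.GAP_CHARS, .AMBIG_CHARS)
  if (gap_policy == "exclude") {
    column <- column[!is_gap]
  } else {
    column[is_gap] <- "-"
  }
  if (length(column) == 0L) return(NA_real_)
  bad <- setdiff(unique(column), c(AA_ALPHABET, "-"))
  if (length(bad) > 0) {
    stop(sprintf("unexpected symbol(s) in column: %s", paste(bad, collapse = ", ")))
  }
  p <- table(column)
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Evolutionary conservation profile over a region
#'
#' Scores each region position from the multiple sequence alignment: the
#' position is mapped to its alignment column through the reference
#' sequence's gap structure, the column's Shannon entropy H (bits) is
#' computed, the raw conservation score is `1 - H / log2(20)`, and the
#' relative evolutionary conservation score (ECS) is the min-max rescaling of
#' the raw scores over the region (so the least conserved scored position is
#' 0 and the most conserved is 1). Columns whose gap fraction exceeds
#' `gap_fraction_max` are flagged low-confidence. Raw scores are always
#' emitted alongside the relative ones, and the scoring choices (entropy base
#' 2, gap policy, min-max normalisation) are recorded as attributes.
#'
#' @param msa An [read_alignment()] object with `reference_id` set (or passed
#'   via `reference_id`).
#' @param region A [region_spec()]; its wild-type sequence must occur in the
#'   degapped reference sequence.
#' @param gap_policy Passed to [column_entropy()].
#' @param gap_fraction_max Columns with a larger gap fraction are flagged.
#' @param reference_id Optional override of `msa$reference_id`.
#' @return Data frame of class `conservation_profile` with columns
#'   `position`, `wt_aa`, `aln_column`, `entropy_bits`, `raw_score`,
#'   `relative_ecs`, `gap_fraction`, `low_confidence`.
#' @export
conservation_profile <- function(msa, region,
                                 gap_policy = c("exclude", "symbol"),
                                 gap_fraction_max = 0.5,
                                 reference_id = msa$reference_id) {
  gap_policy <- match.arg(gap_policy)
  if (is.null(reference_id)) stop("reference_id must be given")
  if (!(reference_id %in% msa$ids)) {
    stop(sprintf("reference_id '%s' not in alignment", reference_id))
  }
  ref <- strsplit(msa$seqs[match(reference_id, msa$ids)], "")[[1]]
  non_gap_cols <- which(!(ref %in% .GAP_CHARS))
  degapped <- paste(ref[non_gap_cols], collapse = "")

  hit <- regexpr(region$wt_sequence, degapped, fixed = TRUE)
  if (hit == -1L) {
    stop(sprintf(
      "region %s %d-%d not found in degapped reference '%s'; best local match: %s",
      region$protein_name, region$start, region$end, reference_id,
      .best_local_match(degapped, region$wt_sequence)))
  }
  offset <- as.integer(hit) - 1L

  cols <- .alignment_columns(msa)
  n_pos <- region_length(region)
  aln_col <- non_gap_cols[offset + seq_len(n_pos)]
  ent <- vapply(aln_col, function(j) column_entropy(cols[, j], gap_policy),
                numeric(1))
  gap_frac <- vapply(aln_col, function(j) {
    mean(cols[, j] %in% c(.GAP_CHARS, .AMBIG_CHARS))
  }, numeric(1))
  raw <- 1 - ent / log2(20)
  rng <- range(raw, na.rm = TRUE)
  rel <- if (any(is.finite(rng)) && diff(rng) > 0) {
    (raw - rng[1L]) / diff(rng)
  } else {
    # region constant: no spread to rescale, report all zeros
    ifelse(is.na(raw), NA_real_, 0)
  }
  out <- data.frame(
    position = region_positions(region),
    wt_aa = region_residues(region),
    aln_column = aln_col,
    entropy_bits = ent,
    raw_score = raw,
    relative_ecs = rel,
    gap_fraction = gap_frac,
    low_confidence = gap_frac > gap_fraction_max
  )
  attr(out, "scoring") <- list(entropy_base = 2, gap_policy = gap_policy,
                               gap_fraction_max = gap_fraction_max,
                               normalisation = "min-max over region")
  class(out) <- c("conservation_profile", "data.frame")
  out
}

# report the alignment window with the fewest mismatches to the region
.best_local_match <- function(degapped, target) {
  n <- nchar(degapped); k <- nchar(target)
  if (n < k) return("reference shorter than region")
  tg <- strsplit(target, "")[[1]]
  best <- c(start = 1L, mism = k + 1L)
  for (s in seq_len(n - k + 1L)) {
    w <- strsplit(substr(degapped, s, s + k - 1L), "")[[1]]
    m <- sum(w != tg)
    if (m < best["mism"]) best <- c(start = s, mism = m)
  }
  sprintf("degapped offset %d with %d mismatch(es)", best[["start"]], best[["mism"]])
}

#' Write a conservation profile as CSV
#'
#' @param profile A [conservation_profile()].
#' @param path CSV file path.
#' @export
write_conservation_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
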
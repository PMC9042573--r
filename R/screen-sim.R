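#' Translate a codon under the standard genetic code
#'
#' Vectorised lookup in the standard code (61 sense codons over 20 amino
#' acids, 3 stops reported as `"*"`).
#'
#' @param codon Character vector of 3-letter DNA codons over A/C/G/T.
#' @return One-letter amino acids, `"*"` for stops.
#' @examples
#' translate_codon(c("ATG", "TAA"))
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L) || any(grepl("[^ACGT]", codon))) {
    stop("codons must be 3-letter strings over A, C, G, T")
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Screen simulator configuration
#'
#' Parameters of the simulated saturation-mutagenesis suppressor screen.
#' Each region position receives `n_per_position` independent transformants,
#' each carrying one uniformly random NNN codon at that position (the
#' mutagenesis uses fully random primers, so all 64 codons are
#' equiprobable, including the 3 stops). A transformant survives selection
#' iff its translated residue differs from wild type, is not a stop, is in
#' the hidden truth set, and an independent Bernoulli detection draw
#' succeeds; `detection_prob` is the uniform detection probability, optionally
#' overridden per allele by `detection_table`. Defaults are sized to yield a
#' few hundred revertants per screen, the scale real plate screens of this
#' design recover.
#'
#' @param region A [region_spec()].
#' @param n_per_position Transformants per position (default 1000).
#' @param detection_prob Uniform detection probability in \[0, 1\]
#'   (default 0.05).
#' @param detection_table Optional data frame `position`, `mut_aa`, `prob`
#'   overriding `detection_prob` for specific alleles.
#' @param seed Integer seed; all simulator draws are ordered position-major
#'   so identical seeds give bit-identical outputs.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(region, n_per_position = 1000L,
                          detection_prob = 0.05, detection_table = NULL,
                          seed = 1L) {
  stopifnot(inherits(region, "region_spec"), n_per_position > 0,
            detection_prob >= 0, detection_prob <= 1)
  if (!is.null(detection_table)) {
    stopifnot(all(c("position", "mut_aa", "prob") %in% names(detection_table)),
              all(detection_table$prob >= 0 & detection_table$prob <= 1))
  }
  structure(list(region = region,
                 n_per_position = as.integer(n_per_position),
                 detection_prob = detection_prob,
                 detection_table = detection_table,
                 codon_model = "uniform_nnn",
                 seed = as.integer(seed)),
            class = "screen_config")
}

#' Hidden ground-truth suppressor set
#'
#' The set of (position, mutant) alleles that genuinely suppress — the role
#' played in a real screen by the unknown complete suppressor repertoire.
#' Identity alleles and stops are rejected at construction.
#'
#' @param region A [region_spec()].
#' @param alleles Data frame with columns `position`, `mut_aa`.
#' @return Data frame of class `truth_set` with attribute `region`.
#' @export
truth_set <- function(region, alleles) {
  stopifnot(all(c("position", "mut_aa") %in% names(alleles)))
  pos <- as.integer(alleles$position)
  mut <- toupper(as.character(alleles$mut_aa))
  if (any(pos < region$start | pos > region$end)) {
    stop("truth allele position outside region")
  }
  if (any(!(mut %in% AA_ALPHABET))) {
    stop("truth alleles must be standard amino acids; stop codons cannot suppress")
  }
  if (any(mut == region_wt_at(region, pos))) {
    stop("truth set contains identity alleles")
  }
  out <- unique(data.frame(position = pos, mut_aa = mut))
  out <- out[order(out$position, match(out$mut_aa, AA_ALPHABET)), ]
  rownames(out) <- NULL
  class(out) <- c("truth_set", "data.frame")
  attr(out, "region") <- region
  out
}

#' Sample a random truth set
#'
#' Draws `n_alleles` distinct non-identity (position, mutant) pairs, useful
#' as a hidden repertoire for simulation studies. The candidate mutants can
#' be restricted (e.g. to hydrophilic residues) and the candidate positions
#' likewise.
#'
#' @param region A [region_spec()].
#' @param n_alleles Number of distinct alleles to draw.
#' @param seed Optional seed (`NULL` uses the current RNG state).
#' @param positions Candidate positions (default: whole region).
#' @param mut_pool Candidate mutant residues (default: all 20).
#' @return A [truth_set()].
#' @export
sample_truth_set <- function(region, n_alleles, seed = NULL,
                             positions = region_positions(region),
                             mut_pool = AA_ALPHABET) {
  if (!is.null(seed)) set.seed(seed)
  cand <- expand.grid(position = positions, mut_aa = mut_pool,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$mut_aa != region_wt_at(region, cand$position), ]
  if (n_alleles > nrow(cand)) stop("n_alleles exceeds candidate alleles")
  truth_set(region, cand[sample.int(nrow(cand), n_alleles), ])
}

#' Build a per-position NNN codon library
#'
#' For every region position, draws `n_per_position` codons uniformly from
#' the 64 (so stop codons enter the library at an expected rate of 3/64).
#' Draws are position-major: reproducible for a given seed.
#'
#' @param region A [region_spec()].
#' @param n_per_position Codons per position.
#' @param seed Optional seed (`NULL` uses the current RNG state).
#' @return Data frame of class `nnn_library`: `position`, `draw` (1..n
#'   within position), `codon`, `mut_aa` (translated; `"*"` for stop).
#' @export
build_nnn_library <- function(region, n_per_position, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_per_position <- as.integer(n_per_position)
  codons <- names(Biostrings::GENETIC_CODE)
  positions <- region_positions(region)
  drawn <- if (n_per_position > 0L) {
    # one vector draw per position, position-major order
    unlist(lapply(positions, function(p) {
      codons[sample.int(64L, n_per_position, replace = TRUE)]
    }))
  } else {
    character(0)
  }
  out <- data.frame(
    position = rep(positions, each = n_per_position),
    draw = rep(seq_len(n_per_position), times = length(positions) *
                 (n_per_position > 0L)),
    codon = drawn,
    stringsAsFactors = FALSE
  )
  out$mut_aa <- if (nrow(out)) translate_codon(out$codon) else character(0)
  class(out) <- c("nnn_library", "data.frame")
  attr(out, "region") <- region
  out
}

.allele_detection_prob <- function(position, mut_aa, config) {
  p <- rep(config$detection_prob, length(position))
  tab <- config$detection_table
  if (!is.null(tab)) {
    idx <- match(paste(position, mut_aa), paste(tab$position, tab$mut_aa))
    p[!is.na(idx)] <- tab$prob[idx[!is.na(idx)]]
  }
  p
}

#' Simulate selection on a mutagenesis library
#'
#' Applies the screen's double selection to a codon library: a library
#' member survives iff its translated residue differs from the wild type at
#' its position, is not a stop codon, the (position, residue) allele belongs
#' to the hidden truth set, and an independent Bernoulli(detection
#' probability) draw succeeds. Survivors are aggregated into substitution
#' records whose hit counts are the number of independent surviving
#' revertants per allele, mimicking one Sanger-read substitution per
#' revertant.
#'
#' @param library A [build_nnn_library()] result.
#' @param truth A [truth_set()] over the same region.
#' @param config A [screen_config()]; its `seed` (unless `NULL`) seeds the
#'   detection draws.
#' @return List of class `revertant_sample`: `survivors` (position, codon,
#'   mut_aa of each surviving revertant), `records` (substitution records
#'   with hit counts), `n_library`, `region`.
#' @export
simulate_screen <- function(library, truth, config) {
  region <- attr(library, "region")
  if (!identical(region, attr(truth, "region"))) {
    stop("library and truth set regions differ")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  if (nrow(library) == 0L) {
    surv <- library[integer(0), c("position", "codon", "mut_aa")]
  } else {
    wt <- region_wt_at(region, library$position)
    eligible <- library$mut_aa != "*" & library$mut_aa != wt &
      paste(library$position, library$mut_aa) %in%
        paste(truth$position, truth$mut_aa)
    p <- .allele_detection_prob(library$position, library$mut_aa, config)
    detected <- stats::runif(nrow(library)) < p
    surv <- library[eligible & detected, c("position", "codon", "mut_aa")]
  }
  rownames(surv) <- NULL
  recs <- if (nrow(surv) > 0L) {
    agg <- stats::aggregate(list(hit_count = rep(1L, nrow(surv))),
                            by = list(position = surv$position,
                                      mut_aa = surv$mut_aa), FUN = sum)
    agg$wt_aa <- region_wt_at(region, agg$position)
    as_substitution_records(agg, region)
  } else {
    as_substitution_records(
      data.frame(position = integer(), wt_aa = character(),
                 mut_aa = character(), hit_count = integer()), region)
  }
  structure(list(survivors = surv, records = recs,
                 n_library = nrow(library), region = region),
            class = "revertant_sample")
}

#' @export
print.revertant_sample <- function(x, ...) {
  cat(sprintf("<revertant_sample> %d revertants, %d distinct alleles (library %d)\n",
              nrow(x$survivors), nrow(x$records), x$n_library))
  invisible(x)
}

#' Run a complete simulated screen
#'
#' Convenience wrapper drawing the library and the detection outcomes from a
#' single seeded stream: `set.seed(config$seed)` once, then library draws
#' (position-major) followed by detection draws.
#'
#' @param config A [screen_config()].
#' @param truth A [truth_set()] over the config's region.
#' @return A [simulate_screen()] result.
#' @export
run_screen <- function(config, truth) {
  set.seed(config$seed)
  lib <- build_nnn_library(config$region, config$n_per_position, seed = NULL)
  cfg <- config; cfg$seed <- NULL
  simulate_screen(lib, truth, cfg)
}

#' Saturation curve over sequencing/screening depth
#'
#' Re-screens nested prefixes of the library (the first `depth` draws at
#' every position, with detection outcomes held fixed across depths) and
#' reports, per depth, the number of surviving revertants, the number of
#' distinct alleles recovered, and the fraction of distinct alleles seen in
#' at least two revertants (`NA` when nothing is recovered). Distinct-allele
#' counts are non-decreasing in depth by construction.
#'
#' @param library A [build_nnn_library()] result.
#' @param truth A [truth_set()].
#' @param config A [screen_config()].
#' @param depths Ascending per-position depths, each `<=` the library depth.
#' @return Data frame: `depth`, `n_revertants`, `n_distinct`,
#'   `fraction_multi_hit`.
#' @export
saturation_curve <- function(library, truth, config, depths) {
  if (is.unsorted(depths)) stop("depths must be ascending")
  if (length(depths) && max(depths) > max(c(library$draw, 0L))) {
    stop("depth exceeds library depth")
  }
  region <- attr(library, "region")
  if (!is.null(config$seed)) set.seed(config$seed)
  wt <- if (nrow(library)) region_wt_at(region, library$position) else character(0)
  eligible <- library$mut_aa != "*" & library$mut_aa != wt &
    paste(library$position, library$mut_aa) %in%
      paste(truth$position, truth$mut_aa)
  detected <- stats::runif(nrow(library)) <
    .allele_detection_prob(library$position, library$mut_aa, config)
  surv_all <- eligible & detected
  out <- do.call(rbind, lapply(depths, function(d) {
    s <- surv_all & library$draw <= d
    n_rev <- sum(s)
    if (n_rev == 0L) {
      return(data.frame(depth = d, n_revertants = 0L, n_distinct = 0L,
                        fraction_multi_hit = NA_real_))
    }
    counts <- table(paste(library$position[s], library$mut_aa[s]))
    data.frame(depth = d, n_revertants = n_rev,
               n_distinct = length(counts),
               fraction_multi_hit = mean(counts >= 2L))
  }))
  rownames(out) <- NULL
  out
}

#' Screen config and truth set JSON I/O
#'
#' Serialises simulator inputs so a simulated study is fully described by
#' two small JSON files.
#'
#' @param config A [screen_config()]; `truth` a [truth_set()].
#' @param path JSON file path.
#' @export
write_screen_config <- function(config, path) {
  jsonlite::write_json(list(
    region = config$region[c("protein_name", "start", "end", "wt_sequence")],
    n_per_position = config$n_per_position,
    detection_prob = config$detection_prob,
    detection_table = config$detection_table,
    codon_model = config$codon_model,
    seed = config$seed
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_screen_config
#' @export
read_screen_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  region <- region_spec(x$region$protein_name, x$region$start, x$region$end,
                        x$region$wt_sequence)
  screen_config(region, x$n_per_position, x$detection_prob,
                detection_table = x$detection_table, seed = x$seed)
}

#' @rdname write_screen_config
#' @param truth A [truth_set()].
#' @export
write_truth_set <- function(truth, path) {
  region <- attr(truth, "region")
  jsonlite::write_json(list(
    region = region[c("protein_name", "start", "end", "wt_sequence")],
    alleles = as.data.frame(truth)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_screen_config
#' @export
read_truth_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  region <- region_spec(x$region$protein_name, x$region$start, x$region$end,
                        x$region$wt_sequence)
  truth_set(region, x$alleles)
}
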
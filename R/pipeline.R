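#' Combined per-position profile
#'
#' Joins the per-position screen statistics into one table: substitution
#' number, mean relative molecular weight, mean relative hydropathy and
#' (when an alignment is supplied) the conservation scores. Positions with no
#' substitutions carry `NA` means.
#'
#' @param records Substitution records.
#' @param region A [region_spec()].
#' @param table An [aa_property_table()].
#' @param conservation Optional [conservation_profile()] for the same region.
#' @return Data frame with columns `position`, `wt_aa`,
#'   `substitution_number`, `mean_rel_mw`, `mean_rel_hs` and, if provided,
#'   `entropy_bits`, `raw_score`, `relative_ecs`.
#' @export
position_profile <- function(records, region, table = aa_property_table(),
                             conservation = NULL) {
  records <- as_substitution_records(records, region)
  mw <- mean_relative_profile(records, region, "mw", table)
  hs <- mean_relative_profile(records, region, "hs", table)
  prof <- substitution_number_profile(substitution_matrix(records, region))
  out <- data.frame(position = mw$position, wt_aa = mw$wt_aa,
                    substitution_number = as.integer(prof),
                    mean_rel_mw = mw$mean_relative,
                    mean_rel_hs = hs$mean_relative)
  if (!is.null(conservation)) {
    idx <- match(out$position, conservation$position)
    out$entropy_bits <- conservation$entropy_bits[idx]
    out$raw_score <- conservation$raw_score[idx]
    out$relative_ecs <- conservation$relative_ecs[idx]
  }
  out
}

#' Call mutational hotspots
#'
#' Maximal runs of at least `min_run` consecutive positions whose
#' substitution number reaches `min_count`. The defaults (5 substitutions
#' over at least 3 consecutive positions) are a config-exposed
#' operationalisation of "frequently mutated"; no universal numeric
#' criterion exists, so interval recovery on real data is
#' threshold-dependent.
#'
#' @param counts Named integer vector of per-position substitution numbers
#'   over a contiguous region ([substitution_number_profile()] output).
#' @param min_count Minimum substitution number per position.
#' @param min_run Minimum run length.
#' @return Data frame of non-overlapping ascending intervals: `start`,
#'   `end`, `length`, `max_count` (region numbering, inclusive).
#' @export
hotspot_call <- function(counts, min_count = 5L, min_run = 3L) {
  positions <- as.integer(names(counts))
  if (length(positions) == 0L) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      max_count = integer()))
  }
  if (any(diff(positions) != 1L)) stop("counts must cover a contiguous region")
  above <- counts >= min_count
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  out <- data.frame(
    start = positions[starts[keep]],
    end = positions[ends[keep]],
    length = r$lengths[keep],
    max_count = vapply(which(keep), function(i) {
      as.integer(max(counts[starts[i]:ends[i]]))
    }, integer(1))
  )
  rownames(out) <- NULL
  out
}

#' Read a pipeline configuration
#'
#' Configurations are JSON or YAML (by extension). See [run_pipeline()] for
#' the accepted fields.
#'
#' @param path Config file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.resolve_region <- function(region) {
  if (inherits(region, "region_spec")) return(region)
  if (is.character(region) && length(region) == 1L) {
    return(switch(region,
                  psm3_hcj = psm3_hcj_region(),
                  rad21_ntd = rad21_ntd_region(),
                  stop(sprintf("unknown built-in region '%s'", region))))
  }
  region_spec(region$protein_name, region$start, region$end, region$wt_sequence)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full screen-analysis pipeline
#'
#' Sequences all analysis stages for one or more mutagenised proteins and
#' writes a machine-readable report bundle. Per protein the bundle contains
#' `<name>_matrix.csv` (position x amino-acid substitution matrix),
#' `<name>_profile.csv` (substitution number, mean relative MW/HS,
#' conservation scores), `<name>_sites.csv` (structural site annotations)
#' and `<name>_hotspots.csv`, plus a shared `run_metadata.json` recording
#' every threshold actually used and the seed. Stages are skippable: with no
#' alignment the conservation columns stay empty, with no structure the site
#' annotation columns stay empty, and the run still succeeds (with a
#' warning). Output is deterministic given inputs and seed; on any stage
#' error the partial outputs are removed.
#'
#' @param config A named list or a path readable by
#'   [read_pipeline_config()]. Fields: `out_dir`; optional `seed` (default
#'   1); `proteins`, a list of entries each with `name`, `region` (a
#'   [region_spec()] field list or `"psm3_hcj"` / `"rad21_ntd"`), and one of
#'   `substitutions` (TSV path) or `simulate` (list with `n_per_position`,
#'   `detection_prob`, and `truth` path or `truth_n` allele count); optional
#'   `msa` (list: `path`, `format`, `reference_id`) and `structure_chain` /
#'   `structure_partner_chain` / `structure_offset`; optional top-level
#'   `structure` (list: `path`, `format`); optional `thresholds`
#'   (`vdw`, `hbond`, `salt`, `burial_radius`, `burial_min`) and `hotspot`
#'   (`min_count`, `min_run`).
#' @return Invisibly, a list of class `report_bundle`: `out_dir`, `files`,
#'   and per-protein result objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)

  thr <- utils::modifyList(
    list(vdw = 4.0, hbond = 3.5, salt = 4.0,
         burial_radius = 7.5, burial_min = 30),
    as.list(config$thresholds %||% list()))
  hot <- utils::modifyList(list(min_count = 5L, min_run = 3L),
                           as.list(config$hotspot %||% list()))

  written <- character(0)
  emit <- function(obj, file, writer) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }

  model <- NULL
  if (!is.null(config$structure)) {
    model <- .stage("structure", read_structure(
      config$structure$path, config$structure$format %||% "auto"))
  }

  results <- list()
  tryCatch({
    for (pr in config$proteins) {
      name <- pr$name
      region <- .stage(paste0(name, "/region"), .resolve_region(pr$region))

      records <- .stage(paste0(name, "/substitutions"), {
        if (!is.null(pr$substitutions)) {
          read_substitution_table(pr$substitutions, region)
        } else if (!is.null(pr$simulate)) {
          sim <- pr$simulate
          truth <- if (!is.null(sim$truth)) {
            read_truth_set(sim$truth)
          } else {
            sample_truth_set(region, sim$truth_n %||% 50L)
          }
          cfg <- screen_config(region,
                               n_per_position = sim$n_per_position %||% 1000L,
                               detection_prob = sim$detection_prob %||% 0.05,
                               seed = seed)
          run_screen(cfg, truth)$records
        } else {
          stop("protein entry needs 'substitutions' or 'simulate'")
        }
      })

      mat <- substitution_matrix(records, region)
      cons <- NULL
      if (!is.null(pr$msa)) {
        cons <- .stage(paste0(name, "/conservation"), {
          msa <- read_alignment(pr$msa$path, pr$msa$format %||% "fasta",
                                reference_id = pr$msa$reference_id)
          conservation_profile(msa, region)
        })
      }
      prof <- position_profile(records, region, conservation = cons)

      sites <- NULL
      if (!is.null(model) && !is.null(pr$structure_chain)) {
        sites <- .stage(paste0(name, "/annotation"), {
          chain <- pr$structure_chain
          contacts <- if (!is.null(pr$structure_partner_chain)) {
            inter_chain_contacts(model, chain, pr$structure_partner_chain,
                                 vdw_cutoff = thr$vdw,
                                 hbond_cutoff = thr$hbond,
                                 salt_cutoff = thr$salt)
          } else {
            NULL
          }
          core <- hydrophobic_core_residues(model, chain,
                                            radius = thr$burial_radius,
                                            burial_min = thr$burial_min)
          annotate_sites(records, region, contacts = contacts,
                         core_positions = core$resno[core$in_core],
                         chain = chain,
                         offset = pr$structure_offset %||% 0L,
                         resolved_positions = unique(
                           model$atoms$resno[model$atoms$chain == chain]))
        })
      } else if (is.null(model)) {
        warning(sprintf("no structure configured: site annotation skipped for %s", name))
      }

      counts <- substitution_number_profile(mat)
      hotspots <- hotspot_call(counts, hot$min_count, hot$min_run)

      emit(mat, paste0(name, "_matrix.csv"), write_substitution_matrix)
      emit(prof, paste0(name, "_profile.csv"), function(x, p) {
        utils::write.csv(x, p, row.names = FALSE, quote = FALSE, na = "")
      })
      if (!is.null(sites)) {
        emit(sites, paste0(name, "_sites.csv"), function(x, p) {
          utils::write.csv(as.data.frame(x), p, row.names = FALSE, quote = FALSE)
        })
      }
      emit(hotspots, paste0(name, "_hotspots.csv"), function(x, p) {
        utils::write.csv(x, p, row.names = FALSE, quote = FALSE)
      })
      results[[name]] <- list(region = region, records = records,
                              matrix = mat, profile = prof,
                              conservation = cons, sites = sites,
                              hotspots = hotspots)
    }

    meta <- list(
      package = "supscreen",
      version = as.character(utils::packageVersion("supscreen")),
      seed = seed,
      thresholds = thr,
      hotspot = hot,
      conservation = list(entropy_base = 2, gap_policy = "exclude",
                          gap_fraction_max = 0.5,
                          normalisation = "min-max over region"),
      proteins = vapply(config$proteins, function(p) p$name, character(1))
    )
    emit(meta, "run_metadata.json", function(x, p) {
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }, error = on_fail)

  invisible(structure(list(out_dir = out_dir, files = written,
                           results = results),
                      class = "report_bundle"))
}
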
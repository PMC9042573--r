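.BACKBONE <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")

#' Build a structure model from an atom table
#'
#' The internal coordinate container: one row per heavy atom with chain,
#' author residue number, insertion code, 3-letter residue name, atom name,
#' element and xyz in Angstrom. Used both by [read_structure()] and to
#' construct synthetic coordinates in code.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`; optional `insert` (default `""`), `element` (default:
#'   first letter of `elety`), `occ` (default 1).
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  req <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop("atoms need columns ", paste(req, collapse = ", "))
  }
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$element)) atoms$element <- substr(atoms$elety, 1L, 1L)
  if (is.null(atoms$occ)) atoms$occ <- 1
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- model_chains(x)
  cat(sprintf("<structure_model> %d heavy atoms, %d chain(s): %s\n",
              nrow(x$atoms), length(ch), paste(ch, collapse = ", ")))
  invisible(x)
}

#' @rdname structure_model
#' @param model A `structure_model`.
#' @export
model_chains <- function(model) sort(unique(model$atoms$chain))

.chain_atoms <- function(model, chain) {
  if (!(chain %in% model$atoms$chain)) {
    stop(sprintf("chain '%s' not in model; available chains: %s", chain,
                 paste(model_chains(model), collapse = ", ")))
  }
  model$atoms[model$atoms$chain == chain, , drop = FALSE]
}

#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Parses coordinates via bio3d, keeping protein heavy atoms of the first
#' model only: hydrogens are dropped and alternate locations are resolved to
#' the highest-occupancy conformer.
#'
#' @param path Coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- if (format == "pdb") {
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  } else {
    # read.cif warns about its beta status and absent secondary-structure
    # records; neither affects the atom table we consume
    suppressWarnings(bio3d::read.cif(path, multi = FALSE, verbose = FALSE))
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  elem <- if (!is.null(at$elesy) && !all(is.na(at$elesy)) && !all(at$elesy == "")) {
    toupper(trimws(at$elesy))
  } else {
    # infer from the atom name: strip digits/primes, first letter
    substr(gsub("[0-9']", "", toupper(at$elety)), 1L, 1L)
  }
  keep <- elem != "H" & elem != "D"
  at <- at[keep, , drop = FALSE]; elem <- elem[keep]
  # altloc resolution: highest occupancy per (chain, resno, insert, atom name)
  ins <- at$insert; ins[is.na(ins)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, ins, at$elety, sep = "|")
  ord <- order(key, -occ)
  at <- at[ord, , drop = FALSE]; elem <- elem[ord]
  ins <- ins[ord]; occ <- occ[ord]; key <- key[ord]
  first <- !duplicated(key)
  structure_model(data.frame(
    chain = at$chain[first], resno = at$resno[first], insert = ins[first],
    resid = toupper(at$resid[first]), elety = at$elety[first],
    element = elem[first], x = at$x[first], y = at$y[first], z = at$z[first],
    occ = occ[first], stringsAsFactors = FALSE
  ))
}

.acid_sidechain_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.base_sidechain_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                          HIS = c("ND1", "NE2"))

#' Inter-chain residue contacts
#'
#' Residue pairs across two chains whose minimum heavy-atom distance is at or
#' below the van der Waals cutoff, classified in precedence order: a
#' `salt_bridge` when an Asp/Glu side-chain oxygen and a Lys/Arg/His
#' side-chain nitrogen lie within `salt_cutoff`; otherwise an `hbond` when
#' any N/O - N/O atom pair lies within `hbond_cutoff`; otherwise `vdw`. The
#' result is symmetric in chain order.
#'
#' @param model A [structure_model()].
#' @param chain_a,chain_b Chain identifiers (must differ and be present).
#' @param vdw_cutoff,hbond_cutoff,salt_cutoff Distance thresholds in
#'   Angstrom; defaults 4.0 / 3.5 / 4.0 follow common structural practice.
#' @return Data frame of class `residue_contacts`: `chain_a`, `resno_a`,
#'   `resid_a`, `chain_b`, `resno_b`, `resid_b`, `min_dist`, `category`.
#' @export
inter_chain_contacts <- function(model, chain_a, chain_b,
                                 vdw_cutoff = 4.0, hbond_cutoff = 3.5,
                                 salt_cutoff = 4.0) {
  a <- .chain_atoms(model, chain_a)
  b <- .chain_atoms(model, chain_b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty chain")
  d <- .cross_dist(as.matrix(a[, c("x", "y", "z")]),
                   as.matrix(b[, c("x", "y", "z")]))
  reach <- max(vdw_cutoff, hbond_cutoff, salt_cutoff)
  hit <- which(d <= reach, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(.empty_contacts())
  pair_key <- paste(a$resno[hit[, 1L]], b$resno[hit[, 2L]], sep = "|")
  out <- do.call(rbind, lapply(split(seq_len(nrow(hit)), pair_key), function(ii) {
    ai <- hit[ii, 1L]; bi <- hit[ii, 2L]
    dd <- d[cbind(ai, bi)]
    min_d <- min(dd)
    if (min_d > reach) return(NULL)
    cat_ <- .classify_contact(a[ai, ], b[bi, ], dd,
                              hbond_cutoff, salt_cutoff)
    if (is.na(cat_) && min_d > vdw_cutoff) return(NULL)
    if (is.na(cat_)) cat_ <- "vdw"
    data.frame(chain_a = chain_a, resno_a = a$resno[ai[1L]],
               resid_a = a$resid[ai[1L]],
               chain_b = chain_b, resno_b = b$resno[bi[1L]],
               resid_b = b$resid[bi[1L]],
               min_dist = min_d, category = cat_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(.empty_contacts())
  out <- out[order(out$resno_a, out$resno_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("residue_contacts", "data.frame")
  out
}

.empty_contacts <- function() {
  out <- data.frame(chain_a = character(), resno_a = integer(),
                    resid_a = character(), chain_b = character(),
                    resno_b = integer(), resid_b = character(),
                    min_dist = numeric(), category = character())
  class(out) <- c("residue_contacts", "data.frame")
  out
}

# classify one residue pair given its qualifying atom rows and distances
.classify_contact <- function(at_a, at_b, dd, hbond_cutoff, salt_cutoff) {
  res_a <- at_a$resid[1L]; res_b <- at_b$resid[1L]
  is_salt_pair <- function(res_o, ety_o, res_n, ety_n) {
    !is.null(.acid_sidechain_O[[res_o]]) && !is.null(.base_sidechain_N[[res_n]]) &&
      ety_o %in% .acid_sidechain_O[[res_o]] && ety_n %in% .base_sidechain_N[[res_n]]
  }
  salt <- mapply(function(ea, eb, dist) {
    dist <= salt_cutoff &&
      (is_salt_pair(res_a, ea, res_b, eb) || is_salt_pair(res_b, eb, res_a, ea))
  }, at_a$elety, at_b$elety, dd)
  if (any(salt)) return("salt_bridge")
  hb <- at_a$element %in% c("N", "O") & at_b$element %in% c("N", "O") &
    dd <= hbond_cutoff
  if (any(hb)) return("hbond")
  NA_character_
}

.cross_dist <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(pmax(d2, 0))
}

#' Hydrophobic-core residues by burial proxy
#'
#' A residue belongs to the hydrophobic core when (i) its side chain is
#' hydrophobic and (ii) its burial proxy — the number of heavy atoms
#' belonging to *other* residues (any chain) within `radius` of its
#' side-chain centroid — reaches `burial_min`. The proxy replaces a solvent
#' accessibility computation with a deterministic neighbour count. Glycine's
#' centroid falls back to its C-alpha.
#'
#' @param model A [structure_model()].
#' @param chain Chain to scan (>= 3 residues).
#' @param radius Neighbour radius in Angstrom (default 7.5).
#' @param burial_min Minimum neighbour count for a buried side chain
#'   (default 30).
#' @param hydrophobic One-letter codes counted as hydrophobic.
#' @return Data frame: `resno`, `resid`, `aa`, `is_hydrophobic`, `burial`,
#'   `in_core`.
#' @export
hydrophobic_core_residues <- function(model, chain, radius = 7.5,
                                      burial_min = 30,
                                      hydrophobic = c("A", "V", "L", "I",
                                                      "M", "F", "W", "Y")) {
  ch <- .chain_atoms(model, chain)
  res_key <- paste(ch$chain, ch$resno, ch$insert)
  if (length(unique(res_key)) < 3L) stop("chain has fewer than 3 residues")
  all_xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  all_key <- paste(model$atoms$chain, model$atoms$resno, model$atoms$insert)
  out <- do.call(rbind, lapply(unique(res_key), function(k) {
    rows <- ch[res_key == k, , drop = FALSE]
    sc <- rows[!(rows$elety %in% .BACKBONE), , drop = FALSE]
    centroid <- if (nrow(sc) > 0L) {
      colMeans(as.matrix(sc[, c("x", "y", "z")]))
    } else {
      ca <- rows[rows$elety == "CA", , drop = FALSE]
      if (nrow(ca) == 0L) ca <- rows[1L, , drop = FALSE]
      unlist(ca[1L, c("x", "y", "z")])
    }
    other <- all_key != k
    dd <- sqrt(colSums((t(all_xyz[other, , drop = FALSE]) - centroid)^2))
    aa <- bio3d::aa321(rows$resid[1L])
    data.frame(resno = rows$resno[1L], resid = rows$resid[1L], aa = aa,
               is_hydrophobic = aa %in% hydrophobic,
               burial = sum(dd <= radius),
               stringsAsFactors = FALSE)
  }))
  out$in_core <- out$is_hydrophobic & out$burial >= burial_min
  rownames(out) <- NULL
  out
}

#' Annotate suppressor sites against a structure
#'
#' Labels each substitution record's position as `interface` (backed by at
#' least one inter-chain residue contact), `hydrophobic_core` (member of the
#' burial-based core set), both, `other` (resolved but neither), or
#' `unresolved` (absent from the structure, e.g. disordered; excluded from
#' fraction summaries).
#'
#' @param records Substitution records.
#' @param region The records' [region_spec()].
#' @param contacts A [inter_chain_contacts()] result, or `NULL`.
#' @param core_positions Integer vector of core residue numbers (structure
#'   numbering), e.g. `resno[in_core]` from [hydrophobic_core_residues()],
#'   or `NULL`.
#' @param chain Structure chain carrying this protein (used to pick the
#'   matching side of `contacts`).
#' @param offset Added to record positions to obtain structure residue
#'   numbers (0 when the structure uses author numbering).
#' @param resolved_positions Residue numbers present in the structure chain;
#'   `NULL` treats every position as resolved.
#' @return Data frame of class `site_annotations`: record columns plus
#'   `struct_resno`, `interface`, `n_contacts`, `hydrophobic_core`,
#'   `category`.
#' @export
annotate_sites <- function(records, region, contacts = NULL,
                           core_positions = NULL, chain = NULL, offset = 0L,
                           resolved_positions = NULL) {
  records <- as_substitution_records(records, region)
  struct_resno <- records$position + as.integer(offset)
  iface_resno <- integer(0)
  n_contacts_at <- function(r) 0L
  if (!is.null(contacts) && nrow(contacts) > 0L) {
    if (is.null(chain)) stop("chain must be given when contacts are supplied")
    on_a <- contacts$chain_a == chain
    on_b <- contacts$chain_b == chain
    iface_resno <- c(contacts$resno_a[on_a], contacts$resno_b[on_b])
    n_contacts_at <- function(r) {
      sum(contacts$resno_a[on_a] == r) + sum(contacts$resno_b[on_b] == r)
    }
  }
  resolved <- if (is.null(resolved_positions)) {
    rep(TRUE, nrow(records))
  } else {
    struct_resno %in% resolved_positions
  }
  interface <- resolved & struct_resno %in% iface_resno
  core <- resolved & struct_resno %in% as.integer(core_positions %||% integer(0))
  category <- ifelse(!resolved, "unresolved",
              ifelse(interface & core, "interface+hydrophobic_core",
              ifelse(interface, "interface",
              ifelse(core, "hydrophobic_core", "other"))))
  out <- data.frame(as.data.frame(records),
                    struct_resno = struct_resno,
                    interface = interface,
                    n_contacts = vapply(struct_resno, n_contacts_at, integer(1)),
                    hydrophobic_core = core,
                    category = category,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_annotations", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise site annotations
#'
#' Fractions of substitutions in each structural category, over resolved
#' records only. The headline screen statistic is `fraction_core`: the share
#' of suppressor substitutions mapping to hydrophobic-core positions.
#'
#' @param annotations An [annotate_sites()] result.
#' @return List: `n_total` (resolved records), `n_unresolved`,
#'   `n_interface`, `n_core`, `n_other`, `fraction_interface`,
#'   `fraction_core`, `fraction_other`.
#' @export
site_summary <- function(annotations) {
  resolved <- annotations$category != "unresolved"
  n <- sum(resolved)
  if (n == 0L) stop("no resolved records")
  list(
    n_total = n,
    n_unresolved = sum(!resolved),
    n_interface = sum(annotations$interface[resolved]),
    n_core = sum(annotations$hydrophobic_core[resolved]),
    n_other = sum(annotations$category[resolved] == "other"),
    fraction_interface = sum(annotations$interface[resolved]) / n,
    fraction_core = sum(annotations$hydrophobic_core[resolved]) / n,
    fraction_other = sum(annotations$category[resolved] == "other") / n
  )
}
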
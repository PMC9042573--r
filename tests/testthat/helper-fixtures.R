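# Shared fixture builders and independent oracles. Everything here is
# generated in code at test time; oracles are deliberately naive
# re-implementations kept independent of the package internals.

toy_region <- function() region_spec("toy", 10L, 19L, "LVIAMWYFST")

toy_records <- function(region = toy_region()) {
  as_substitution_records(data.frame(
    position = c(10L, 10L, 11L, 14L, 17L),
    wt_aa    = c("L", "L", "V", "M", "F"),
    mut_aa   = c("R", "K", "G", "E", "A"),
    hit_count = c(3L, 1L, 2L, 1L, 2L)
  ), region)
}

# ideal-ish alpha helix C-alpha trace along +z (100 deg/residue, 1.5 A rise)
helix_atoms <- function(n, chain = "A", start = 1L, resid = "ALA",
                        origin = c(0, 0, 0)) {
  t <- seq_len(n)
  data.frame(chain = chain, resno = start + t - 1L, resid = resid,
             elety = "CA", element = "C",
             x = origin[1] + 2.3 * cos(t * 100 * pi / 180),
             y = origin[2] + 2.3 * sin(t * 100 * pi / 180),
             z = origin[3] + 1.5 * t,
             stringsAsFactors = FALSE)
}

rotation_about <- function(axis, theta_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

transform_atoms <- function(atoms, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms[, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
  atoms
}

# fixed-width PDB writer for synthetic fixtures (independent of bio3d)
write_pdb_text <- function(atoms, path) {
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$element)) atoms$element <- substr(atoms$elety, 1, 1)
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    name <- if (nchar(a$elety) < 4) sprintf(" %-3s", a$elety) else a$elety
    sprintf("ATOM  %5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name, a$alt, a$resid, a$chain, a$resno, a$x, a$y, a$z,
            a$occ, 0, a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# minimal mmCIF atom_site writer with the same content
write_cif_text <- function(atoms, path) {
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$alt)) atoms$alt <- "."
  if (is.null(atoms$element)) atoms$element <- substr(atoms$elety, 1, 1)
  atoms$alt[atoms$alt == ""] <- "."
  header <- c(
    "data_synthetic", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
            i, a$element, a$elety, a$alt, a$resid, a$chain, a$resno,
            a$x, a$y, a$z, a$occ, a$resno, a$resid, a$chain, a$elety)
  }, character(1))
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}

# write a clustal-format file for given named sequences
# (header line must be followed by two blank lines)
write_clustal_text <- function(ids, seqs, path) {
  lines <- c("CLUSTAL W (1.83) multiple sequence alignment", "", "")
  width <- max(nchar(ids)) + 4
  for (i in seq_along(ids)) {
    lines <- c(lines, sprintf(paste0("%-", width, "s%s"), ids[i], seqs[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

# straight 40-residue helix with a hinge: residues hinge+1..40 of the bent
# copy are rigidly rotated by `angle` degrees about the x-axis through the
# hinge point
hinge_models <- function(angle, n = 40L, hinge = 20L) {
  a <- helix_atoms(n)
  b <- a
  pivot <- unlist(a[a$resno == hinge, c("x", "y", "z")])
  R <- rotation_about(c(1, 0, 0), angle)
  seg <- b$resno > hinge
  xyz <- as.matrix(b[seg, c("x", "y", "z")])
  b[seg, c("x", "y", "z")] <- sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, "+")
  list(a = structure_model(a), b = structure_model(b))
}

# --- independent oracles -------------------------------------------------

# naive per-column entropy over explicit frequencies
oracle_entropy <- function(symbols) {
  symbols <- symbols[symbols %in% supscreen::AA_ALPHABET]
  if (length(symbols) == 0) return(NA_real_)
  p <- as.numeric(table(symbols)) / length(symbols)
  -sum(p * log2(p))
}

# brute-force O(n^2) neighbour count for the burial proxy
oracle_burial <- function(atoms, chain, radius = 7.5) {
  backbone <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")
  ch <- atoms[atoms$chain == chain, ]
  res <- unique(ch$resno)
  vapply(res, function(r) {
    rows <- ch[ch$resno == r, ]
    sc <- rows[!(rows$elety %in% backbone), ]
    cen <- if (nrow(sc) > 0) {
      colMeans(sc[, c("x", "y", "z")])
    } else {
      unlist(rows[rows$elety == "CA", c("x", "y", "z")][1, ])
    }
    n <- 0L
    for (j in seq_len(nrow(atoms))) {
      if (atoms$chain[j] == chain && atoms$resno[j] == r) next
      d <- sqrt(sum((unlist(atoms[j, c("x", "y", "z")]) - cen)^2))
      if (d <= radius) n <- n + 1L
    }
    n
  }, integer(1))
}

# closed-form occupancy expectation for the multi-hit fraction:
# allele counts are Binomial(n, q_a) marginals, so
#   E[#seen>=1] = sum_a 1-(1-q_a)^n
#   E[#seen>=2] = sum_a 1-(1-q_a)^n - n q_a (1-q_a)^(n-1)
# and the expected fraction is approximated by the ratio of expectations.
oracle_occupancy_fraction <- function(q, n) {
  e1 <- sum(1 - (1 - q)^n)
  e2 <- sum(1 - (1 - q)^n - n * q * (1 - q)^(n - 1))
  e2 / e1
}

# codon multiplicity of each amino acid under the standard code
codon_multiplicity <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  vapply(aa, function(a) sum(code == a), numeric(1))
}
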
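#' Parse a residue selection string
#'
#' Selections are written `chain:start-end[,start-end...]`, e.g.
#' `"A:1-149,1150-1220"`; several chains may be combined with `;`.
#'
#' @param selection Selection string, or a data frame with columns `chain`,
#'   `start`, `end` (returned unchanged).
#' @return Data frame with columns `chain`, `start`, `end`.
#' @export
parse_selection <- function(selection) {
  if (is.data.frame(selection)) {
    stopifnot(all(c("chain", "start", "end") %in% names(selection)))
    return(selection)
  }
  parts <- strsplit(selection, ";", fixed = TRUE)[[1]]
  out <- do.call(rbind, lapply(parts, function(p) {
    p <- trimws(p)
    m <- regmatches(p, regexec("^([^:]+):(.+)$", p))[[1]]
    if (length(m) != 3L) stop(sprintf("cannot parse selection '%s'", p))
    ranges <- strsplit(m[3L], ",", fixed = TRUE)[[1]]
    do.call(rbind, lapply(ranges, function(r) {
      se <- as.integer(strsplit(trimws(r), "-", fixed = TRUE)[[1]])
      if (length(se) == 1L) se <- c(se, se)
      if (length(se) != 2L || anyNA(se) || se[2L] < se[1L]) {
        stop(sprintf("bad range '%s' in selection", r))
      }
      data.frame(chain = m[2L], start = se[1L], end = se[2L])
    }))
  }))
  rownames(out) <- NULL
  out
}

# C-alpha coordinates for a selection, named by chain|resno, ordered by
# chain then residue number
.ca_coords <- function(model, selection) {
  sel <- parse_selection(selection)
  at <- model$atoms
  keep <- rep(FALSE, nrow(at))
  for (i in seq_len(nrow(sel))) {
    keep <- keep | (at$chain == sel$chain[i] & at$elety == "CA" &
                      at$resno >= sel$start[i] & at$resno <= sel$end[i])
  }
  at <- at[keep, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno)), , drop = FALSE]
  at <- at[order(at$chain, at$resno), , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rownames(xyz) <- paste(at$chain, at$resno, sep = "|")
  xyz
}

# Kabsch: optimal rotation (det +1) and translation mapping y onto x
.kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  h <- crossprod(sweep(y, 2, cy), sweep(x, 2, cx))
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = rot, translation = as.numeric(cx - cy %*% t(rot)))
}

#' Rigid-body superposition of two models
#'
#' Least-squares (Kabsch) superposition of `model_b` onto `model_a` over
#' C-alpha atoms paired by chain and author residue number within
#' `selection`. The proper-rotation branch is enforced (determinant +1), so
#' no reflection can be returned.
#'
#' @param model_a,model_b [structure_model()] objects.
#' @param selection Selection (see [parse_selection()]) naming the atoms to
#'   fit on; at least 3 residue pairs must be present in both models.
#' @return List of class `superposition`: `rotation` (3x3), `translation`
#'   (length 3; the fitted map is `x_b %*% t(rotation) + translation`),
#'   `rmsd` (Angstrom, over the selection after fitting), `n_atoms`.
#' @export
superpose <- function(model_a, model_b, selection) {
  xa <- .ca_coords(model_a, selection)
  xb <- .ca_coords(model_b, selection)
  common <- intersect(rownames(xa), rownames(xb))
  if (length(common) < 3L) {
    stop(sprintf("only %d paired C-alpha atoms in selection; need >= 3",
                 length(common)))
  }
  xa <- xa[common, , drop = FALSE]
  xb <- xb[common, , drop = FALSE]
  fit <- .kabsch(xa, xb)
  moved <- xb %*% t(fit$rotation) +
    matrix(fit$translation, nrow(xb), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - xa)^2)))
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = rmsd, n_atoms = length(common)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d C-alpha pairs, RMSD %.3f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to a model
#'
#' @param model A [structure_model()].
#' @param fit A [superpose()] result (or list with `rotation`,
#'   `translation`).
#' @return The transformed [structure_model()].
#' @export
apply_transform <- function(model, fit) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  moved <- xyz %*% t(fit$rotation) +
    matrix(fit$translation, nrow(xyz), 3, byrow = TRUE)
  out <- model$atoms
  out[, c("x", "y", "z")] <- moved
  structure_model(out)
}

# dominant principal direction of a C-alpha trace, oriented N -> C
.segment_axis <- function(xyz) {
  if (nrow(xyz) < 4L) stop("segment has fewer than 4 residues; axis unstable")
  centred <- sweep(xyz, 2, colMeans(xyz))
  v <- svd(centred)$v[, 1L]
  nc <- xyz[nrow(xyz), ] - xyz[1L, ]
  if (sum(v * nc) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Rotation angle of a segment between two conformations
#'
#' Measures how far a structural segment (e.g. the coiled coil emerging from
#' an ATPase head) has pivoted between two conformational states. `model_b`
#' is first superposed onto `model_a` over `align_selection` (the common
#' frame, e.g. the head domain); the segment axis is then computed in each
#' model as the dominant principal direction of the segment's C-alpha trace,
#' oriented N to C, and the angle between the two axes is returned in
#' degrees, in \[0, 180\].
#'
#' @param model_a,model_b [structure_model()] objects for the two states.
#' @param align_selection Selection defining the shared reference frame.
#' @param segment_selection Selection for the pivoting segment (>= 4
#'   residues in each model).
#' @return Angle in degrees.
#' @export
segment_rotation_angle <- function(model_a, model_b, align_selection,
                                   segment_selection) {
  fit <- superpose(model_a, model_b, align_selection)
  moved_b <- apply_transform(model_b, fit)
  axis_a <- .segment_axis(.ca_coords(model_a, segment_selection))
  axis_b <- .segment_axis(.ca_coords(moved_b, segment_selection))
  acos(max(-1, min(1, sum(axis_a * axis_b)))) * 180 / pi
}
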
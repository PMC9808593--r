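#' @title Backbone and glycosidic torsion angles
#' @description Dihedral geometry for nucleic-acid backbones: the six
#'   backbone torsions alpha--zeta along P-O5'-C5'-C4'-C3'-O3'-P and the
#'   glycosidic angle chi about the base--sugar bond. All angles are reported
#'   in degrees on `[0, 360)`; the convention is IUPAC-signed (cis = 0,
#'   trans = 180) before wrapping, which is the convention the handedness
#'   thresholds (252, 300, 325 degrees) live on.
#' @name torsion
NULL

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Wrap an angle to [0, 360)
#'
#' @param x numeric vector of angles in degrees; must be finite.
#' @return `x` reduced modulo 360 into `[0, 360)`.
#' @examples
#' wrap_angle(-60)    # 300
#' wrap_angle(725.5)  # 5.5
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("wrap_angle() requires finite numeric input", call. = FALSE)
  }
  x %% 360
}

#' Torsion angle of four points
#'
#' Signed dihedral of the quadruple `p1-p2-p3-p4` about the `p2-p3` bond,
#' computed with the atan2 triple-product formula and wrapped to `[0, 360)`.
#' Eclipsed (cis) geometry gives 0, anti-periplanar (trans) gives 180.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstroms.
#' @param tol collinearity tolerance on the cross-product norms.
#' @return angle in degrees, in `[0, 360)`.
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))   # 0
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180
#' @export
dihedral <- function(p1, p2, p3, p4, tol = 1e-8) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < tol || sqrt(sum(n2^2)) < tol || sqrt(sum(b2^2)) < tol) {
    stop("degenerate geometry: collinear atom triplet in dihedral()", call. = FALSE)
  }
  u2 <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * u2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

# atom quadruples per angle; prev/next refer to the covalently linked
# neighbours (alpha/beta need the 5' phosphate linkage, epsilon/zeta the 3')
.torsion_quadruples <- list(
  alpha   = list(c("prev", "O3'"), c("self", "P"),   c("self", "O5'"), c("self", "C5'")),
  beta    = list(c("self", "P"),   c("self", "O5'"), c("self", "C5'"), c("self", "C4'")),
  gamma   = list(c("self", "O5'"), c("self", "C5'"), c("self", "C4'"), c("self", "C3'")),
  delta   = list(c("self", "C5'"), c("self", "C4'"), c("self", "C3'"), c("self", "O3'")),
  epsilon = list(c("self", "C4'"), c("self", "C3'"), c("self", "O3'"), c("next", "P")),
  zeta    = list(c("self", "C3'"), c("self", "O3'"), c("next", "P"),   c("next", "O5'"))
)

.purine_bases <- c("A", "G")

chi_quadruple <- function(base) {
  if (base %in% .purine_bases) {
    list(c("self", "O4'"), c("self", "C1'"), c("self", "N9"), c("self", "C4"))
  } else {
    list(c("self", "O4'"), c("self", "C1'"), c("self", "N1"), c("self", "C2"))
  }
}

lookup_atom <- function(unit, prev, nxt, where, name) {
  u <- switch(where, self = unit, prev = prev, `next` = nxt)
  if (is.null(u)) return(NULL)
  pos <- u$atoms[[name]]
  if (is.null(pos)) NULL else pos
}

#' Compute the seven torsion angles of one nucleotide
#'
#' Angles whose atoms are absent (5'-terminal units lack the alpha/beta
#' quadruple, 3'-terminal units lack epsilon/zeta, incomplete residues may
#' lack more) are returned as `NA`, never silently as zero.
#'
#' @param unit a `NucleotideUnit` as produced by [extract_nucleotides()].
#' @param prev,nxt the covalently linked neighbours, or `NULL`. Defaults to
#'   the links stored on `unit`.
#' @return named numeric vector `alpha ... chi`, degrees in `[0,360)` or `NA`.
#' @seealso [compute_profiles()] for whole structures.
#' @export
compute_profile <- function(unit, prev = unit[["prev"]], nxt = unit[["nxt"]]) {
  quads <- .torsion_quadruples
  quads$chi <- chi_quadruple(unit$base)
  # alpha and beta are only defined through the 5' phosphate linkage: a
  # terminal residue's free phosphate (when present at all) is not part of a
  # backbone step, so both are reported missing without a prev link
  if (is.null(prev)) quads$beta <- NULL
  out <- stats::setNames(rep(NA_real_, length(ANGLE_NAMES)), ANGLE_NAMES)
  for (ang in names(quads)) {
    pts <- lapply(quads[[ang]], function(q) lookup_atom(unit, prev, nxt, q[1L], q[2L]))
    if (!any(vapply(pts, is.null, logical(1L)))) {
      out[ang] <- dihedral(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]])
    }
  }
  out
}

#' Torsion profiles for a list of nucleotide units
#'
#' @param units list of `NucleotideUnit`s (see [extract_nucleotides()]);
#'   labelled units (after [apply_manifest()]) carry their structural class
#'   and label through.
#' @param pdb_id structure identifier recorded in the `pdb_id` column.
#' @return data frame with one row per unit: `pdb_id`, `chain`, `resseq`,
#'   `base`, `class`, `label`, then the seven angle columns (`NA` = missing).
#' @export
compute_profiles <- function(units, pdb_id = NA_character_) {
  rows <- lapply(units, function(u) {
    ang <- compute_profile(u)
    cbind(
      data.frame(
        pdb_id = pdb_id, chain = u$chain_id, resseq = u$resseq, base = u$base,
        class = if (is.null(u$structural_class)) NA_character_ else u$structural_class,
        label = if (is.null(u$label)) NA_integer_ else u$label,
        stringsAsFactors = FALSE
      ),
      as.data.frame(as.list(ang))
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
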
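#' @title Synthetic torsion profiles and geometric fixtures
#' @description Generates labelled torsion-angle datasets whose
#'   class-conditional distributions emulate the curated structure families
#'   (left-handed and right-handed parallel quadruplexes, Z-DNA, B-DNA), and
#'   builds small geometrically exact PDB fixtures from internal coordinates
#'   so the whole coordinate-to-classifier pipeline is testable offline.
#'   Angles are drawn from wrapped-normal mixtures; the shipped defaults put
#'   left-handed quadruplex guanosine alpha at 180 (sd 12.5, ~95% of mass in
#'   150--200 degrees), right-handed quadruplex alpha at 300 (sd 18), a
#'   bimodal epsilon/zeta split tied to first- vs second-in-tract guanosines,
#'   Z-DNA syn/anti alternation (guanosine chi ~60, cytidine chi ~240,
#'   cytidine alpha ~180), and a broad B-DNA alpha around 300 (sd 25).
#' @name synthetic
NULL

#' Default synthetic distribution spec
#'
#' Reads the wrapped-normal mixture parameters shipped at
#' `inst/extdata/torsion_spec.yaml`: one entry per structural class
#' (`LHG4`, `RHG4`, `ZDNA`, `BDNA`) with its handedness label, default
#' sample count (the curated-set sizes 125/88/76/175) and per-subpopulation
#' angle components. The file is plain YAML and meant to be edited.
#'
#' @param path alternative spec file (YAML).
#' @return a validated `synthetic_spec` list.
#' @export
default_torsion_spec <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "torsion_spec.yaml", package = "g4hand",
                        mustWork = TRUE)
  }
  validate_spec(yaml::read_yaml(path))
}

#' Validate a synthetic spec
#'
#' Checks the structural invariants: subpopulation weights sum to one, all
#' sds are positive, all means lie in `[0, 360)`, and labels agree with the
#' handedness of the class.
#'
#' @param spec a spec list (as from [default_torsion_spec()]).
#' @return the spec, invisibly classed `synthetic_spec`; errors otherwise.
#' @export
validate_spec <- function(spec) {
  stopifnot(is.list(spec$classes), length(spec$classes) > 0L)
  for (cls in names(spec$classes)) {
    e <- spec$classes[[cls]]
    expected <- if (cls %in% c("LHG4", "ZDNA")) 0L else 1L
    if (!identical(as.integer(e$label), expected)) {
      stop("spec: label of ", cls, " must be ", expected, call. = FALSE)
    }
    if (!is.numeric(e$count) || e$count < 0) {
      stop("spec: bad count for ", cls, call. = FALSE)
    }
    w <- vapply(e$subpopulations, function(s) s$weight, numeric(1L))
    if (abs(sum(w) - 1) > 1e-9) {
      stop("spec: subpopulation weights of ", cls, " must sum to 1", call. = FALSE)
    }
    for (s in e$subpopulations) {
      if (!setequal(names(s$angles), ANGLE_NAMES)) {
        stop("spec: ", cls, "/", s$name, " must parameterize all 7 angles",
             call. = FALSE)
      }
      for (a in s$angles) {
        if (a$sd <= 0 || a$mean < 0 || a$mean >= 360) {
          stop("spec: means must be in [0,360) and sds positive (", cls, ")",
               call. = FALSE)
        }
      }
    }
  }
  invisible(structure(spec, class = c("synthetic_spec", "list")))
}

#' Draw a labelled synthetic dataset
#'
#' Each sample independently draws every angle from its subpopulation's
#' wrapped normal (a normal draw reduced modulo 360). Classes with several
#' subpopulations (the two tract positions of a left-handed quadruplex, the
#' syn-guanosine / anti-cytidine halves of a Z-DNA step) assign samples to
#' subpopulations in strict alternation, mirroring the repeating structure
#' they stand for.
#'
#' @param spec a `synthetic_spec`.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param n_per_class optional named vector overriding the per-class counts
#'   in the spec (e.g. `c(LHG4 = 200, RHG4 = 200)`); classes absent from the
#'   override keep their spec count, classes set to 0 are omitted.
#' @param classes which classes to generate (default: all in the spec).
#' @return a `torsion_dataset`; left-handed quadruplex rows carry a
#'   `tract_position` column (1 or 2), never used as a classifier feature.
#' @export
sample_dataset <- function(spec, seed, n_per_class = NULL,
                           classes = names(spec$classes)) {
  spec <- validate_spec(spec)
  rows <- with_seed(seed, {
    out <- list()
    for (cls in classes) {
      e <- spec$classes[[cls]]
      n <- if (!is.null(n_per_class) && cls %in% names(n_per_class)) {
        n_per_class[[cls]]
      } else {
        e$count
      }
      if (n < 0) stop("negative sample count for ", cls, call. = FALSE)
      if (n == 0) next
      nsub <- length(e$subpopulations)
      sub_idx <- rep_len(seq_len(nsub), n)
      df <- data.frame(
        pdb_id = paste0("SYN_", cls), chain = "A",
        resseq = as.character(seq_len(n)),
        base = NA_character_, class = cls, label = as.integer(e$label),
        stringsAsFactors = FALSE
      )
      for (ang in ANGLE_NAMES) df[[ang]] <- NA_real_
      df$tract_position <- NA_integer_
      for (si in seq_len(nsub)) {
        s <- e$subpopulations[[si]]
        pick <- sub_idx == si
        m <- sum(pick)
        if (!m) next
        bases <- unlist(s$base)
        df$base[pick] <- if (length(bases) == 1L) bases else
          sample(bases, m, replace = TRUE)
        if (!is.null(s$tract_position)) {
          df$tract_position[pick] <- as.integer(s$tract_position)
        }
        for (ang in ANGLE_NAMES) {
          a <- s$angles[[ang]]
          df[[ang]][pick] <- wrap_angle(stats::rnorm(m, a$mean, a$sd))
        }
      }
      out[[cls]] <- df
    }
    out
  })
  if (!length(rows)) stop("no samples requested", call. = FALSE)
  suppressMessages(build_dataset(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                                 name = paste(classes, collapse = "+")))
}

# ---- geometric fixture builder -------------------------------------------

# place atom D given anchors A-B-C, a bond length C-D, the B-C-D bond angle
# and the A-B-C-D torsion (degrees), consistent with dihedral()
nerf_place <- function(A, B, C, bond, angle_deg, torsion_deg) {
  theta <- angle_deg * pi / 180
  phi <- torsion_deg * pi / 180
  u <- C - B; u <- u / sqrt(sum(u^2))
  w <- (A - B) - sum((A - B) * u) * u        # in-plane direction toward A
  if (sqrt(sum(w^2)) < 1e-10) stop("collinear anchors in nerf_place()", call. = FALSE)
  p <- w / sqrt(sum(w^2))
  q <- cross3(u, p)                          # completes right-handed frame
  C + bond * (-cos(theta) * u + sin(theta) * (cos(phi) * p + sin(phi) * q))
}

.fixture_defaults <- list(
  "idealized-duplex" = c(alpha = 300, beta = 175, gamma = 55, delta = 130,
                         epsilon = 190, zeta = 265, chi = 250),
  "idealized-quadruplex-column" = c(alpha = 180, beta = 190, gamma = 55,
                                    delta = 135, epsilon = 195, zeta = 60,
                                    chi = 250)
)

.fixture_bonds <- c(`P-O5'` = 1.60, `O5'-C5'` = 1.44, `C5'-C4'` = 1.51,
                    `C4'-C3'` = 1.52, `C3'-O3'` = 1.42, `O3'-P` = 1.61)

#' Build an idealized PDB fixture from backbone torsions
#'
#' Constructs a single covalently linked guanosine chain atom-by-atom from
#' internal coordinates (fixed bond lengths and bond angles, caller-chosen
#' torsions), so every generated torsion is known exactly and
#' [compute_profile()] can be validated against ground truth. The
#' `idealized-duplex` kind uses canonical right-handed backbone torsions,
#' `idealized-quadruplex-column` left-handed ones.
#'
#' @param kind `"idealized-duplex"` or `"idealized-quadruplex-column"`.
#' @param n_residues number of residues (>= 2).
#' @param torsions optional data frame (`n_residues` rows, any subset of the
#'   seven angle columns) overriding the kind's default torsions; `NA`
#'   entries keep the default.
#' @param chain chain identifier written to the records.
#' @return a `fixture_structure` list: `atoms` (layout of
#'   [read_structure()]), `pdb` (PDB text lines), and `torsions`, the
#'   generating torsion table (angles a terminal residue cannot realize are
#'   `NA`).
#' @export
make_fixture_structure <- function(kind = c("idealized-duplex",
                                            "idealized-quadruplex-column"),
                                   n_residues, torsions = NULL, chain = "A") {
  kind <- match.arg(kind)
  if (n_residues < 2L) stop("fixture needs at least 2 residues", call. = FALSE)
  tor <- as.data.frame(matrix(rep(.fixture_defaults[[kind]], each = n_residues),
                              nrow = n_residues,
                              dimnames = list(NULL, ANGLE_NAMES)))
  if (!is.null(torsions)) {
    torsions <- as.data.frame(torsions)
    stopifnot(nrow(torsions) == n_residues)
    for (ang in intersect(names(torsions), ANGLE_NAMES)) {
      ok <- !is.na(torsions[[ang]])
      tor[[ang]][ok] <- torsions[[ang]][ok]
    }
  }
  b <- .fixture_bonds
  atoms <- list()
  add <- function(resno, name, pos) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, residue_name = "DG", chain_id = chain,
      resno = resno, insert = "", x = pos[1L], y = pos[2L], z = pos[3L],
      occupancy = 1, altloc = "", record = "ATOM",
      residue_seq = as.character(resno), stringsAsFactors = FALSE
    )
    pos
  }
  sugar_and_base <- function(resno, P, O5, C5, C4, g, chi) {
    C3 <- add(resno, "C3'", nerf_place(O5, C5, C4, b[["C4'-C3'"]], 116, g))
    O4 <- add(resno, "O4'", nerf_place(O5, C5, C4, 1.45, 109, wrap_angle(g - 121)))
    O3 <- add(resno, "O3'", nerf_place(C5, C4, C3, b[["C3'-O3'"]], 110,
                                       tor$delta[resno]))
    C1 <- add(resno, "C1'", nerf_place(C5, C4, O4, 1.42, 110, 215))
    N9 <- add(resno, "N9", nerf_place(C4, O4, C1, 1.47, 108, 240))
    add(resno, "C4", nerf_place(O4, C1, N9, 1.37, 127, chi))
    list(C4 = C4, C3 = C3, O3 = O3)
  }
  # residue 1: seed frame by hand (its alpha has no upstream anchor)
  P <- add(1L, "P", c(0, 0, 0))
  O5 <- add(1L, "O5'", c(b[["P-O5'"]], 0, 0))
  C5 <- add(1L, "C5'", O5 + b[["O5'-C5'"]] * c(cos(pi / 3), sin(pi / 3), 0))
  C4 <- add(1L, "C4'", nerf_place(P, O5, C5, b[["C5'-C4'"]], 111, tor$beta[1L]))
  anchors <- sugar_and_base(1L, P, O5, C5, C4, tor$gamma[1L], tor$chi[1L])
  for (i in 2L:n_residues) {
    prevC4 <- C4; prevC3 <- anchors$C3; prevO3 <- anchors$O3
    P <- add(i, "P", nerf_place(prevC4, prevC3, prevO3, b[["O3'-P"]], 119,
                                tor$epsilon[i - 1L]))
    O5 <- add(i, "O5'", nerf_place(prevC3, prevO3, P, b[["P-O5'"]], 104,
                                   tor$zeta[i - 1L]))
    C5 <- add(i, "C5'", nerf_place(prevO3, P, O5, b[["O5'-C5'"]], 120,
                                   tor$alpha[i]))
    C4 <- add(i, "C4'", nerf_place(P, O5, C5, b[["C5'-C4'"]], 111, tor$beta[i]))
    anchors <- sugar_and_base(i, P, O5, C5, C4, tor$gamma[i], tor$chi[i])
  }
  atom_df <- do.call(rbind, c(atoms, list(make.row.names = FALSE)))
  # the generating-torsion table only claims angles an interior linkage realizes
  tor$alpha[1L] <- tor$beta[1L] <- NA
  tor$epsilon[n_residues] <- tor$zeta[n_residues] <- NA
  tor <- cbind(data.frame(residue = seq_len(n_residues)), tor)
  structure(list(atoms = atom_df, pdb = write_structure(atom_df),
                 torsions = tor, kind = kind),
            class = "fixture_structure")
}
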
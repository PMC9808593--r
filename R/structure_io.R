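#' @title PDB structure input and residue selection
#' @description Reads PDB-format coordinate files into atom records, groups
#'   them into covalently linked nucleotide units, and applies the shipped
#'   (user-editable) per-structure residue selections that define which
#'   nucleotides enter the handedness data set.
#' @name structure_io
NULL

# parent-base map for the modified residues appearing in the curated
# structure set (bromo-cytosine, inosine, 2-aminoadenine) plus standards
.base_parent <- c(
  DA = "A", A = "A", ADE = "A", DG = "G", G = "G", GUA = "G",
  DC = "C", C = "C", CYT = "C", DT = "T", T = "T", THY = "T",
  DU = "U", U = "U", URA = "U",
  CBR = "C", BRC = "C", `5CM` = "C", `5BU` = "U",
  DI = "G", I = "G", `2DA` = "A", `6MA` = "A", MA7 = "A", FDA = "A", AF2 = "A"
)

parent_base <- function(resid, atom_names = character()) {
  b <- unname(.base_parent[toupper(resid)])
  if (!is.na(b) && length(b)) return(b)
  # unknown residue code: fall back on ring nitrogens to pick the chi quadruple
  if ("N9" %in% atom_names) "G" else "C"
}

#' Read a PDB file into atom records
#'
#' Parses ATOM and HETATM records (bio3d does the column work), keeps the
#' requested model of multi-model files, and resolves alternate locations by
#' keeping the highest-occupancy record (ties go to altloc `'A'`, then file
#' order).
#'
#' @param path path to a PDB-format file.
#' @param model_index 1-based model to keep; multi-model NMR ensembles
#'   contribute only this model.
#' @return data frame of atom records: `name`, `residue_name`, `chain_id`,
#'   `residue_seq` (number + insertion code), `resno`, `insert`, `x`, `y`,
#'   `z`, `occupancy`, `altloc`, `record`.
#' @export
read_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) {
    stop("cannot read structure file: ", path, call. = FALSE)
  }
  pdb <- try(suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                              verbose = FALSE)), silent = TRUE)
  if (inherits(pdb, "try-error") || is.null(pdb$atom) || nrow(pdb$atom) == 0L) {
    stop("no coordinate records found in ", path, call. = FALSE)
  }
  n_models <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > n_models) {
    stop("model_index ", model_index, " out of range; file has ", n_models,
         " model(s)", call. = FALSE)
  }
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
  at <- pdb$atom
  atoms <- data.frame(
    name = at$elety,
    residue_name = at$resid,
    chain_id = ifelse(is.na(at$chain) | at$chain == "", " ", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    record = at$type,
    stringsAsFactors = FALSE
  )
  atoms$residue_seq <- paste0(atoms$resno, atoms$insert)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  resolve_altloc(atoms)
}

# keep, within each (chain, residue, atom name) group, the highest-occupancy
# altloc; ties prefer altloc 'A', then blank, then file order
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$residue_seq, atoms$name, sep = "\r")
  ord <- order(key,
               -atoms$occupancy,
               atoms$altloc != "A",
               atoms$altloc,
               seq_len(nrow(atoms)))
  keep <- ord[!duplicated(key[ord])]
  out <- atoms[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write atom records back to PDB text
#'
#' Fixed-column (wwPDB v3.3) ATOM/HETATM formatter; coordinates to three
#' decimals. Used for fixtures and round-trip checks.
#'
#' @param atoms data frame in the layout of [read_structure()].
#' @param path optional output file; when `NULL` the lines are returned.
#' @return invisibly (or visibly when `path` is `NULL`) the PDB lines.
#' @export
write_structure <- function(atoms, path = NULL) {
  element <- sub("'.*$", "", substr(trimws(atoms$name), 1L, 1L))
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$record,
    seq_len(nrow(atoms)),
    formatC(atoms$name, width = 4, flag = "-"),
    substr(paste0(atoms$altloc, " "), 1L, 1L),
    atoms$residue_name,
    atoms$chain_id,
    atoms$resno,
    substr(paste0(atoms$insert, " "), 1L, 1L),
    atoms$x, atoms$y, atoms$z,
    atoms$occupancy, 0,
    element
  )
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Group atom records into linked nucleotide units
#'
#' A residue qualifies as a nucleotide when it carries at least the sugar
#' atoms C1', O4' and C4'. Covalent 5'/3' connectivity is established purely
#' geometrically — an O3'--P contact under 2 Angstroms — never from residue
#' numbering, and units are returned sorted 5' to 3' along each linked chain.
#'
#' @param atoms atom records from [read_structure()].
#' @param link_cutoff maximum O3'--P distance (Angstroms) treated as a bond.
#' @return list of `NucleotideUnit`s: each has `chain_id`, `resno`, `insert`,
#'   `resseq`, `residue_name`, `base` (parent base for modified residues),
#'   `atoms` (named list of 3-vectors), neighbour stubs `prev`/`nxt` holding
#'   the linked neighbour's relevant atoms, and `prev_index`/`next_index`.
#'   Residues skipped for missing sugar atoms are reported via a message and
#'   the `"excluded"` attribute.
#' @export
extract_nucleotides <- function(atoms, link_cutoff = 2.0) {
  key <- paste(atoms$chain_id, atoms$residue_seq, sep = "\r")
  groups <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  units <- list()
  excluded <- character()
  for (idx in groups) {
    sub <- atoms[idx, , drop = FALSE]
    pos <- lapply(seq_len(nrow(sub)), function(i) c(sub$x[i], sub$y[i], sub$z[i]))
    names(pos) <- trimws(sub$name)
    if (!all(c("C1'", "O4'", "C4'") %in% names(pos))) {
      excluded <- c(excluded,
                    paste0(sub$chain_id[1L], "/", sub$residue_seq[1L], " (",
                           sub$residue_name[1L], ")"))
      next
    }
    units[[length(units) + 1L]] <- list(
      chain_id = sub$chain_id[1L],
      resno = sub$resno[1L],
      insert = sub$insert[1L],
      resseq = sub$residue_seq[1L],
      residue_name = sub$residue_name[1L],
      base = parent_base(sub$residue_name[1L], names(pos)),
      atoms = pos,
      prev = NULL, nxt = NULL,
      prev_index = NA_integer_, next_index = NA_integer_
    )
  }
  if (length(excluded)) {
    message("extract_nucleotides: excluded ", length(excluded),
            " non-nucleotide residue(s): ", paste(excluded, collapse = ", "))
  }
  units <- link_units(units, link_cutoff)
  attr(units, "excluded") <- excluded
  units
}

link_units <- function(units, link_cutoff) {
  n <- length(units)
  if (n == 0L) return(units)
  nxt_of <- rep(NA_integer_, n)
  prev_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    o3 <- units[[i]]$atoms[["O3'"]]
    if (is.null(o3)) next
    hits <- integer()
    for (j in seq_len(n)) {
      if (j == i) next
      p <- units[[j]]$atoms[["P"]]
      if (is.null(p)) next
      if (sqrt(sum((o3 - p)^2)) < link_cutoff) hits <- c(hits, j)
    }
    if (length(hits) > 1L) {
      stop("branching connectivity: O3' of ", units[[i]]$chain_id, "/",
           units[[i]]$resseq, " bonds ", length(hits), " phosphates (",
           paste(vapply(units[hits], function(u) paste0(u$chain_id, "/", u$resseq),
                        character(1L)), collapse = ", "), ")", call. = FALSE)
    }
    if (length(hits) == 1L) {
      j <- hits
      if (!is.na(prev_of[j])) {
        stop("branching connectivity: P of ", units[[j]]$chain_id, "/",
             units[[j]]$resseq, " bonds two O3' atoms", call. = FALSE)
      }
      nxt_of[i] <- j
      prev_of[j] <- i
    }
  }
  # order 5'->3' following the links, chain by chain
  order_out <- integer()
  visited <- rep(FALSE, n)
  heads <- which(is.na(prev_of))
  for (h in heads) {
    k <- h
    while (!is.na(k) && !visited[k]) {
      visited[k] <- TRUE
      order_out <- c(order_out, k)
      k <- nxt_of[k]
    }
  }
  order_out <- c(order_out, which(!visited))  # cyclic leftovers, if any
  remap <- match(seq_len(n), order_out)
  out <- vector("list", n)
  for (new_i in seq_len(n)) {
    old <- order_out[new_i]
    u <- units[[old]]
    pi <- prev_of[old]; ni <- nxt_of[old]
    u$prev_index <- if (is.na(pi)) NA_integer_ else remap[pi]
    u$next_index <- if (is.na(ni)) NA_integer_ else remap[ni]
    # lightweight neighbour stubs carrying just the atoms torsions reach into
    u$prev <- if (!is.na(pi)) list(atoms = units[[pi]]$atoms["O3'"]) else NULL
    u$nxt <- if (!is.na(ni)) list(atoms = units[[ni]]$atoms[c("P", "O5'")]) else NULL
    out[[new_i]] <- u
  }
  out
}

#' Read a structure-selection manifest
#'
#' The manifest mirrors the curated structure table: one entry per structure
#' component with its structural class (`LHG4`, `RHG4`, `ZDNA`, `BDNA`), the
#' implied handedness label (0 for the left-handed classes, 1 otherwise) and
#' either an explicit `chain:resseq` residue list (tetrad guanines of the G4
#' entries) or the keyword `all-complete` (duplex entries; completeness
#' filtering happens downstream in [build_dataset()]). The copy shipped at
#' `system.file("extdata", "table1_manifest.yaml", package = "g4hand")` is a
#' reconstruction from the published sequences and is meant to be edited.
#'
#' @param path YAML (or JSON) manifest file.
#' @return list of manifest entries with elements `pdb_id`,
#'   `structural_class`, `label`, `residues` (`"all-complete"` or a data
#'   frame `chain`/`resseq`).
#' @export
read_manifest <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- lapply(raw, function(e) {
    cls <- e$structural_class
    if (!cls %in% c("LHG4", "RHG4", "ZDNA", "BDNA")) {
      stop("manifest: unknown structural_class '", cls, "'", call. = FALSE)
    }
    label <- if (cls %in% c("LHG4", "ZDNA")) 0L else 1L
    if (!is.null(e$label) && as.integer(e$label) != label) {
      stop("manifest: label for ", e$pdb_id, " contradicts its class", call. = FALSE)
    }
    res <- e$residues
    if (!identical(res, "all-complete")) {
      parts <- strsplit(unlist(res), ":", fixed = TRUE)
      res <- data.frame(
        chain = vapply(parts, `[`, character(1L), 1L),
        resseq = vapply(parts, `[`, character(1L), 2L),
        stringsAsFactors = FALSE
      )
    }
    list(pdb_id = e$pdb_id, structural_class = cls, label = label, residues = res)
  })
  names(entries) <- vapply(entries, function(e) e$pdb_id, character(1L))
  entries
}

#' Apply a manifest selection to extracted nucleotides
#'
#' @param units nucleotide units from [extract_nucleotides()].
#' @param manifest manifest list from [read_manifest()], or a single entry.
#' @param pdb_id which manifest entry (or entries — a structure split into
#'   left- and right-handed components has several) to apply.
#' @return the selected units, each annotated with `structural_class` and
#'   `label`. An explicitly listed residue absent from the structure is an
#'   error.
#' @export
apply_manifest <- function(units, manifest, pdb_id) {
  entries <- manifest[vapply(manifest, function(e) identical(e$pdb_id, pdb_id), logical(1L))]
  if (!length(entries)) {
    stop("no manifest entry for structure '", pdb_id, "'", call. = FALSE)
  }
  keys <- vapply(units, function(u) paste(u$chain_id, u$resseq, sep = ":"), character(1L))
  out <- list()
  for (e in entries) {
    if (identical(e$residues, "all-complete")) {
      idx <- seq_along(units)
    } else {
      want <- paste(e$residues$chain, e$residues$resseq, sep = ":")
      idx <- match(want, keys)
      if (anyNA(idx)) {
        stop("manifest mismatch for ", pdb_id, ": residue(s) ",
             paste(want[is.na(idx)], collapse = ", "),
             " not present in the structure", call. = FALSE)
      }
    }
    for (i in idx) {
      u <- units[[i]]
      u$structural_class <- e$structural_class
      u$label <- e$label
      out[[length(out) + 1L]] <- u
    }
  }
  out
}
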
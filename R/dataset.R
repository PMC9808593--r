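#' @title Labelled torsion feature tables
#' @description Turns per-nucleotide torsion profiles into the labelled
#'   feature table the classifiers train on: seven angle columns, a
#'   handedness label (0 = left, 1 = right) and provenance. Profiles with any
#'   missing angle are dropped — in real structures that removes the chain
#'   termini, whose alpha/beta or epsilon/zeta quadruples do not exist.
#' @name dataset
NULL

.dataset_header <- c("pdb_id", "chain", "resseq", "base", "class", "label", ANGLE_NAMES)

.class_label <- c(LHG4 = 0L, ZDNA = 0L, RHG4 = 1L, BDNA = 1L)

#' Assemble a labelled dataset from torsion profiles
#'
#' @param profiles data frame of profiles ([compute_profiles()] layout, or
#'   the synthetic generator's output). Labels are derived from the
#'   structural class when the `label` column is absent or `NA`.
#' @param name short dataset name (e.g. `"G4"`, `"DH"`).
#' @return a `torsion_dataset`: the complete-case feature table with fixed
#'   column order; excluded rows (any missing angle) are logged via a message
#'   and kept in the `"excluded"` attribute with the missing angles named.
#' @export
build_dataset <- function(profiles, name = "dataset") {
  stopifnot(is.data.frame(profiles))
  miss <- is.na(profiles[, ANGLE_NAMES, drop = FALSE])
  keep <- rowSums(miss) == 0L
  excluded <- character()
  if (any(!keep)) {
    excluded <- vapply(which(!keep), function(i) {
      paste0(profiles$pdb_id[i], " ", profiles$chain[i], "/", profiles$resseq[i],
             ": missing ", paste(ANGLE_NAMES[miss[i, ]], collapse = ","))
    }, character(1L))
    message("build_dataset: dropped ", sum(!keep),
            " incomplete profile(s):\n  ", paste(excluded, collapse = "\n  "))
  }
  ds <- profiles[keep, , drop = FALSE]
  if (nrow(ds) == 0L) {
    stop("no complete torsion profiles survive; dataset is empty", call. = FALSE)
  }
  if (!"label" %in% names(ds) || anyNA(ds$label)) {
    ds$label <- unname(.class_label[ds$class])
  }
  if (anyNA(ds$label) || !all(ds$label %in% c(0L, 1L))) {
    stop("labels must be 0 (LH) or 1 (RH); check structural classes", call. = FALSE)
  }
  if (any(ds[, ANGLE_NAMES] < 0 | ds[, ANGLE_NAMES] >= 360)) {
    stop("all angles must lie in [0, 360)", call. = FALSE)
  }
  extra <- setdiff(names(ds), .dataset_header)
  ds <- ds[, c(.dataset_header, extra), drop = FALSE]
  rownames(ds) <- NULL
  structure(ds,
            name = name,
            excluded = excluded,
            class = c("torsion_dataset", "data.frame"))
}

#' @export
print.torsion_dataset <- function(x, ...) {
  cat("<torsion_dataset '", attr(x, "name"), "': ", nrow(x), " samples, ",
      sum(x$label == 0L), " LH / ", sum(x$label == 1L), " RH>\n", sep = "")
  print(as.data.frame(utils::head(x, 6L)))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Percentage of a class in a dataset
#'
#' The majority-class percentage is the accuracy baseline any classifier must
#' beat (58.6% for a 125 LH / 88 RH table).
#'
#' @param ds a `torsion_dataset` (or any data frame with a `label` column).
#' @param label class label, 0 or 1.
#' @return percentage, `100 * count(label) / total`.
#' @export
class_proportion <- function(ds, label) {
  if (!is.data.frame(ds) || nrow(ds) == 0L) {
    stop("class_proportion() needs a nonempty dataset", call. = FALSE)
  }
  100 * sum(ds$label == label) / nrow(ds)
}

#' Per-class, per-angle histograms
#'
#' @param ds a `torsion_dataset`.
#' @param bin_width bin width in degrees; must divide 360.
#' @return long data frame `class`, `angle`, `bin_lo`, `bin_hi`, `count`;
#'   per class and angle the counts sum to the class size.
#' @export
angle_histograms <- function(ds, bin_width = 10) {
  if (!is.numeric(bin_width) || bin_width <= 0 || (360 %% bin_width) != 0) {
    stop("bin_width must be a positive divisor of 360", call. = FALSE)
  }
  breaks <- seq(0, 360, by = bin_width)
  out <- list()
  for (cls in unique(ds$class)) {
    sub <- ds[ds$class == cls, , drop = FALSE]
    for (ang in ANGLE_NAMES) {
      cnt <- tabulate(findInterval(sub[[ang]], breaks, rightmost.closed = FALSE),
                      nbins = length(breaks) - 1L)
      out[[length(out) + 1L]] <- data.frame(
        class = cls, angle = ang,
        bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
        count = cnt, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write / read the feature table as CSV
#'
#' Fixed header `pdb_id, chain, resseq, base, class, label, alpha ... chi`;
#' missing values are empty cells. Round-trips losslessly to at least four
#' decimals.
#'
#' @param ds a `torsion_dataset`.
#' @param path CSV file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   rebuilt `torsion_dataset`.
#' @export
write_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @param name dataset name for the rebuilt object.
#' @export
read_dataset <- function(path, name = "dataset") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(resseq = "character"))
  build_dataset(df, name = name)
}
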
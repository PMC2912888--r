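## Lennard-Jones atom classes. All heavy atoms are grouped into 20 chemical
## classes (backbone N/CA/C/O; aliphatic carbons by hydrogen count; aromatic
## carbon; amide/carboxyl/guanidinium carbon; amide/carboxyl/hydroxyl oxygen;
## amide/amine/guanidinium/ring nitrogen; thiol/thioether sulfur). The
## grouping and the per-class well depths/radii ship as editable tabular
## configs so users can substitute their own parameterization.

#' Load the shipped (or a user) LJ atom-class table
#'
#' @param path TSV with columns `resid`, `elety`, `class`; defaults to the
#'   table shipped with the package (167 standard heavy-atom names, 20
#'   classes).
#' @return data.frame with the class assignments.
#' @export
load_lj_class_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lj_classes.tsv", package = "rotapack")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("resid", "elety", "class") %in% names(tab)))
  tab
}

#' Load LJ per-class parameters (well depth, radius, polarity)
#'
#' @param path TSV with columns `class`, `epsilon` (kcal/mol), `radius`
#'   (Angstrom), `polar` (logical); defaults to the shipped parameter set.
#'   Well depths follow CHARMM19-style values; radii are fitted to observed
#'   interatomic contact distances (see [fit_lj_radii()]).
#' @return list with `epsilon`, `radius` (named numeric), `polar` (named
#'   logical), `ratio` (the repulsion linearization ratio, 0.89) and
#'   `overrides` (optional pair-specific optimal-distance overrides).
#' @export
load_lj_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lj_params.tsv", package = "rotapack")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("class", "epsilon", "radius") %in% names(tab)))
  if (any(tab$epsilon <= 0) || any(tab$radius <= 0)) {
    stop("LJ parameters must be positive")
  }
  lj_params(stats::setNames(tab$epsilon, tab$class),
            stats::setNames(tab$radius, tab$class),
            polar = if ("polar" %in% names(tab))
              stats::setNames(as.logical(tab$polar), tab$class) else NULL)
}

#' Construct an LJ parameter object
#'
#' Combination rules: `eps_ij = sqrt(eps_i * eps_j)` and
#' `r_ij_min = r_i + r_j`; the repulsive branch is linearized below
#' `ratio * r_ij_min` (default ratio 0.89).
#'
#' @param epsilon,radius named numeric vectors over the 20 classes.
#' @param polar optional named logical (used by calibration).
#' @param ratio linearization ratio.
#' @param overrides optional data.frame (`class_a`, `class_b`, `rmin`) of
#'   pair-specific optimal distances (e.g. polar-polar pairs fixed to their
#'   observed peaks).
#' @export
lj_params <- function(epsilon, radius, polar = NULL, ratio = 0.89,
                      overrides = NULL) {
  stopifnot(length(epsilon) == length(radius),
            all(names(epsilon) == names(radius)),
            all(epsilon > 0), all(radius > 0), ratio > 0, ratio < 1)
  structure(list(epsilon = epsilon, radius = radius, polar = polar,
                 ratio = ratio, overrides = overrides),
            class = "rp_lj_params")
}

#' Assign LJ classes to every heavy atom of a structure
#'
#' Atoms whose (residue type, atom name) is absent from the class table are
#' marked `"unclassified"` (and later excluded from LJ sums) with a logged
#' count. `OXT` maps to the backbone oxygen class.
#'
#' @param structure an `rp_structure`.
#' @param class_table mapping as returned by [load_lj_class_table()].
#' @return the structure with `lj_class` filled in.
#' @export
assign_lj_classes <- function(structure, class_table = load_lj_class_table()) {
  stopifnot(is_structure(structure))
  a <- structure$atoms
  elety <- ifelse(a$elety == "OXT", "O", a$elety)
  key <- paste(a$resid, elety, sep = "|")
  tab_key <- paste(class_table$resid, class_table$elety, sep = "|")
  cls <- class_table$class[match(key, tab_key)]
  n_unknown <- sum(is.na(cls))
  if (n_unknown > 0) {
    message(sprintf("%d atom(s) not in the LJ class table: marked unclassified",
                    n_unknown))
    cls[is.na(cls)] <- "unclassified"
  }
  structure$atoms$lj_class <- cls
  structure
}
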
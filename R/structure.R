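## Structure data model. A structure is a light S3 object holding a flat
## heavy-atom table (one row per atom) plus a residue table with backbone
## dihedrals. Internal residue indices (`res_index`) are 1-based and
## contiguous in order of appearance; author numbering is preserved in
## `resno`.

new_structure <- function(atoms, id = "structure", model_index = 1L,
                          resolution = NA_real_) {
  stopifnot(is.data.frame(atoms))
  required <- c("res_index", "chain", "resno", "resid", "elety",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  atoms$res_index <- as.integer(atoms$res_index)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (is.null(atoms$element)) atoms$element <- element_of(atoms$elety)
  if (is.null(atoms$is_backbone)) {
    atoms$is_backbone <- atoms$elety %in% BACKBONE_ATOMS
  }
  if (is.null(atoms$lj_class)) atoms$lj_class <- NA_character_
  atoms <- atoms[order(atoms$res_index), , drop = FALSE]
  rownames(atoms) <- NULL

  res <- atoms[!duplicated(atoms$res_index),
               c("res_index", "chain", "resno", "resid")]
  rownames(res) <- NULL
  if (!identical(res$res_index, seq_len(nrow(res)))) {
    stop("res_index must be contiguous 1..n in order of appearance")
  }
  s <- structure(
    list(id = id, atoms = atoms, residues = res,
         model_index = as.integer(model_index), resolution = resolution),
    class = "rp_structure")
  s$residues <- cbind(s$residues, backbone_dihedrals(s))
  s
}

is_structure <- function(x) inherits(x, "rp_structure")

#' @export
print.rp_structure <- function(x, ...) {
  cat(sprintf("<structure '%s': %d residues, %d heavy atoms, %d chain(s)>\n",
              x$id, nrow(x$residues), nrow(x$atoms),
              length(unique(x$atoms$chain))))
  invisible(x)
}

n_residues <- function(s) nrow(s$residues)

## Named coordinate matrix (rows = atom names) for one residue.
residue_xyz <- function(s, res_index) {
  sel <- s$atoms$res_index == res_index
  m <- as.matrix(s$atoms[sel, c("x", "y", "z")])
  rownames(m) <- s$atoms$elety[sel]
  m
}

atom_xyz <- function(xyzm, name) {
  i <- match(name, rownames(xyzm))
  if (is.na(i)) NULL else xyzm[i, ]
}

## Backbone phi/psi per residue; NA at chain breaks and termini. Two
## residues are considered peptide-bonded when consecutive in the file,
## same chain, and C(i)-N(i+1) < 2 A.
backbone_dihedrals <- function(s) {
  n <- nrow(s$residues)
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  xyzs <- lapply(seq_len(n), function(i) residue_xyz(s, i))
  bonded <- rep(FALSE, n)  # bonded[i]: residue i bonded to i+1
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (s$residues$chain[i] != s$residues$chain[i + 1]) next
      c_i <- atom_xyz(xyzs[[i]], "C")
      n_j <- atom_xyz(xyzs[[i + 1]], "N")
      if (!is.null(c_i) && !is.null(n_j) && vnorm(c_i - n_j) < 2.0) {
        bonded[i] <- TRUE
      }
    }
  }
  for (i in seq_len(n)) {
    ni <- atom_xyz(xyzs[[i]], "N")
    cai <- atom_xyz(xyzs[[i]], "CA")
    ci <- atom_xyz(xyzs[[i]], "C")
    if (is.null(ni) || is.null(cai) || is.null(ci)) next
    if (i > 1 && bonded[i - 1]) {
      cp <- atom_xyz(xyzs[[i - 1]], "C")
      if (!is.null(cp)) phi[i] <- dihedral_angle(cp, ni, cai, ci)
    }
    if (i < n && bonded[i]) {
      nn <- atom_xyz(xyzs[[i + 1]], "N")
      if (!is.null(nn)) psi[i] <- dihedral_angle(ni, cai, ci, nn)
    }
  }
  data.frame(phi = phi, psi = psi)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records into the package's structure object. Hydrogens and
#' HETATM records are dropped, alternate locations are resolved to the
#' highest-occupancy conformer (ties broken in favour of altloc 'A'), and
#' non-standard residues are skipped with a message. Backbone phi/psi
#' dihedrals are computed where peptide-bonded neighbours exist.
#'
#' @param path path to a PDB file.
#' @param model_index which MODEL to read from a multi-model file
#'   (default 1; NMR entries are treated as single conformers).
#' @param chain_filter optional character vector of chain identifiers to
#'   keep.
#' @return an object of class `rp_structure`.
#' @export
read_structure <- function(path, model_index = 1L, chain_filter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  model_index <- as.integer(model_index)
  if (model_index < 1 || model_index > n_models) {
    stop("model_index ", model_index, " out of range (file has ",
         n_models, " model(s))")
  }
  if (is.matrix(pdb$xyz) && n_models >= 1) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  n_het <- sum(at$type != "ATOM")
  at <- at[at$type == "ATOM", , drop = FALSE]
  nonstd <- unique(at$resid[!(at$resid %in% AA3)])
  if (length(nonstd) > 0 || n_het > 0) {
    message(sprintf("skipped %d HETATM atom(s) and %d non-standard residue type(s)%s",
                    n_het, length(nonstd),
                    if (length(nonstd)) paste0(" (", paste(nonstd, collapse = ","), ")")
                    else ""))
  }
  at <- at[at$resid %in% AA3, , drop = FALSE]
  ## drop hydrogens / deuteriums
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- element_of(at$elety[is.na(elem) | elem == ""])
  keep <- !(toupper(elem) %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]

  if (!is.null(chain_filter)) {
    at <- at[at$chain %in% chain_filter, , drop = FALSE]
  }
  if (nrow(at) == 0) stop("empty structure: no standard protein atoms selected")

  ## altloc resolution: highest occupancy; ties prefer 'A', then lexicographic
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  if (anyDuplicated(akey)) {
    alt_rank <- ifelse(at$alt %in% c("", "A"), 0L, match(at$alt, LETTERS))
    ord <- order(akey, -at$o, alt_rank)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "|")), , drop = FALSE]
    ## restore file order
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }

  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  at$res_index <- match(rkey, unique(rkey))
  atoms <- data.frame(res_index = at$res_index, chain = at$chain,
                      resno = at$resno, resid = at$resid, elety = at$elety,
                      element = element_of(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  new_structure(atoms, id = sub("\\.pdb$", "", basename(path)),
                model_index = model_index)
}

#' Write a structure to a PDB file
#'
#' Emits standard ATOM records; coordinates are written with 3 decimals so
#' a write/read round trip reproduces atom names, residue order and
#' coordinates at that precision. Dihedrals are derived quantities and are
#' not stored.
#'
#' @param structure an `rp_structure`.
#' @param path output file path.
#' @export
write_structure <- function(structure, path) {
  stopifnot(is_structure(structure))
  a <- structure$atoms
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("cannot write to '", path, "': directory does not exist")
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno,
                   resid = a$resid, chain = a$chain,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

## Rebuild a structure with one residue's side-chain atoms replaced by
## `coords` (named matrix, canonical build order). Backbone rows untouched.
replace_sidechain <- function(s, res_index, coords) {
  a <- s$atoms
  keep <- !(a$res_index == res_index & !a$is_backbone)
  a <- a[keep, , drop = FALSE]
  if (!is.null(coords) && nrow(coords) > 0) {
    i <- which(a$res_index == res_index)
    tmpl <- a[rep(i[1], nrow(coords)), , drop = FALSE]
    tmpl$elety <- rownames(coords)
    tmpl$element <- element_of(tmpl$elety)
    tmpl$is_backbone <- FALSE
    tmpl$lj_class <- NA_character_
    tmpl$x <- coords[, 1]; tmpl$y <- coords[, 2]; tmpl$z <- coords[, 3]
    a <- rbind(a, tmpl)
  }
  a <- a[order(a$res_index), , drop = FALSE]
  out <- new_structure(a, id = s$id, model_index = s$model_index,
                       resolution = s$resolution)
  out
}

## Measure the chi angles of one residue from its coordinates. Returns a
## numeric vector of length N_CHI[restype] (NA where atoms are missing).
measure_chi <- function(s, res_index) {
  restype <- s$residues$resid[res_index]
  nchi <- N_CHI[[restype]]
  if (nchi == 0) return(numeric(0))
  xyzm <- residue_xyz(s, res_index)
  defs <- CHI_ATOMS[[restype]]
  out <- rep(NA_real_, nchi)
  for (k in seq_len(nchi)) {
    pts <- lapply(defs[[k]], function(nm) atom_xyz(xyzm, nm))
    if (!any(vapply(pts, is.null, logical(1)))) {
      out[k] <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    }
  }
  out
}
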
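## Model-accuracy metrics: symmetry-aware side-chain RMSD, burial
## classification by relative side-chain accessibility, chi-angle accuracy,
## normalized RMSD against the random-rotamer baseline, the 0-100 contact
## score, and decoy ranking with Z-scores.

## Symmetry-aware RMSD between two named side-chain coordinate sets of one
## residue: the minimum over the identity naming and the residue's
## symmetry-equivalent renaming (e.g. an aromatic ring flip swaps CD1/CD2
## and CE1/CE2 together). Returns the per-residue RMSD over atoms present
## in both.
sidechain_rmsd_residue <- function(restype, xyz_a, xyz_b) {
  common <- intersect(rownames(xyz_a), rownames(xyz_b))
  if (length(common) == 0) return(NA_real_)
  ssd <- function(names_b) {
    sum((xyz_a[common, , drop = FALSE] -
           xyz_b[names_b, , drop = FALSE])^2)
  }
  best <- ssd(common)
  swaps <- SYMMETRY_SWAPS[[restype]]
  if (!is.null(swaps)) {
    renamed <- common
    for (sw in swaps) {
      renamed[renamed == sw[1]] <- "_tmp_"
      renamed[renamed == sw[2]] <- sw[1]
      renamed[renamed == "_tmp_"] <- sw[2]
    }
    if (all(renamed %in% rownames(xyz_b))) {
      best <- min(best, ssd(renamed))
    }
  }
  sqrt(best / length(common))
}

## Per-residue squared-deviation sums (for pooled RMSD) with symmetry.
sidechain_ssd_residue <- function(restype, xyz_a, xyz_b) {
  common <- intersect(rownames(xyz_a), rownames(xyz_b))
  r <- sidechain_rmsd_residue(restype, xyz_a, xyz_b)
  c(ssd = r^2 * length(common), n = length(common))
}

check_correspondence <- function(model, native) {
  stopifnot(is_structure(model), is_structure(native))
  if (n_residues(model) != n_residues(native) ||
      !all(model$residues$resid == native$residues$resid)) {
    stop("model and native residue identities do not match")
  }
}

#' Side-chain heavy-atom RMSD between a model and its native structure
#'
#' Pooled RMSD over side-chain heavy atoms (CB included, backbone
#' excluded), assuming aligned backbones (no superposition). Symmetry-
#' equivalent atom namings (Phe/Tyr ring flips, Asp/Glu carboxylates, Arg
#' NH pair, Leu/Val methyl pairs) are resolved by the minimum-RMSD naming
#' per residue. Residues with atoms missing on either side are excluded
#' with a message.
#'
#' @param model,native `rp_structure`s with identical residue identities.
#' @param selection `"all"`, `"buried"`, `"exposed"` (burial classified on
#'   the native), or `"per_residue"` for the per-residue RMSD vector.
#' @param burial optional precomputed burial labels (from
#'   [classify_burial()]).
#' @return RMSD in Angstrom (or a per-residue vector).
#' @export
sidechain_rmsd <- function(model, native,
                           selection = c("all", "buried", "exposed",
                                         "per_residue"),
                           burial = NULL) {
  selection <- match.arg(selection)
  check_correspondence(model, native)
  res <- native$residues
  n <- nrow(res)
  keep <- rep(TRUE, n)
  if (selection %in% c("buried", "exposed")) {
    if (is.null(burial)) burial <- classify_burial(native)
    keep <- burial == selection
  }
  per <- rep(NA_real_, n)
  ssd_tot <- 0; n_tot <- 0L; n_miss <- 0L
  for (i in seq_len(n)) {
    rt <- res$resid[i]
    if (rt == "GLY") next
    want <- sidechain_atoms(rt)
    xa <- residue_xyz(model, i)
    xb <- residue_xyz(native, i)
    if (!all(want %in% rownames(xa)) || !all(want %in% rownames(xb))) {
      n_miss <- n_miss + 1L
      next
    }
    per[i] <- sidechain_rmsd_residue(rt, xa[want, , drop = FALSE],
                                     xb[want, , drop = FALSE])
    if (keep[i]) {
      ssd_tot <- ssd_tot + per[i]^2 * length(want)
      n_tot <- n_tot + length(want)
    }
  }
  if (n_miss > 0) {
    message(n_miss, " residue(s) excluded from RMSD (missing atoms)")
  }
  if (selection == "per_residue") return(per)
  if (n_tot == 0) return(NA_real_)
  sqrt(ssd_tot / n_tot)
}

## Deterministic near-uniform unit-sphere points (golden spiral).
sphere_points <- function(n = 92) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a rolling probe (default 1.4 A water) over
#' element-based van der Waals radii and a deterministic point sphere.
#'
#' @param structure an `rp_structure`.
#' @param probe probe radius in Angstrom.
#' @param n_points sphere points per atom.
#' @return numeric vector of per-atom SASA (A^2), in atom-table order.
#' @export
atom_sasa <- function(structure, probe = 1.4, n_points = 92) {
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- vdw_radius(a$element) + probe
  n <- nrow(a)
  pts <- sphere_points(n_points)
  out <- numeric(n)
  dm <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    nb <- which(dm[i, ] < rad[i] + rad & dm[i, ] > 0)
    p <- sweep(pts * rad[i], 2, xyz[i, ], FUN = "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > rad[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * rad[i]^2 * mean(acc)
  }
  out
}

## Reference maximal accessibility per residue type: side-chain SASA of X
## in an extended Gly-X-Gly tripeptide (computed once, cached).
.rp_cache <- new.env(parent = emptyenv())

max_sidechain_sasa <- function(restype, probe = 1.4) {
  key <- paste0("maxsasa_", restype, "_", probe)
  if (!is.null(.rp_cache[[key]])) return(.rp_cache[[key]])
  seq1 <- paste0("G", three2one(restype), "G")
  s <- make_toy_structure(seq1, conformation = "extended")
  sas <- atom_sasa(s, probe = probe)
  sel <- if (restype == "GLY") {
    s$atoms$res_index == 2
  } else {
    s$atoms$res_index == 2 & !s$atoms$is_backbone
  }
  val <- sum(sas[sel])
  .rp_cache[[key]] <- val
  val
}

#' Classify residues as buried or exposed
#'
#' Relative side-chain accessibility (1.4 A probe) against the residue
#' type's maximum in an extended Gly-X-Gly tripeptide; at or below the
#' threshold (default 20%) a residue is buried. Gly is classified by
#' full-residue accessibility.
#'
#' @param structure an `rp_structure`.
#' @param threshold relative-accessibility cutoff (default 0.2).
#' @param probe probe radius in Angstrom.
#' @return character vector (`"buried"` / `"exposed"`) per residue.
#' @export
classify_burial <- function(structure, threshold = 0.2, probe = 1.4) {
  sas <- atom_sasa(structure, probe = probe)
  res <- structure$residues
  out <- character(nrow(res))
  for (i in seq_len(nrow(res))) {
    rt <- res$resid[i]
    sel <- structure$atoms$res_index == i
    if (rt != "GLY") sel <- sel & !structure$atoms$is_backbone
    rel <- sum(sas[sel]) / max_sidechain_sasa(rt, probe)
    out[i] <- if (rel <= threshold) "buried" else "exposed"
  }
  out
}

#' Chi-angle prediction accuracy
#'
#' Fraction of residues whose chi1 (and chi1+chi2) deviate from the native
#' by at most `tolerance` degrees (inclusive), computed modulo 360 with
#' terminal 180-degree symmetries (Asp/Phe/Tyr chi2, Glu chi3) taken at
#' minimum. Residues lacking an angle are excluded from that denominator.
#'
#' @param model,native matching `rp_structure`s.
#' @param tolerance degrees (default 15).
#' @return list with `chi1_pct` and `chi12_pct` (percentages).
#' @export
chi_accuracy <- function(model, native, tolerance = 15) {
  check_correspondence(model, native)
  res <- native$residues
  ok1 <- 0L; n1 <- 0L; ok12 <- 0L; n12 <- 0L
  for (i in seq_len(nrow(res))) {
    rt <- res$resid[i]
    if (N_CHI[[rt]] < 1) next
    ca <- measure_chi(model, i)
    cb <- measure_chi(native, i)
    if (is.na(ca[1]) || is.na(cb[1])) next
    dev <- chi_deviation(rt, ca, cb)
    n1 <- n1 + 1L
    if (dev[1] <= tolerance) ok1 <- ok1 + 1L
    if (N_CHI[[rt]] >= 2 && !is.na(dev[2])) {
      n12 <- n12 + 1L
      if (dev[1] <= tolerance && dev[2] <= tolerance) ok12 <- ok12 + 1L
    }
  }
  list(chi1_pct = if (n1 > 0) 100 * ok1 / n1 else NA_real_,
       chi12_pct = if (n12 > 0) 100 * ok12 / n12 else NA_real_)
}

#' Normalized per-residue side-chain RMSD
#'
#' Per residue, the model's side-chain RMSD divided by the expected RMSD of
#' random rotamer placement — the probability-weighted mean RMSD over the
#' residue's library group (deterministic; no sampling). A value of 1 means
#' random-placement accuracy, 0 a side chain matching the native. An
#' undefined baseline (single rotamer identical to the native) yields NA.
#'
#' @param model,native matching `rp_structure`s.
#' @param library an `rp_rotlib`.
#' @return numeric vector of per-residue nRMSD (NA for Gly/Ala and
#'   undefined baselines).
#' @export
nrmsd <- function(model, native, library) {
  check_correspondence(model, native)
  res <- native$residues
  out <- rep(NA_real_, nrow(res))
  for (i in seq_len(nrow(res))) {
    rt <- res$resid[i]
    if (N_CHI[[rt]] < 1) next
    want <- sidechain_atoms(rt)
    xn <- residue_xyz(native, i)
    xm <- residue_xyz(model, i)
    if (!all(want %in% rownames(xn)) || !all(want %in% rownames(xm))) next
    num <- sidechain_rmsd_residue(rt, xm[want, , drop = FALSE],
                                  xn[want, , drop = FALSE])
    grp <- rotamer_group(library, rt, res$phi[i], res$psi[i])
    base <- 0
    for (k in seq_len(nrow(grp))) {
      coords <- build_side_chain(rt, atom_xyz(xn, "N"), atom_xyz(xn, "CA"),
                                 atom_xyz(xn, "C"),
                                 rotamer_chi(grp[k, , drop = FALSE]))
      base <- base + grp$prob[k] *
        sidechain_rmsd_residue(rt, coords, xn[want, , drop = FALSE])
    }
    out[i] <- if (base > 1e-9) num / base else NA_real_
  }
  out
}

## Enumerate ScSc and ScMc atom-atom contacts (van der Waals + pad rule).
## Returns atom-pair records with distances.
atom_contacts <- function(structure, pad = 1) {
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- vdw_radius(a$element)
  dm <- as.matrix(stats::dist(xyz))
  n <- nrow(a)
  pair <- which(upper.tri(dm), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  lim <- rad[i] + rad[j] + pad
  sel <- dm[cbind(i, j)] < lim
  ## ScSc or ScMc only (not both backbone), different residues, not
  ## sequence-adjacent in the same chain
  sel <- sel & !(a$is_backbone[i] & a$is_backbone[j])
  sel <- sel & a$res_index[i] != a$res_index[j]
  adj <- a$chain[i] == a$chain[j] & abs(a$res_index[i] - a$res_index[j]) < 2
  sel <- sel & !adj
  i <- i[sel]; j <- j[sel]
  data.frame(res_i = a$res_index[i], atom_i = a$elety[i],
             res_j = a$res_index[j], atom_j = a$elety[j],
             d = dm[cbind(i, j)], stringsAsFactors = FALSE)
}

#' Contact score of a model against its native structure
#'
#' Enumerates native ScSc and ScMc atom-atom contacts (distance below the
#' sum of van der Waals radii plus 1 A; radii 1.548/1.348/1.400/1.808 A for
#' C/O/N/S), matches each to the same atom pair in the model, and scores it
#' by how closely the model reproduces the native distance: within
#' 0.125 A further / 0.0675 A closer scores 4, then 3 for 0.25/0.125, 2
#' for 0.5/0.25, 1 for 1.0/0.5, else 0. The total is divided by the
#' native-contact count and multiplied by 25, scaling the score to 0-100.
#'
#' @param model,native matching `rp_structure`s.
#' @return list with `score` (0-100, NA when the native has no contacts)
#'   and `n_native` contacts.
#' @export
contact_score <- function(model, native) {
  check_correspondence(model, native)
  nat <- atom_contacts(native)
  if (nrow(nat) == 0) {
    message("native structure has no ScSc/ScMc contacts; contact score undefined")
    return(list(score = NA_real_, n_native = 0L))
  }
  a <- model$atoms
  akey <- paste(a$res_index, a$elety)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  total <- 0
  for (r in seq_len(nrow(nat))) {
    ia <- match(paste(nat$res_i[r], nat$atom_i[r]), akey)
    ib <- match(paste(nat$res_j[r], nat$atom_j[r]), akey)
    if (is.na(ia) || is.na(ib)) next
    dm <- vnorm(xyz[ia, ] - xyz[ib, ])
    diff <- dm - nat$d[r]
    sc <- if (diff <= 0.125 && diff >= -0.0675) 4
    else if (diff <= 0.25 && diff >= -0.125) 3
    else if (diff <= 0.5 && diff >= -0.25) 2
    else if (diff <= 1.0 && diff >= -0.5) 1
    else 0
    total <- total + sc
  }
  list(score = 25 * total / nrow(nat), n_native = nrow(nat))
}

#' Rank a reference structure within a set of scores
#'
#' Rank 1 is the lowest score; the reference's rank is 1 plus the number of
#' strictly lower scores (ties share the better rank). The Z-score is
#' `(mean - score_ref) / sd_pop` (population standard deviation), positive
#' when the reference scores better (lower) than the average.
#'
#' @param scores numeric vector (length >= 2).
#' @param reference_index index of the reference (e.g. the native) in
#'   `scores`.
#' @return list with `rank`, `z`, and the input `scores`.
#' @export
rank_decoys <- function(scores, reference_index) {
  stopifnot(length(scores) >= 2, reference_index >= 1,
            reference_index <= length(scores))
  ref <- scores[reference_index]
  rank <- 1L + sum(scores < ref)
  sd_pop <- sqrt(mean((scores - mean(scores))^2))
  z <- if (sd_pop > 0) (mean(scores) - ref) / sd_pop else NA_real_
  list(rank = rank, z = z, scores = scores)
}

#' Full evaluation report for a model against its native
#'
#' @param model,native matching `rp_structure`s.
#' @param library optional `rp_rotlib` (enables nRMSD).
#' @return an `rp_report`: pooled/buried/exposed RMSD, chi accuracies,
#'   contact score, per-residue nRMSD and burial labels.
#' @export
evaluate_model <- function(model, native, library = NULL) {
  burial <- classify_burial(native)
  chi <- chi_accuracy(model, native)
  cs <- contact_score(model, native)
  structure(list(
    rmsd_all = sidechain_rmsd(model, native),
    rmsd_buried = sidechain_rmsd(model, native, "buried", burial = burial),
    rmsd_exposed = sidechain_rmsd(model, native, "exposed", burial = burial),
    chi1_pct = chi$chi1_pct, chi12_pct = chi$chi12_pct,
    contact_score = cs$score, n_native_contacts = cs$n_native,
    nrmsd = if (!is.null(library)) nrmsd(model, native, library) else NULL,
    burial = burial), class = "rp_report")
}

#' @export
print.rp_report <- function(x, ...) {
  cat(sprintf("<evaluation: RMSD %.2f A (buried %.2f, exposed %.2f) | chi1 %.0f%%  chi1+2 %.0f%% | contact score %.0f>\n",
              x$rmsd_all, x$rmsd_buried, x$rmsd_exposed,
              x$chi1_pct, x$chi12_pct, x$contact_score))
  invisible(x)
}
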
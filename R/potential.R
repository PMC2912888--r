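## The four-term knowledge-based potential: inverse-Boltzmann ScSc and ScMc
## contact terms, the rotamer probability term, and a linearized
## Lennard-Jones term, combined as a weighted sum (lower = better; the
## native should score lowest).

#' Term weights for the combined potential
#'
#' Defaults are the calibrated values 0.13 (ScSc), 0.13 (ScMc), 0.33
#' (rotamer), 0.41 (Lennard-Jones).
#'
#' @param w_scsc,w_scmc,w_rot,w_lj non-negative weights.
#' @export
potential_weights <- function(w_scsc = 0.13, w_scmc = 0.13, w_rot = 0.33,
                              w_lj = 0.41) {
  w <- c(w_scsc = w_scsc, w_scmc = w_scmc, w_rot = w_rot, w_lj = w_lj)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  w
}

## Shared contact-term kernel: -sum over contacts of
## ln[(P_real({dist}|AA) P_real(AA)) / (P_rand({dist}|AA) P_rand(AA))],
## probabilities floored per pair before the ratio.
contact_term <- function(contacts, tables) {
  if (nrow(contacts) == 0) return(list(score = 0, n = 0L))
  score <- 0
  n_used <- 0L
  warned <- character(0)
  for (r in seq_len(nrow(contacts))) {
    key <- contacts$key[r]
    h_real <- tables$real[[key]]
    h_rand <- tables$random[[key]]
    if (is.null(h_real) || h_real$uninformative) {
      if (!key %in% warned) {
        warning("pair ", key, " has no real statistics; contributes 0")
        warned <- c(warned, key)
      }
      next
    }
    fl <- tables$floor_probability[[key]]
    q <- as.numeric(contacts[r, c("d11", "d12", "d21", "d22")])
    p_real <- max(hist_prob_at(h_real, q), fl)
    p_rand <- if (is.null(h_rand) || h_rand$uninformative) fl else
      max(hist_prob_at(h_rand, q), fl)
    pa_real <- max(tables$pair_frequency_real[[key]], fl)
    pa_rand <- max(tables$pair_frequency_random[[key]], fl)
    score <- score - log((p_real * pa_real) / (p_rand * pa_rand))
    n_used <- n_used + 1L
  }
  list(score = score, n = n_used)
}

#' Side chain-side chain contact term
#'
#' Sums the inverse-Boltzmann log-ratio over all unique contacting residue
#' pairs (at least one of the four definition distances below the cutoff).
#' Pairs without statistics contribute 0 with a warning.
#'
#' @param structure an `rp_structure`.
#' @param tables an `rp_tables` from [build_statistics()].
#' @return list with `score` and contact count `n`.
#' @export
score_scsc <- function(structure, tables) {
  stopifnot(is_structure(structure), is_tables(tables))
  defs <- tables$defs[tables$defs$type_b != "MAINCHAIN", , drop = FALSE]
  contacts <- extract_contacts(structure, defs, cutoff = tables$meta$cutoff)
  contact_term(contacts, tables)
}

#' Side chain-main chain contact term
#'
#' As [score_scsc()] with the side-chain pair against the backbone (O, N)
#' pair of partner residues.
#'
#' @inheritParams score_scsc
#' @export
score_scmc <- function(structure, tables) {
  stopifnot(is_structure(structure), is_tables(tables))
  defs <- tables$defs[tables$defs$type_b == "MAINCHAIN", , drop = FALSE]
  contacts <- extract_contacts(structure, defs, cutoff = tables$meta$cutoff)
  contact_term(contacts, tables)
}

#' Rotamer probability term
#'
#' `-sum ln(N_i p_i)` over assigned residues, where `p_i` is the assigned
#' rotamer's library probability and `N_i` its group size. The uniform
#' reference makes a uniform group contribute 0; since `N_i` is fixed per
#' position this differs from `-sum ln p_i` only by a constant and yields
#' identical optimization behaviour.
#'
#' @param assignment data.frame with columns `res_index` and `rot` (row
#'   number within the residue's library group).
#' @param library an `rp_rotlib`.
#' @param structure the structure providing residue types and phi/psi.
#' @return numeric score.
#' @export
score_rot <- function(assignment, library, structure) {
  stopifnot(is.data.frame(assignment), is_rotlib(library))
  res <- structure$residues
  total <- 0
  for (r in seq_len(nrow(assignment))) {
    i <- assignment$res_index[r]
    grp <- rotamer_group(library, res$resid[i], res$phi[i], res$psi[i])
    k <- assignment$rot[r]
    if (k < 1 || k > nrow(grp)) {
      stop("assigned rotamer ", k, " not in the library group of residue ", i)
    }
    total <- total - log(nrow(grp) * grp$prob[k])
  }
  total
}

## 12-6 energy with tangent-line continuation below ratio * rmin.
lj_pair_energy <- function(d, eps, rmin, ratio) {
  e126 <- function(x) eps * ((rmin / x)^12 - 2 * (rmin / x)^6)
  d0 <- ratio * rmin
  lin <- d < d0
  out <- numeric(length(d))
  out[!lin] <- e126(d[!lin])
  if (any(lin)) {
    e0 <- e126(d0)
    slope <- eps * (-12 * rmin^12 / d0^13 + 12 * rmin^6 / d0^7)
    out[lin] <- e0 + slope * (d[lin] - d0)
  }
  out
}

#' Lennard-Jones packing term
#'
#' Pairwise 12-6 energy `eps_ij [(r_min/d)^12 - 2 (r_min/d)^6]` over
#' classified heavy-atom pairs within the evaluation cutoff, with the
#' repulsive branch replaced by its tangent line below
#' `ratio * r_ij_min` (default 0.89) to cap clash penalties during
#' optimization. Favourable (negative) pair energies accumulate into
#' `e_lja`, repulsive ones into `e_ljr`. Excluded pairs: same residue,
#' backbone-backbone (constant under side-chain packing), and the
#' short bond paths across the peptide bond of adjacent residues.
#'
#' @param structure a classified `rp_structure` (see [assign_lj_classes()]).
#' @param params an `rp_lj_params` ([load_lj_params()]).
#' @param cutoff evaluation cutoff in Angstrom (default 10, no shift).
#' @return list with `e_lja` (<= 0), `e_ljr` (>= 0) and pair count `n`.
#' @export
score_lj <- function(structure, params, cutoff = 10) {
  stopifnot(is_structure(structure), inherits(params, "rp_lj_params"))
  a <- structure$atoms
  known <- !is.na(a$lj_class) & a$lj_class %in% names(params$epsilon)
  if (any(!known)) {
    message(sum(!known), " unclassified atom(s) skipped in LJ term")
  }
  a <- a[known, , drop = FALSE]
  n <- nrow(a)
  if (n < 2) return(list(e_lja = 0, e_ljr = 0, n = 0L))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  pair <- which(upper.tri(dm) & dm < cutoff & dm > 0, arr.ind = TRUE)
  if (nrow(pair) == 0) return(list(e_lja = 0, e_ljr = 0, n = 0L))
  i <- pair[, 1]; j <- pair[, 2]
  same_res <- a$res_index[i] == a$res_index[j]
  bb_bb <- a$is_backbone[i] & a$is_backbone[j]
  adj <- a$chain[i] == a$chain[j] & abs(a$res_index[i] - a$res_index[j]) == 1
  ## 1-4 paths across the peptide bond not already covered by bb-bb:
  ## CB(i)-N(i+1) and C(i)-CB(i+1)
  lo <- ifelse(a$res_index[i] < a$res_index[j], i, j)
  hi <- ifelse(a$res_index[i] < a$res_index[j], j, i)
  pep14 <- adj & ((a$elety[lo] == "CB" & a$elety[hi] == "N") |
                  (a$elety[lo] == "C" & a$elety[hi] == "CB"))
  keep <- !(same_res | bb_bb | pep14)
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) return(list(e_lja = 0, e_ljr = 0, n = 0L))
  ci <- a$lj_class[i]; cj <- a$lj_class[j]
  eps <- sqrt(params$epsilon[ci] * params$epsilon[cj])
  rmin <- params$radius[ci] + params$radius[cj]
  if (!is.null(params$overrides) && nrow(params$overrides) > 0) {
    ov <- params$overrides
    okey <- paste(pmin(ov$class_a, ov$class_b), pmax(ov$class_a, ov$class_b))
    pkey <- paste(pmin(ci, cj), pmax(ci, cj))
    m <- match(pkey, okey)
    rmin[!is.na(m)] <- ov$rmin[m[!is.na(m)]]
  }
  d <- dm[cbind(i, j)]
  e <- vapply(seq_along(d), function(k) {
    lj_pair_energy(d[k], eps[k], rmin[k], params$ratio)
  }, numeric(1))
  list(e_lja = sum(e[e < 0]), e_ljr = sum(e[e > 0]), n = length(e))
}

#' Assign each residue its nearest library rotamer
#'
#' Matches measured chi angles to the closest rotamer of the residue's
#' phi/psi group (minimum sum of squared circular chi deviations, terminal
#' 180-degree symmetries taken at minimum; ties keep the lower library
#' index). Used to evaluate the rotamer term of an arbitrary structure.
#'
#' @param structure an `rp_structure`.
#' @param library an `rp_rotlib`.
#' @return data.frame with `res_index` and `rot`.
#' @export
nearest_rotamer_assignment <- function(structure, library) {
  res <- structure$residues
  rows <- list()
  for (i in seq_len(nrow(res))) {
    rt <- res$resid[i]
    if (N_CHI[[rt]] == 0) next
    chi <- measure_chi(structure, i)
    if (anyNA(chi)) next
    grp <- rotamer_group(library, rt, res$phi[i], res$psi[i])
    dev <- vapply(seq_len(nrow(grp)), function(k) {
      sum(chi_deviation(rt, chi, rotamer_chi(grp[k, , drop = FALSE]))^2)
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(res_index = i,
                                           rot = which.min(dev))
  }
  if (length(rows) == 0) {
    return(data.frame(res_index = integer(0), rot = integer(0)))
  }
  do.call(rbind, rows)
}

## Per-chi circular deviation with terminal-symmetry minimization.
chi_deviation <- function(restype, chi_a, chi_b) {
  d <- abs(angle_diff(chi_a, chi_b))
  sym_k <- CHI_SYMMETRIC[restype]
  if (!is.na(sym_k) && sym_k <= length(d)) {
    alt <- abs(angle_diff(chi_a[sym_k], chi_b[sym_k] + 180))
    d[sym_k] <- min(d[sym_k], alt)
  }
  d
}

#' Total weighted potential
#'
#' `E = w_scsc E_scsc + w_scmc E_scmc + w_rot E_rot + w_lj (E_lja + E_ljr)`.
#'
#' @param structure a classified `rp_structure`.
#' @param tables an `rp_tables`.
#' @param library an `rp_rotlib`.
#' @param params an `rp_lj_params`.
#' @param weights from [potential_weights()].
#' @param assignment optional rotamer assignment (data.frame `res_index`,
#'   `rot`); when NULL the nearest library rotamers are used.
#' @return an `rp_energy` breakdown with per-term scores, contact counts
#'   and the weighted total.
#' @export
total_score <- function(structure, tables, library, params,
                        weights = potential_weights(), assignment = NULL) {
  if (is.null(assignment)) {
    assignment <- nearest_rotamer_assignment(structure, library)
  }
  scsc <- score_scsc(structure, tables)
  scmc <- score_scmc(structure, tables)
  erot <- score_rot(assignment, library, structure)
  lj <- score_lj(structure, params)
  energy_breakdown(scsc$score, scmc$score, erot, lj$e_lja, lj$e_ljr, weights,
                   counts = c(scsc = scsc$n, scmc = scmc$n,
                              rot = nrow(assignment), lj = lj$n))
}

energy_breakdown <- function(e_scsc, e_scmc, e_rot, e_lja, e_ljr, weights,
                             counts = NULL) {
  total <- weights[["w_scsc"]] * e_scsc + weights[["w_scmc"]] * e_scmc +
    weights[["w_rot"]] * e_rot + weights[["w_lj"]] * (e_lja + e_ljr)
  structure(list(e_scsc = e_scsc, e_scmc = e_scmc, e_rot = e_rot,
                 e_lja = e_lja, e_ljr = e_ljr, total = total,
                 weights = weights, counts = counts),
            class = "rp_energy")
}

#' @export
print.rp_energy <- function(x, ...) {
  cat(sprintf(
    "<energy: total %.4f | ScSc %.4f  ScMc %.4f  rot %.4f  LJa %.4f  LJr %.4f>\n",
    x$total, x$e_scsc, x$e_scmc, x$e_rot, x$e_lja, x$e_ljr))
  invisible(x)
}
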
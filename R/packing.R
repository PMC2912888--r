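## Side-chain placement by Monte Carlo simulated annealing over rotamer
## space, with greedy quenching. The potential is decomposed once into
## per-position (self) and position-pair energy tables — backbone and
## immutable side chains are fixed, so every term is either constant, a
## function of one position's rotamer, or of two — which makes moves O(n)
## and guarantees incremental updates match a full rescore.

#' MCSA configuration
#'
#' @param cooling_steps number of cooling steps (temperature decreases
#'   linearly to zero; default 100).
#' @param moves_per_step rotamer substitutions per step (default 10000).
#' @param warmup_acceptance target acceptance for the starting-temperature
#'   calibration (default 0.95).
#' @param rng_seed seed (determinism contract).
#' @param off_rotamer also propose 5-degree single-chi perturbations.
#' @param off_rotamer_delta perturbation size in degrees.
#' @param library_variant `"full"` or `"reduced"` (applied when the scorer
#'   is built internally from an original-variant library).
#' @export
mcsa_config <- function(cooling_steps = 100, moves_per_step = 10000,
                        warmup_acceptance = 0.95, rng_seed = 1,
                        off_rotamer = FALSE, off_rotamer_delta = 5,
                        library_variant = c("full", "reduced")) {
  stopifnot(cooling_steps >= 1, moves_per_step >= 1,
            warmup_acceptance > 0, warmup_acceptance < 1)
  list(cooling_steps = as.integer(cooling_steps),
       moves_per_step = as.integer(moves_per_step),
       warmup_acceptance = warmup_acceptance,
       rng_seed = rng_seed, off_rotamer = off_rotamer,
       off_rotamer_delta = off_rotamer_delta,
       library_variant = match.arg(library_variant))
}

#' Build a generic table scorer
#'
#' A scorer over discrete assignments defined by per-position energies and
#' pairwise coupling matrices; the form every fixed-backbone rotamer
#' packing problem reduces to. Useful directly for toy systems with known
#' optima.
#'
#' @param e_self list over positions of numeric vectors (energy per
#'   rotamer).
#' @param e_pair list of lists: `e_pair[[i]][[j]]` (i < j) a matrix of
#'   couplings, or NULL for non-interacting pairs.
#' @param const additive constant (environment-environment energy).
#' @return an `rp_scorer`.
#' @export
table_scorer <- function(e_self, e_pair = NULL, const = 0) {
  n_pos <- length(e_self)
  n_rot <- vapply(e_self, length, integer(1))
  stopifnot(all(n_rot >= 1))
  if (is.null(e_pair)) {
    e_pair <- lapply(seq_len(n_pos), function(i) vector("list", n_pos))
  }
  energy <- function(state) {
    tot <- const
    for (i in seq_len(n_pos)) {
      tot <- tot + e_self[[i]][state[i]]
      if (i < n_pos) for (j in (i + 1):n_pos) {
        m <- e_pair[[i]][[j]]
        if (!is.null(m)) tot <- tot + m[state[i], state[j]]
      }
    }
    tot
  }
  delta <- function(state, i, r) {
    d <- e_self[[i]][r] - e_self[[i]][state[i]]
    for (j in seq_len(n_pos)) {
      if (j == i) next
      m <- if (i < j) e_pair[[i]][[j]] else e_pair[[j]][[i]]
      if (is.null(m)) next
      d <- d + if (i < j) m[r, state[j]] - m[state[i], state[j]] else
        m[state[j], r] - m[state[j], state[i]]
    }
    d
  }
  structure(list(n_pos = n_pos, n_rot = n_rot, energy = energy,
                 delta = delta, e_self = e_self, e_pair = e_pair,
                 const = const),
            class = "rp_scorer")
}

## Flat atom table (res_index, chain, elety, is_backbone, cls, xyz) for LJ.
atom_frame <- function(xyz, res_index, chain, elety, is_backbone, cls) {
  data.frame(res_index = res_index, chain = chain, elety = elety,
             is_backbone = is_backbone, cls = cls,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

## LJ energy between two atom frames with the packing exclusion rules.
lj_cross <- function(A, B, params, cutoff = 10) {
  if (nrow(A) == 0 || nrow(B) == 0) return(0)
  knownA <- A$cls %in% names(params$epsilon)
  knownB <- B$cls %in% names(params$epsilon)
  A <- A[knownA, , drop = FALSE]; B <- B[knownB, , drop = FALSE]
  if (nrow(A) == 0 || nrow(B) == 0) return(0)
  total <- 0
  for (ia in seq_len(nrow(A))) {
    dx <- B$x - A$x[ia]; dy <- B$y - A$y[ia]; dz <- B$z - A$z[ia]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    sel <- d < cutoff & d > 0
    ## exclusions: same residue; bb-bb; peptide 1-4 (CB-N / C-CB adjacent)
    sel <- sel & !(B$res_index == A$res_index[ia])
    sel <- sel & !(B$is_backbone & A$is_backbone[ia])
    adj <- B$chain == A$chain[ia] & abs(B$res_index - A$res_index[ia]) == 1
    lo_is_a <- A$res_index[ia] < B$res_index
    pep14 <- adj & ((lo_is_a & A$elety[ia] == "CB" & B$elety == "N") |
                    (lo_is_a & A$elety[ia] == "C" & B$elety == "CB") |
                    (!lo_is_a & B$elety == "CB" & A$elety[ia] == "N") |
                    (!lo_is_a & B$elety == "C" & A$elety[ia] == "CB"))
    sel <- sel & !pep14
    if (!any(sel)) next
    eps <- sqrt(params$epsilon[A$cls[ia]] * params$epsilon[B$cls[sel]])
    rmin <- params$radius[A$cls[ia]] + params$radius[B$cls[sel]]
    dd <- d[sel]
    for (k in seq_along(dd)) {
      total <- total + lj_pair_energy(dd[k], eps[k], rmin[k], params$ratio)
    }
  }
  total
}

## Single-contact inverse-Boltzmann contribution (0 if no contact or no
## statistics).
contribution_one <- function(key, q, tables) {
  if (min(q) >= tables$meta$cutoff) return(0)
  h_real <- tables$real[[key]]
  if (is.null(h_real) || h_real$uninformative) return(0)
  fl <- tables$floor_probability[[key]]
  h_rand <- tables$random[[key]]
  p_real <- max(hist_prob_at(h_real, q), fl)
  p_rand <- if (is.null(h_rand) || h_rand$uninformative) fl else
    max(hist_prob_at(h_rand, q), fl)
  pa_real <- max(tables$pair_frequency_real[[key]], fl)
  pa_rand <- max(tables$pair_frequency_random[[key]], fl)
  -log((p_real * pa_real) / (p_rand * pa_rand))
}

## ScSc contribution between residues i < j given their coordinate sets.
pair_scsc_energy <- function(type_i, type_j, xyz_i, xyz_j, tables) {
  defs <- tables$defs
  key <- scsc_key(type_i, type_j)
  k <- which(defs$key == key & defs$type_b != "MAINCHAIN")
  if (length(k) == 0) return(0)
  d <- defs[k[1], ]
  if (type_i == d$type_a) { xa <- xyz_i; xb <- xyz_j } else {
    xa <- xyz_j; xb <- xyz_i
  }
  A1 <- atom_xyz(xa, d$a1); A2 <- atom_xyz(xa, d$a2)
  B1 <- atom_xyz(xb, d$b1); B2 <- atom_xyz(xb, d$b2)
  if (is.null(A1) || is.null(A2) || is.null(B1) || is.null(B2)) return(0)
  contribution_one(key, quad_dist(A1, A2, B1, B2), tables)
}

#' Build a potential-backed packing scorer for a structure
#'
#' Decomposes the four-term potential over the structure's mutable
#' positions (side-chain-bearing residues other than Ala; Ala's CB is
#' rebuilt once into the fixed environment). Candidate side-chain
#' coordinates are built per library rotamer of each position's phi/psi
#' group.
#'
#' @param structure a classified `rp_structure`.
#' @param tables an `rp_tables`.
#' @param library an `rp_rotlib`.
#' @param params an `rp_lj_params`.
#' @param weights from [potential_weights()].
#' @param lj_cutoff LJ evaluation cutoff.
#' @return an `rp_scorer` that can also rebuild structures from states
#'   (`$build(state)`).
#' @export
potential_scorer <- function(structure, tables, library, params,
                             weights = potential_weights(), lj_cutoff = 10) {
  stopifnot(is_structure(structure))
  res <- structure$residues
  class_tab <- load_lj_class_table()
  lookup_cls <- function(resid, elety) {
    elety <- ifelse(elety == "OXT", "O", elety)
    cls <- class_tab$class[match(paste(resid, elety, sep = "|"),
                                 paste(class_tab$resid, class_tab$elety,
                                       sep = "|"))]
    cls[is.na(cls)] <- "unclassified"
    cls
  }
  mutable <- which(vapply(res$resid, function(r) N_CHI[[r]] >= 1, logical(1)))
  ## environment: all backbone atoms + Gly (nothing) + Ala CB rebuilt once
  env_rows <- list()
  for (i in seq_len(nrow(res))) {
    xyzm <- residue_xyz(structure, i)
    bb_names <- intersect(rownames(xyzm), BACKBONE_ATOMS)
    bb <- xyzm[bb_names, , drop = FALSE]
    env_rows[[length(env_rows) + 1]] <- atom_frame(
      bb, i, res$chain[i], rownames(bb), TRUE,
      lookup_cls(res$resid[i], rownames(bb)))
    if (res$resid[i] == "ALA") {
      cb <- build_side_chain("ALA", atom_xyz(xyzm, "N"), atom_xyz(xyzm, "CA"),
                             atom_xyz(xyzm, "C"), numeric(0))
      env_rows[[length(env_rows) + 1]] <- atom_frame(
        cb, i, res$chain[i], "CB", FALSE, lookup_cls("ALA", "CB"))
    }
  }
  env <- do.call(rbind, env_rows)

  ## per-position rotamer groups and candidate coordinates
  groups <- list()
  cand <- list()
  for (p in seq_along(mutable)) {
    i <- mutable[p]
    rt <- res$resid[i]
    grp <- rotamer_group(library, rt, res$phi[i], res$psi[i])
    xyzm <- residue_xyz(structure, i)
    coords <- lapply(seq_len(nrow(grp)), function(k) {
      build_side_chain(rt, atom_xyz(xyzm, "N"), atom_xyz(xyzm, "CA"),
                       atom_xyz(xyzm, "C"),
                       rotamer_chi(grp[k, , drop = FALSE]))
    })
    groups[[p]] <- grp
    cand[[p]] <- coords
  }

  ## environment coordinate sets per residue (for ScSc with Ala and ScMc)
  env_xyz_by_res <- lapply(seq_len(nrow(res)), function(i) {
    sel <- env$res_index == i
    m <- as.matrix(env[sel, c("x", "y", "z")])
    rownames(m) <- env$elety[sel]
    m
  })
  scmc_defs <- tables$defs[tables$defs$type_b == "MAINCHAIN", , drop = FALSE]

  sc_frame <- function(p, coords) {
    i <- mutable[p]
    atom_frame(coords, i, res$chain[i], rownames(coords), FALSE,
               lookup_cls(res$resid[i], rownames(coords)))
  }

  ## combined residue coordinates (backbone + candidate side chain)
  full_xyz <- function(p, coords) {
    rbind(env_xyz_by_res[[mutable[p]]], coords)
  }

  ## self energies
  e_self <- vector("list", length(mutable))
  for (p in seq_along(mutable)) {
    i <- mutable[p]
    rt <- res$resid[i]
    grp <- groups[[p]]
    nr <- nrow(grp)
    vals <- numeric(nr)
    dk <- which(scmc_defs$type_a == rt)
    for (r in seq_len(nr)) {
      coords <- cand[[p]][[r]]
      e <- -log(nr * grp$prob[r]) * weights[["w_rot"]]
      ## LJ against the fixed environment
      e <- e + weights[["w_lj"]] *
        lj_cross(sc_frame(p, coords), env, params, lj_cutoff)
      ## ScMc: this side chain against every partner backbone (O, N)
      if (length(dk) > 0) {
        d <- scmc_defs[dk[1], ]
        A1 <- atom_xyz(coords, d$a1); A2 <- atom_xyz(coords, d$a2)
        if (!is.null(A1) && !is.null(A2)) {
          for (j in seq_len(nrow(res))) {
            if (j == i || seq_excluded(res, i, j)) next
            B1 <- atom_xyz(env_xyz_by_res[[j]], "O")
            B2 <- atom_xyz(env_xyz_by_res[[j]], "N")
            if (is.null(B1) || is.null(B2)) next
            e <- e + weights[["w_scmc"]] *
              contribution_one(d$key, quad_dist(A1, A2, B1, B2), tables)
          }
        }
      }
      ## ScSc with immutable Ala side chains (their pair is CA+CB)
      for (j in which(res$resid == "ALA")) {
        if (seq_excluded(res, i, j)) next
        e <- e + weights[["w_scsc"]] *
          pair_scsc_energy(rt, "ALA", full_xyz(p, coords),
                           env_xyz_by_res[[j]], tables)
      }
      vals[r] <- e
    }
    e_self[[p]] <- vals
  }

  ## pair energies
  e_pair <- lapply(seq_along(mutable), function(i) {
    vector("list", length(mutable))
  })
  for (p in seq_along(mutable)) {
    for (q2 in seq_along(mutable)) {
      if (q2 <= p) next
      i <- mutable[p]; j <- mutable[q2]
      ## quick reach check: CA-CA distance vs max side-chain extent
      ca_i <- atom_xyz(env_xyz_by_res[[i]], "CA")
      ca_j <- atom_xyz(env_xyz_by_res[[j]], "CA")
      if (vnorm(ca_i - ca_j) > 28) next
      seqx <- seq_excluded(res, i, j)
      m <- matrix(0, length(cand[[p]]), length(cand[[q2]]))
      nonzero <- FALSE
      for (r in seq_along(cand[[p]])) {
        fi <- sc_frame(p, cand[[p]][[r]])
        xi <- full_xyz(p, cand[[p]][[r]])
        for (s2 in seq_along(cand[[q2]])) {
          e <- weights[["w_lj"]] *
            lj_cross(fi, sc_frame(q2, cand[[q2]][[s2]]), params, lj_cutoff)
          if (!seqx) {
            e <- e + weights[["w_scsc"]] *
              pair_scsc_energy(res$resid[i], res$resid[j], xi,
                               full_xyz(q2, cand[[q2]][[s2]]), tables)
          }
          if (e != 0) nonzero <- TRUE
          m[r, s2] <- e
        }
      }
      if (nonzero) e_pair[[p]][[q2]] <- m
    }
  }

  ## environment-environment constant: score the stripped structure
  env_structure <- local({
    s <- structure
    for (p in seq_along(mutable)) s <- replace_sidechain(s, mutable[p], NULL)
    if (any(res$resid == "ALA")) {
      for (j in which(res$resid == "ALA")) {
        xyzm <- residue_xyz(s, j)
        cb <- build_side_chain("ALA", atom_xyz(xyzm, "N"),
                               atom_xyz(xyzm, "CA"), atom_xyz(xyzm, "C"),
                               numeric(0))
        s <- replace_sidechain(s, j, cb)
      }
    }
    assign_lj_classes(s, class_tab)
  })
  const <- suppressWarnings(suppressMessages(
    total_score(env_structure, tables, library, params, weights,
                assignment = data.frame(res_index = integer(0),
                                        rot = integer(0)))$total))

  sc <- table_scorer(e_self, e_pair, const)
  sc$positions <- mutable
  sc$groups <- groups
  sc$cand <- cand
  sc$build <- function(state) {
    s <- env_structure
    for (p in seq_along(mutable)) {
      s <- replace_sidechain(s, mutable[p], cand[[p]][[state[p]]])
    }
    assign_lj_classes(s, class_tab)
  }
  sc$assignment <- function(state) {
    data.frame(res_index = mutable, rot = as.integer(state))
  }
  sc
}

#' Calibrate the MCSA starting temperature
#'
#' Starting from T = 1, doubles the temperature until the measured
#' Metropolis acceptance over `n_probe` hypothetical probe moves reaches
#' the target (default 0.95). Probe moves never alter the assignment.
#'
#' @param scorer an `rp_scorer`.
#' @param state current assignment (integer vector).
#' @param target target acceptance fraction.
#' @param n_probe probe moves per measurement.
#' @param max_doublings failure bound (pathological scorers).
#' @return the starting temperature T0.
#' @export
calibrate_temperature <- function(scorer, state, target = 0.95,
                                  n_probe = 1000, max_doublings = 60) {
  T0 <- 1
  for (it in seq_len(max_doublings + 1)) {
    acc <- 0L
    for (k in seq_len(n_probe)) {
      i <- sample.int(scorer$n_pos, 1)
      r <- sample.int(scorer$n_rot[i], 1)
      d <- scorer$delta(state, i, r)
      if (d <= 0 || stats::runif(1) < exp(-d / T0)) acc <- acc + 1L
    }
    if (acc / n_probe >= target) return(T0)
    T0 <- 2 * T0
  }
  stop("acceptance target not reached after ", max_doublings,
       " temperature doublings")
}

#' Greedy quench of a rotamer assignment
#'
#' Repeatedly visits positions in random order, testing every rotamer at
#' the visited position and keeping any improvement, until a full pass
#' changes nothing. The returned assignment is 1-rotamer locally optimal
#' and the score trace is non-increasing.
#'
#' @param scorer an `rp_scorer`.
#' @param state integer assignment vector.
#' @return the quenched state.
#' @export
quench <- function(scorer, state) {
  repeat {
    improved <- FALSE
    for (i in sample.int(scorer$n_pos)) {
      best_r <- state[i]
      best_d <- 0
      for (r in seq_len(scorer$n_rot[i])) {
        if (r == state[i]) next
        d <- scorer$delta(state, i, r)
        if (d < best_d - 1e-12) {
          best_d <- d
          best_r <- r
        }
      }
      if (best_r != state[i]) {
        state[i] <- best_r
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  state
}

#' Pack side chains by Monte Carlo simulated annealing
#'
#' Starts from a random rotamer assignment, calibrates the starting
#' temperature to the warm-up acceptance target, cools linearly to zero
#' over `cooling_steps` steps of `moves_per_step` uniform
#' (position, rotamer) Metropolis moves, tracks the lowest-scoring
#' assignment, and finishes with a greedy quench from it.
#'
#' @param scorer an `rp_scorer` ([potential_scorer()] or [table_scorer()]).
#' @param config an [mcsa_config()].
#' @return an `rp_packing` result: `state`, `assignment` (when the scorer
#'   maps states to residues), `structure` (when the scorer can rebuild
#'   one), `energy`, `trajectory` (per-step current/best energy and
#'   acceptance), and the seed.
#' @export
mcsa_pack <- function(scorer, config = mcsa_config()) {
  stopifnot(inherits(scorer, "rp_scorer"))
  if (scorer$n_pos == 0) {
    return(structure(list(state = integer(0), energy = scorer$energy(integer(0)),
                          trajectory = NULL, config = config),
                     class = "rp_packing"))
  }
  with_seed(config$rng_seed, {
    state <- vapply(scorer$n_rot, function(nr) sample.int(nr, 1), integer(1))
    cur <- scorer$energy(state)
    T0 <- calibrate_temperature(scorer, state,
                                target = config$warmup_acceptance)
    best <- state
    best_e <- cur
    steps <- config$cooling_steps
    traj <- data.frame(step = seq_len(steps), temperature = NA_real_,
                       energy = NA_real_, best = NA_real_,
                       acceptance = NA_real_)
    for (k in seq_len(steps)) {
      Tk <- T0 * (1 - (k - 1) / steps)
      acc <- 0L
      for (m in seq_len(config$moves_per_step)) {
        i <- sample.int(scorer$n_pos, 1)
        r <- sample.int(scorer$n_rot[i], 1)
        d <- scorer$delta(state, i, r)
        ok <- if (d <= 0) TRUE else if (Tk > 0) {
          stats::runif(1) < exp(-d / Tk)
        } else FALSE
        if (ok) {
          state[i] <- r
          cur <- cur + d
          acc <- acc + 1L
          if (cur < best_e - 1e-12) {
            best_e <- cur
            best <- state
          }
        }
      }
      traj$temperature[k] <- Tk
      traj$energy[k] <- cur
      traj$best[k] <- best_e
      traj$acceptance[k] <- acc / config$moves_per_step
    }
    state <- quench(scorer, best)
    energy <- scorer$energy(state)
    out <- list(state = state,
                assignment = if (!is.null(scorer$assignment))
                  scorer$assignment(state) else NULL,
                structure = if (!is.null(scorer$build)) scorer$build(state)
                else NULL,
                energy = energy, trajectory = traj, T0 = T0,
                config = config)
    structure(out, class = "rp_packing")
  })
}

#' @export
print.rp_packing <- function(x, ...) {
  cat(sprintf("<packing result: %d position(s), final energy %.4f>\n",
              length(x$state), x$energy))
  invisible(x)
}

#' Single off-rotamer perturbation
#'
#' Picks one chi-bearing position uniformly, one of its chi angles
#' uniformly and a sign uniformly, and offsets that angle by
#' `delta` degrees. Operates on (and returns) an offset matrix so applying
#' the inverse perturbation restores the original angles. Uses the current
#' RNG stream.
#'
#' @param offsets numeric matrix (positions x 4) of chi offsets.
#' @param n_chi integer vector of chi counts per position.
#' @param delta perturbation in degrees (default 5).
#' @return list: updated `offsets`, and the sampled `pos`, `chi`, `sign`.
#' @export
off_rotamer_step <- function(offsets, n_chi, delta = 5) {
  eligible <- which(n_chi > 0)
  if (length(eligible) == 0) stop("no chi-bearing positions")
  pos <- eligible[sample.int(length(eligible), 1)]
  chi <- sample.int(n_chi[pos], 1)
  sgn <- if (stats::runif(1) < 0.5) -1 else 1
  offsets[pos, chi] <- offsets[pos, chi] + sgn * delta
  list(offsets = offsets, pos = pos, chi = chi, sign = sgn)
}

#' Best-rotameric reconstruction of a native structure
#'
#' For each residue independently, builds every rotamer of the residue's
#' library group and keeps the one minimizing the symmetry-aware
#' side-chain heavy-atom RMSD to the native side chain (ties: lower
#' library index). The backbone is unchanged; this is the accuracy ceiling
#' of any rotamer-based packer. Residues with incomplete native side
#' chains are left as-is with a message.
#'
#' @param native an `rp_structure`.
#' @param library an `rp_rotlib`.
#' @return the rebuilt `rp_structure`.
#' @export
best_rotameric <- function(native, library) {
  stopifnot(is_structure(native), is_rotlib(library))
  res <- native$residues
  out <- native
  n_skipped <- 0L
  for (i in seq_len(nrow(res))) {
    rt <- res$resid[i]
    if (N_CHI[[rt]] == 0) next
    xyzm <- residue_xyz(native, i)
    want <- sidechain_atoms(rt)
    if (!all(want %in% rownames(xyzm))) {
      n_skipped <- n_skipped + 1L
      next
    }
    native_sc <- xyzm[want, , drop = FALSE]
    grp <- rotamer_group(library, rt, res$phi[i], res$psi[i])
    best_k <- 1L
    best_rmsd <- Inf
    for (k in seq_len(nrow(grp))) {
      coords <- build_side_chain(rt, atom_xyz(xyzm, "N"),
                                 atom_xyz(xyzm, "CA"), atom_xyz(xyzm, "C"),
                                 rotamer_chi(grp[k, , drop = FALSE]))
      r <- sidechain_rmsd_residue(rt, coords, native_sc)
      if (r < best_rmsd - 1e-12) {
        best_rmsd <- r
        best_k <- k
      }
    }
    coords <- build_side_chain(rt, atom_xyz(xyzm, "N"), atom_xyz(xyzm, "CA"),
                               atom_xyz(xyzm, "C"),
                               rotamer_chi(grp[best_k, , drop = FALSE]))
    out <- replace_sidechain(out, i, coords)
  }
  if (n_skipped > 0) {
    message(n_skipped, " residue(s) skipped (incomplete native side chain)")
  }
  out
}
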
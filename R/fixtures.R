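## Synthetic-data generators: ideal-geometry toy structures, planted-geometry
## contact corpora, decoy sets and a toy backbone-dependent rotamer library.
## All generators are seed-deterministic and return assertion-ready ground
## truth alongside the data. Fixtures use ideal covalent geometry throughout.

## Ideal backbone internal coordinates.
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7,
                ca_c_o = 120.5, omega = 180)

## Build an ideal backbone from per-residue (phi, psi). Returns a list of
## per-residue named coordinate matrices with rows N, CA, C, O.
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  g <- BB_GEOM
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  theta <- deg2rad(g$n_ca_c)
  C <- CA + g$ca_c * c(-cos(theta), sin(theta), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      Np <- res[[i - 1]]["N", ]; CAp <- res[[i - 1]]["CA", ]
      Cp <- res[[i - 1]]["C", ]
      N <- place_atom(Np, CAp, Cp, g$c_n, g$ca_c_n, psi[i - 1])
      CA <- place_atom(CAp, Cp, N, g$n_ca, g$c_n_ca, g$omega)
      C <- place_atom(Cp, N, CA, g$ca_c, g$n_ca_c, phi[i])
    }
    ## carbonyl O antiperiplanar to the next amide N
    psi_i <- if (is.na(psi[i])) 180 else psi[i]
    O <- place_atom(N, CA, C, g$c_o, g$ca_c_o, psi_i + 180)
    res[[i]] <- rbind(N = N, CA = CA, C = C, O = O)
    colnames(res[[i]]) <- c("x", "y", "z")
  }
  res
}

## Assemble an rp_structure from a list of residues, each a list with
## fields chain, resno, resid, xyz (named coordinate matrix).
structure_from_residues <- function(res_list, id = "fixture") {
  rows <- lapply(seq_along(res_list), function(i) {
    r <- res_list[[i]]
    data.frame(res_index = i, chain = r$chain, resno = r$resno,
               resid = r$resid, elety = rownames(r$xyz),
               x = r$xyz[, 1], y = r$xyz[, 2], z = r$xyz[, 3],
               stringsAsFactors = FALSE)
  })
  new_structure(do.call(rbind, rows), id = id)
}

## Default chi angles used when no library is supplied.
default_chi <- function(restype) {
  c(-65, 180, 180, 180)[seq_len(N_CHI[[restype]])]
}

#' Generate an ideal-geometry toy structure
#'
#' Builds a single chain with ideal covalent geometry in a helical or
#' extended backbone conformation and library-built (or default-chi) side
#' chains. Deterministic for a fixed seed.
#'
#' @param sequence one-letter amino-acid sequence (length >= 2).
#' @param conformation `"helix"` (phi,psi = -57,-47) or `"extended"`
#'   (-135, 135).
#' @param library optional `rp_rotlib`; when given, side-chain chi angles
#'   are taken from the group's most probable rotamer, or sampled by
#'   probability when `random_sidechains = TRUE`.
#' @param random_sidechains sample rotamers instead of taking the mode.
#' @param seed RNG seed for side-chain sampling.
#' @param chain chain identifier.
#' @return an `rp_structure`.
#' @export
make_toy_structure <- function(sequence, conformation = c("helix", "extended"),
                               library = NULL, random_sidechains = FALSE,
                               seed = 1, chain = "A") {
  conformation <- match.arg(conformation)
  restypes <- one2three(sequence)
  n <- length(restypes)
  if (n < 2) stop("need at least 2 residues")
  ang <- if (conformation == "helix") c(-57, -47) else c(-135, 135)
  bb <- build_backbone(rep(ang[1], n), rep(ang[2], n))
  with_seed(seed, {
    res_list <- lapply(seq_len(n), function(i) {
      rt <- restypes[i]
      chi <- if (rt %in% c("GLY", "ALA")) {
        numeric(0)
      } else if (is.null(library)) {
        default_chi(rt)
      } else {
        phi <- if (i == 1) NA else ang[1]
        psi <- if (i == n) NA else ang[2]
        grp <- rotamer_group(library, rt, phi, psi)
        k <- if (random_sidechains) {
          sample.int(nrow(grp), 1, prob = grp$prob)
        } else which.max(grp$prob)
        rotamer_chi(grp[k, , drop = FALSE])
      }
      sc <- if (rt == "GLY") NULL else {
        build_side_chain(rt, bb[[i]]["N", ], bb[[i]]["CA", ],
                         bb[[i]]["C", ], chi)
      }
      list(chain = chain, resno = i, resid = rt,
           xyz = rbind(bb[[i]], sc))
    })
    structure_from_residues(res_list, id = paste0("toy_", sequence))
  })
}

## Build a free-standing single residue (ideal backbone triad + side chain).
single_residue <- function(restype, chi = default_chi(restype)) {
  bb <- build_backbone(NA_real_, NA_real_)[[1]]
  sc <- if (restype == "GLY") NULL else {
    build_side_chain(restype, bb["N", ], bb["CA", ], bb["C", ], chi)
  }
  rbind(bb, sc)
}

## Solve 3-D positions p1, p2 for the second atom pair of a contact given
## the first pair at a1 = origin, a2 = (s1,0,0), the rigid separation s2 of
## the second pair, and the target quadruple (d11, d12, d21, d22).
## Errors name the violated geometric bound if the quadruple is infeasible.
solve_quadruple <- function(s1, s2, q) {
  d11 <- q[1]; d12 <- q[2]; d21 <- q[3]; d22 <- q[4]
  x1 <- (d11^2 - d21^2 + s1^2) / (2 * s1)
  rho2 <- d11^2 - x1^2
  if (rho2 < -1e-9) {
    stop(sprintf("infeasible quadruple: |d11 - d21| exceeds first-pair separation (d11=%.3g, d21=%.3g, s1=%.3g)",
                 d11, d21, s1))
  }
  rho <- sqrt(max(rho2, 0))
  p1 <- c(x1, rho, 0)
  x2 <- (d12^2 - d22^2 + s1^2) / (2 * s1)
  R2 <- d12^2 - x2^2
  if (R2 < -1e-9) {
    stop(sprintf("infeasible quadruple: |d12 - d22| exceeds first-pair separation (d12=%.3g, d22=%.3g, s1=%.3g)",
                 d12, d22, s1))
  }
  R2 <- max(R2, 0)
  if (rho < 1e-9) {
    ## p1 on the a1-a2 axis; need (x2-x1)^2 + R2 == s2^2
    if (abs((x2 - x1)^2 + R2 - s2^2) > 1e-6) {
      stop("infeasible quadruple: second-pair separation cannot be satisfied (degenerate axis case)")
    }
    z2 <- sqrt(R2)
    return(list(p1 = p1, p2 = c(x2, 0, z2)))
  }
  ## from |p2 - p1|^2 = s2^2 with p1 = (x1, rho, 0), y2^2 + z2^2 = R2
  y2 <- ((x2 - x1)^2 + R2 + rho^2 - s2^2) / (2 * rho)
  z2sq <- R2 - y2^2
  if (z2sq < -1e-9) {
    stop(sprintf("infeasible quadruple: second-pair separation s2=%.3g incompatible with target distances",
                 s2))
  }
  list(p1 = p1, p2 = c(x2, y2, sqrt(max(z2sq, 0))))
}

## Rigid transform mapping points (b1, b2) onto (p1, p2) (rotation aligning
## the segment + seeded random spin about it), applied to matrix xyz.
rigid_map_pair <- function(xyz, b1, b2, p1, p2, spin = 0) {
  u <- vunit(b2 - b1)
  v <- vunit(p2 - p1)
  axis <- vcross(u, v)
  s <- vnorm(axis)
  cth <- sum(u * v)
  R1 <- if (s < 1e-12) {
    if (cth > 0) diag(3) else {
      ## 180-degree flip about any axis perpendicular to u
      w <- vunit(vcross(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
      2 * outer(w, w) - diag(3)
    }
  } else {
    k <- axis / s
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + s * K + (1 - cth) * (K %*% K)
  }
  ## spin about the target segment direction
  k <- v
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  th <- deg2rad(spin)
  R2 <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  R <- R2 %*% R1
  shifted <- sweep(xyz, 2, b1)
  out <- t(R %*% t(shifted))
  sweep(out, 2, p1, FUN = "+")
}

#' Generate a planted-geometry contact corpus
#'
#' Produces a corpus of two-residue, two-chain structures in which the
#' four-distance quadruple between the chosen atom pairs either equals a
#' target (signal contacts, with optional Gaussian jitter) or is drawn
#' uniformly from the contact-compatible region (noise contacts). Used to
#' test histogram building, smoothing and scoring end to end.
#'
#' @param type_a,type_b residue types of the pair.
#' @param atoms_a,atoms_b character(2): the contact atom pair per residue.
#' @param quadruple numeric(4): target (d11, d12, d21, d22) in Angstrom,
#'   each within (0, 10).
#' @param n_signal,n_noise numbers of signal/noise structures.
#' @param jitter Gaussian sd (Angstrom) added to the signal quadruple.
#' @param seed RNG seed.
#' @param cutoff contact cutoff used for the noise region (default 5).
#' @return list with `structures`, `truth` (data.frame of realized
#'   quadruples and a `signal` flag), and the construction parameters.
#' @export
make_planted_corpus <- function(type_a = "ASN", type_b = "GLN",
                                atoms_a = c("ND2", "OD1"),
                                atoms_b = c("NE2", "OE1"),
                                quadruple = c(2.25, 3.25, 2.25, 3.25),
                                n_signal = 100, n_noise = 0, jitter = 0.15,
                                seed = 1, cutoff = 5) {
  stopifnot(length(quadruple) == 4, all(quadruple > 0), all(quadruple < 10),
            n_signal >= 0, n_noise >= 0)
  xyz_a <- single_residue(type_a)
  xyz_b <- single_residue(type_b)
  for (nm in atoms_a) if (!nm %in% rownames(xyz_a)) {
    stop("atom ", nm, " not in ", type_a)
  }
  for (nm in atoms_b) if (!nm %in% rownames(xyz_b)) {
    stop("atom ", nm, " not in ", type_b)
  }
  a1 <- xyz_a[atoms_a[1], ]; a2 <- xyz_a[atoms_a[2], ]
  b1 <- xyz_b[atoms_b[1], ]; b2 <- xyz_b[atoms_b[2], ]
  s1 <- vnorm(a2 - a1); s2 <- vnorm(b2 - b1)
  ## feasibility check on the noiseless target (errors propagate)
  solve_quadruple(s1, s2, quadruple)
  ## canonical frame: first atom pair on the x axis
  frame_a <- rigid_map_pair(xyz_a, a1, a2, c(0, 0, 0), c(s1, 0, 0))
  rownames(frame_a) <- rownames(xyz_a)
  a1f <- frame_a[atoms_a[1], ]; a2f <- frame_a[atoms_a[2], ]

  with_seed(seed, {
    n_tot <- n_signal + n_noise
    structures <- vector("list", n_tot)
    truth <- matrix(NA_real_, n_tot, 4)
    is_signal <- rep(c(TRUE, FALSE), c(n_signal, n_noise))
    for (m in seq_len(n_tot)) {
      repeat {
        q <- if (is_signal[m]) {
          quadruple + stats::rnorm(4, 0, jitter)
        } else {
          ## uniform over [0, 10)^4, accepted when contact-compatible
          stats::runif(4, 0, 10)
        }
        if (any(q <= 0)) next
        if (!is_signal[m] && min(q) >= cutoff) next
        sol <- tryCatch(solve_quadruple(s1, s2, q), error = function(e) NULL)
        if (is.null(sol)) next
        placed <- rigid_map_pair(xyz_b, b1, b2, sol$p1, sol$p2,
                                 spin = stats::runif(1, 0, 360))
        rownames(placed) <- rownames(xyz_b)
        b1f <- placed[atoms_b[1], ]; b2f <- placed[atoms_b[2], ]
        truth[m, ] <- c(vnorm(b1f - a1f), vnorm(b2f - a1f),
                        vnorm(b1f - a2f), vnorm(b2f - a2f))
        structures[[m]] <- structure_from_residues(list(
          list(chain = "A", resno = 1, resid = type_a, xyz = frame_a),
          list(chain = "B", resno = 1, resid = type_b, xyz = placed)),
          id = sprintf("planted_%03d", m))
        break
      }
    }
    truth <- as.data.frame(truth)
    names(truth) <- c("d11", "d12", "d21", "d22")
    truth$signal <- is_signal
    list(structures = structures, truth = truth,
         pair = c(type_a, type_b), atoms_a = atoms_a, atoms_b = atoms_b,
         quadruple = quadruple, seed = seed)
  })
}

#' Generate a decoy set from a native structure
#'
#' Level-1 decoys randomize side chains on the fixed native backbone;
#' higher levels additionally perturb the backbone dihedrals of an
#' ideal-geometry rebuild (only meaningful for toy structures). Each decoy
#' carries its side-chain RMSD to the native in attribute `"rmsd"`.
#'
#' @param native an `rp_structure`.
#' @param n_decoys number of decoys (0 gives an empty list).
#' @param library an `rp_rotlib` for side-chain randomization.
#' @param level perturbation level (1 = side chains only).
#' @param seed RNG seed.
#' @return list of `rp_structure` decoys.
#' @export
make_decoy_set <- function(native, n_decoys, library, level = 1, seed = 1) {
  stopifnot(is_structure(native), n_decoys >= 0)
  if (n_decoys == 0) return(list())
  with_seed(seed, {
    lapply(seq_len(n_decoys), function(k) {
      base <- native
      if (level >= 2) {
        jit <- 5 * (level - 1)
        phi <- native$residues$phi + stats::rnorm(n_residues(native), 0, jit)
        psi <- native$residues$psi + stats::rnorm(n_residues(native), 0, jit)
        phi[is.na(phi)] <- -120; psi[is.na(psi)] <- 140
        bb <- build_backbone(phi, psi)
        res_list <- lapply(seq_len(n_residues(native)), function(i) {
          rt <- native$residues$resid[i]
          chi <- if (rt %in% c("GLY", "ALA")) numeric(0) else
            measure_chi(native, i)
          sc <- if (rt == "GLY") NULL else
            build_side_chain(rt, bb[[i]]["N", ], bb[[i]]["CA", ],
                             bb[[i]]["C", ], chi)
          list(chain = native$residues$chain[i],
               resno = native$residues$resno[i], resid = rt,
               xyz = rbind(bb[[i]], sc))
        })
        base <- structure_from_residues(res_list, id = native$id)
      }
      d <- randomize_side_chains(base, library,
                                 rng_seed = sample.int(.Machine$integer.max / 2, 1))
      d$id <- sprintf("%s_decoy_%03d", native$id, k)
      attr(d, "rmsd") <- sidechain_rmsd(d, base)
      d
    })
  })
}

#' Generate a small, valid toy rotamer library
#'
#' Covers every side-chain-bearing residue type (all but Gly and Ala; Ala
#' needs no chi angles) at every phi/psi bin of a coarse grid, with up to
#' three chi1 wells (gauche-, trans, gauche+) and seed-jittered chi values
#' so that different bins differ. Groups are normalized.
#'
#' @param seed RNG seed.
#' @param grid phi/psi bin width in degrees (default 120, i.e. 3x3 bins).
#' @param n_rot rotamers per group (1..3).
#' @return an `rp_rotlib` with `variant = "original"`.
#' @export
make_toy_rotamer_library <- function(seed = 1, grid = 120, n_rot = 3) {
  stopifnot(n_rot >= 1, n_rot <= 3, 360 %% grid == 0)
  nbin <- as.integer(360 / grid)
  types <- setdiff(AA3, c("GLY", "ALA"))
  chi1_wells <- c(-65, 180, 62)
  base_prob <- c(0.5, 0.3, 0.2)[seq_len(n_rot)]
  with_seed(seed, {
    rows <- list()
    for (rt in types) {
      n <- N_CHI[[rt]]
      for (pb in 0:(nbin - 1)) for (qb in 0:(nbin - 1)) {
        for (r in seq_len(n_rot)) {
          chi <- rep(NA_real_, 4)
          sig <- rep(NA_real_, 4)
          chi[1] <- chi1_wells[r] + stats::rnorm(1, 0, 3)
          if (n > 1) chi[2:n] <- c(180, 180, 180)[1:(n - 1)] +
              stats::rnorm(n - 1, 0, 5)
          sig[seq_len(n)] <- stats::runif(n, 8, 12)
          rows[[length(rows) + 1]] <- data.frame(
            resid = rt, phibin = pb, psibin = qb,
            chi1 = chi[1], chi2 = chi[2], chi3 = chi[3], chi4 = chi[4],
            sig1 = sig[1], sig2 = sig[2], sig3 = sig[3], sig4 = sig[4],
            prob = base_prob[r] / sum(base_prob),
            stringsAsFactors = FALSE)
        }
      }
    }
    entries <- do.call(rbind, rows)
    rownames(entries) <- NULL
    rotlib_new(entries, grid, "original")
  })
}

#' Write a rotamer library to the package's tabular text format
#'
#' Inverse of [load_library()]: emits the documented whitespace-separated
#' columns with phi/psi bin lower edges.
#'
#' @param lib an `rp_rotlib`.
#' @param path output file.
#' @export
write_library <- function(lib, path) {
  stopifnot(is_rotlib(lib))
  e <- lib$entries
  out <- data.frame(resid = e$resid,
                    phi = e$phibin * lib$grid - 180,
                    psi = e$psibin * lib$grid - 180,
                    e[, c(paste0("chi", 1:4), paste0("sig", 1:4), "prob")])
  utils::write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}
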
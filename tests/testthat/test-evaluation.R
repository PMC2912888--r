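test_that("side-chain RMSD is zero on identity and handles symmetry swaps", {
  s <- make_toy_structure("FKDLEV", library = tf_lib())
  expect_equal(sidechain_rmsd(s, s), 0)
  ## flip the Phe ring by renaming the equivalent atoms
  s2 <- s
  sel <- s2$atoms$res_index == 1
  nm <- s2$atoms$elety
  swap <- c(CD1 = "CD2", CD2 = "CD1", CE1 = "CE2", CE2 = "CE1")
  nm[sel & nm %in% names(swap)] <- swap[nm[sel & nm %in% names(swap)]]
  s2$atoms$elety <- nm
  expect_equal(sidechain_rmsd(s2, s), 0, tolerance = 1e-9)
  ## single displaced atom: pooled RMSD = delta / sqrt(n_atoms)
  s3 <- make_toy_structure("SG", conformation = "extended")
  s4 <- s3
  og <- s4$atoms$elety == "OG"
  s4$atoms$x[og] <- s4$atoms$x[og] + 1.2
  expect_equal(sidechain_rmsd(s4, s3), 1.2 / sqrt(2), tolerance = 1e-9)
  ## residue identity mismatch errors
  s5 <- make_toy_structure("AG", conformation = "extended")
  expect_error(sidechain_rmsd(s5, s3), "identities")
})

test_that("burial classification separates core from surface deterministically", {
  ## an isolated residue is fully exposed
  iso <- make_toy_structure("GSG", conformation = "extended")
  expect_equal(classify_burial(iso)[2], "exposed")
  ## burying the side chain inside a spherical cage of residues flips it
  bb <- build_backbone(NA_real_, NA_real_)[[1]]
  sc <- build_side_chain("SER", c(0, 0, 0), c(1.458, 0, 0),
                         c(2.01, 1.42, 0), -65)
  center <- colMeans(rbind(bb, sc))
  pts <- sphere_points(40) * 5.5
  cage_res <- lapply(seq_len(nrow(pts)), function(k) {
    pos <- center + pts[k, ]
    list(chain = "C", resno = k + 10, resid = "GLY",
         xyz = bb - matrix(rep(bb["CA", ] - pos, each = 4), ncol = 3))
  })
  buried <- structure_from_residues(
    c(list(list(chain = "A", resno = 1, resid = "SER",
                xyz = rbind(bb, sc))), cage_res), id = "cage")
  lab <- classify_burial(buried)
  expect_equal(lab[1], "buried")
  ## raising the threshold never shrinks the buried set
  t1 <- classify_burial(buried, threshold = 0.1)
  t2 <- classify_burial(buried, threshold = 0.4)
  expect_true(all(which(t1 == "buried") %in% which(t2 == "buried")))
})

test_that("chi accuracy is inclusive at the tolerance and symmetry-aware", {
  s <- make_toy_structure("NDLKE", library = tf_lib())
  acc <- chi_accuracy(s, s)
  expect_equal(acc$chi1_pct, 100)
  expect_equal(acc$chi12_pct, 100)
  ## a deviation of exactly 15 degrees still counts
  i <- 2  # ASP
  chi <- measure_chi(s, i)
  s15 <- set_rotamer(s, i, chi + c(15, 0))
  expect_equal(chi_accuracy(s15, s)$chi1_pct, 100)
  s16 <- set_rotamer(s, i, chi + c(16, 0))
  expect_lt(chi_accuracy(s16, s)$chi1_pct, 100)
  ## Asp chi2 off by 180 is correct via the carboxylate symmetry
  sflip <- set_rotamer(s, i, chi + c(0, 180))
  expect_equal(chi_accuracy(sflip, s)$chi12_pct, 100)
})

test_that("nRMSD is zero at identity and one against the library baseline", {
  lib <- tf_lib()
  native <- make_toy_structure("GSKG", library = lib)
  expect_equal(nrmsd(native, native, lib)[2:3], c(0, 0))
  ## a model whose residue RMSD is forced to the baseline expectation
  i <- 3  # LYS
  grp <- rotamer_group(lib, "LYS", native$residues$phi[i],
                       native$residues$psi[i])
  xn <- residue_xyz(native, i)
  want <- sidechain_atoms("LYS")
  base <- sum(vapply(seq_len(nrow(grp)), function(k) {
    coords <- build_side_chain("LYS", atom_xyz(xn, "N"), atom_xyz(xn, "CA"),
                               atom_xyz(xn, "C"),
                               rotamer_chi(grp[k, , drop = FALSE]))
    grp$prob[k] * sidechain_rmsd_residue("LYS", coords,
                                         xn[want, , drop = FALSE])
  }, numeric(1)))
  model <- set_rotamer(native, i, rotamer_chi(grp[2, , drop = FALSE]))
  num <- sidechain_rmsd(model, native, "per_residue")[i]
  expect_equal(nrmsd(model, native, lib)[i], num / base, tolerance = 1e-9)
  expect_true(all(stats::na.omit(nrmsd(model, native, lib)) >= 0))
})

test_that("the contact score is 100 on self and follows the printed intervals", {
  s <- make_toy_structure("SKNDLEQV", library = tf_lib())
  cs <- contact_score(s, s)
  expect_gt(cs$n_native, 0)
  expect_equal(cs$score, 100)
  ## single native contact between two lone side-chain atoms
  pair_at <- function(d) {
    a <- data.frame(res_index = 1:2, chain = c("A", "B"), resno = 1,
                    resid = "ALA", elety = "CB", element = "C",
                    is_backbone = FALSE, lj_class = NA_character_,
                    x = c(0, d), y = 0, z = 0, stringsAsFactors = FALSE)
    new_structure(a, id = "pair")
  }
  nat <- pair_at(3.0)   # < 2 * 1.548 + 1: one native contact
  expect_equal(contact_score(nat, nat)$score, 100)
  ## +0.3 A further falls in the 0.5/0.25 interval -> per-contact 2 -> 50
  expect_equal(contact_score(pair_at(3.3), nat)$score, 50)
  ## +0.2 A -> interval 0.25/0.125 -> 3 -> 75; -0.1 A closer -> 3 -> 75
  expect_equal(contact_score(pair_at(3.2), nat)$score, 75)
  expect_equal(contact_score(pair_at(2.9), nat)$score, 75)
  ## +1.5 A is outside every interval
  expect_equal(contact_score(pair_at(4.5), nat)$score, 0)
  ## no native contacts -> missing
  far <- make_toy_structure("GG", conformation = "extended")
  expect_true(is.na(suppressMessages(contact_score(far, far))$score))
})

test_that("decoy ranking uses strict rank and population Z-scores", {
  r <- rank_decoys(c(0, 1, 2, 3), 1)
  expect_equal(r$rank, 1)
  expect_equal(r$z, 1.5 / sqrt(mean((c(0, 1, 2, 3) - 1.5)^2)),
               tolerance = 1e-9)
  expect_equal(round(r$z, 3), 1.342)
  ## reference strictly lowest among 5 -> rank 1, positive Z
  r2 <- rank_decoys(c(-2, 0.5, 1, 1.3, 2), 1)
  expect_equal(r2$rank, 1)
  expect_gt(r2$z, 0)
  ## all equal: rank 1 with undefined Z
  r3 <- rank_decoys(rep(1, 4), 2)
  expect_equal(r3$rank, 1)
  expect_true(is.na(r3$z))
  ## rank invariant under strictly monotone transformation
  sc <- c(0.3, -1.2, 2.5, 0.9, -0.4)
  expect_equal(rank_decoys(exp(sc), 3)$rank, rank_decoys(sc, 3)$rank)
  expect_error(rank_decoys(1, 1))
})

test_that("the evaluation report assembles all metrics", {
  lib <- tf_lib()
  native <- make_toy_structure("SKNDLEQV", library = lib)
  model <- randomize_side_chains(native, lib, rng_seed = 3)
  rep <- suppressMessages(evaluate_model(model, native, lib))
  expect_s3_class(rep, "rp_report")
  expect_gte(rep$rmsd_all, 0)
  expect_true(rep$chi1_pct >= 0 && rep$chi1_pct <= 100)
  expect_true(is.na(rep$contact_score) ||
                (rep$contact_score >= 0 && rep$contact_score <= 100))
  expect_equal(length(rep$burial), n_residues(native))
})
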
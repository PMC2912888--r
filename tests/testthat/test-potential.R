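test_that("weights default to the calibrated values and validate", {
  w <- potential_weights()
  expect_equal(unname(w), c(0.13, 0.13, 0.33, 0.41))
  expect_error(potential_weights(-0.1), "weights")
  expect_error(potential_weights(NA), "weights")
})

test_that("the contact term is a floored log-ratio with the right signs", {
  tabs <- tf_planted_tables()
  nat <- tf_planted()$structures[[1]]
  ## planted-geometry structure scores favourably (negative)
  s_nat <- quiet(score_scsc(nat, tabs))
  expect_lt(s_nat$score, 0)
  expect_equal(s_nat$n, 1)
  ## a scrambled decoy scores higher
  dec <- randomize_side_chains(nat, tf_lib(), rng_seed = 11)
  s_dec <- quiet(score_scsc(dec, tabs))
  expect_gt(s_dec$score, s_nat$score)
  ## identical real and random tables give a zero contribution
  t0 <- tabs
  t0$random <- t0$real
  t0$pair_frequency_random <- t0$pair_frequency_real
  expect_equal(quiet(score_scsc(nat, t0))$score, 0, tolerance = 1e-9)
  ## a contact in a bin with zero real counts is penalized: the floored
  ## ratio floor/P_rand is below 1, so the -log contribution is positive
  t1 <- tabs
  q <- as.numeric(extract_contacts(nat, asn_gln_defs())[1,
                                                        c("d11", "d12", "d21", "d22")])
  nb <- dim(t1$real[["ASN|GLN"]]$prob)[1]
  idx <- pmin(pmax(floor(q / 0.5), 0), nb - 1) + 1
  t1$real[["ASN|GLN"]]$prob[idx[1], idx[2], idx[3], idx[4]] <- 0
  t1$random[["ASN|GLN"]]$prob[idx[1], idx[2], idx[3], idx[4]] <- 0.05
  t1$pair_frequency_random[["ASN|GLN"]] <- t1$pair_frequency_real[["ASN|GLN"]]
  expect_gt(quiet(score_scsc(nat, t1))$score, 0)
})

test_that("structures without scoreable contacts score 0 with count 0", {
  s <- make_toy_structure("GG", conformation = "extended")
  tabs <- tf_planted_tables()
  expect_equal(score_scsc(s, tabs), list(score = 0, n = 0L))
  expect_equal(score_scmc(s, tabs), list(score = 0, n = 0L))
})

test_that("the rotamer term follows -ln(N p)", {
  s <- make_toy_structure("SS", conformation = "extended")
  g <- data.frame(resid = "SER", phibin = 0:0, psibin = 0,
                  chi1 = c(60, 180, -60, -175), chi2 = NA_real_,
                  chi3 = NA_real_, chi4 = NA_real_, sig1 = 9,
                  sig2 = NA_real_, sig3 = NA_real_, sig4 = NA_real_,
                  prob = 0.25)
  lib_u <- rotlib_new(g, 360)
  asn <- data.frame(res_index = 1L, rot = 2L)
  ## uniform group: p = 1/N -> 0 per residue
  expect_equal(score_rot(asn, lib_u, s), 0, tolerance = 1e-12)
  ## single-rotamer group: p = 1, N = 1 -> 0
  lib_1 <- rotlib_new(g[1, ], 360); lib_1$entries$prob <- 1
  expect_equal(score_rot(data.frame(res_index = 1L, rot = 1L), lib_1, s), 0)
  ## p = 0.5, N = 4 -> -ln 2
  g2 <- g; g2$prob <- c(0.5, 0.3, 0.1, 0.1)
  lib_2 <- rotlib_new(g2, 360)
  expect_equal(score_rot(data.frame(res_index = 1L, rot = 1L), lib_2, s),
               -log(4 * 0.5), tolerance = 1e-12)
  expect_error(score_rot(data.frame(res_index = 1L, rot = 9L), lib_2, s),
               "not in the library group")
})

test_that("the LJ term has its minimum at r_min and a tangent-line core", {
  eps <- 0.2; rmin <- 3.6; ratio <- 0.89
  expect_equal(lj_pair_energy(rmin, eps, rmin, ratio), -eps)
  d0 <- ratio * rmin
  ## continuity of value and slope at the linearization point
  e <- function(d) lj_pair_energy(d, eps, rmin, ratio)
  expect_lt(abs(e(d0 - 1e-7) - e(d0 + 1e-7)), 1e-5)
  slope_lin <- (e(d0 - 1e-4) - e(d0 - 2e-4)) / 1e-4
  slope_126 <- (e(d0 + 2e-4) - e(d0 + 1e-4)) / 1e-4
  expect_equal(slope_lin, slope_126, tolerance = 1e-2)
  ## the linear branch caps repulsion below the 12-6 value
  e126 <- eps * ((rmin / (0.5 * rmin))^12 - 2 * (rmin / (0.5 * rmin))^6)
  expect_lt(e(0.5 * rmin), e126)
  expect_gt(e(0.5 * rmin), 0)
})

test_that("score_lj splits attraction and repulsion with the exclusion rules", {
  s <- assign_lj_classes(make_toy_structure("KNDLE", library = tf_lib()))
  lj <- score_lj(s, load_lj_params())
  expect_lte(lj$e_lja, 0)
  expect_gte(lj$e_ljr, 0)
  expect_gt(lj$n, 0)
  ## two isolated classified atoms at exactly r_min contribute -eps
  a <- s$atoms[s$atoms$elety == "CB", ][1:2, ]
  p <- load_lj_params()
  rmin <- p$radius[a$lj_class[1]] + p$radius[a$lj_class[2]]
  a$x <- c(0, rmin); a$y <- 0; a$z <- 0
  a$res_index <- 1:2; a$chain <- c("A", "B"); a$resno <- 1:2
  iso <- new_structure(a, id = "iso")
  lj2 <- score_lj(iso, p)
  expect_equal(lj2$e_lja,
               -sqrt(p$epsilon[a$lj_class[1]] * p$epsilon[a$lj_class[2]]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(lj2$e_ljr, 0)
})

test_that("the total is the weighted dot product of the terms", {
  tabs <- tf_tables()
  s <- assign_lj_classes(tf_corpus()[[1]])
  lib <- tf_lib(); params <- load_lj_params()
  e1 <- quiet(total_score(s, tabs, lib, params, potential_weights(1, 0, 0, 0)))
  expect_equal(e1$total, e1$e_scsc, tolerance = 1e-12)
  w <- potential_weights()
  e <- quiet(total_score(s, tabs, lib, params, w))
  expect_equal(e$total,
               0.13 * e$e_scsc + 0.13 * e$e_scmc + 0.33 * e$e_rot +
                 0.41 * (e$e_lja + e$e_ljr), tolerance = 1e-9)
  ## all-zero terms give zero total
  z <- energy_breakdown(0, 0, 0, 0, 0, w)
  expect_equal(z$total, 0)
})

test_that("scores are invariant under rigid motion and chain relabeling", {
  tabs <- tf_tables()
  lib <- tf_lib(); params <- load_lj_params()
  s <- assign_lj_classes(tf_corpus()[[2]])
  e0 <- quiet(total_score(s, tabs, lib, params))
  ## rigid rotation + translation
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s2 <- s
  s2$atoms$x <- xyz[, 1] + 11.3
  s2$atoms$y <- xyz[, 2] - 4.2
  s2$atoms$z <- xyz[, 3] + 0.7
  s2 <- new_structure(s2$atoms, id = "moved")
  s2 <- assign_lj_classes(s2)
  e1 <- quiet(total_score(s2, tabs, lib, params))
  expect_equal(e1$total, e0$total, tolerance = 1e-6)
  ## chain relabeling
  s3 <- s
  s3$atoms$chain <- "Q"
  s3 <- assign_lj_classes(new_structure(s3$atoms, id = "relabeled"))
  e2 <- quiet(total_score(s3, tabs, lib, params))
  expect_equal(e2$total, e0$total, tolerance = 1e-9)
})

test_that("the table-decomposed scorer matches a full rescore", {
  tabs <- tf_tables()
  lib <- tf_lib(); params <- load_lj_params(); w <- potential_weights()
  s <- assign_lj_classes(tf_corpus()[[1]])
  sc <- quiet(potential_scorer(s, tabs, lib, params, w))
  set.seed(42)
  for (rep in 1:3) {
    state <- vapply(sc$n_rot, function(n) sample.int(n, 1), integer(1))
    e_table <- sc$energy(state)
    e_full <- quiet(total_score(sc$build(state), tabs, lib, params, w,
                                assignment = sc$assignment(state)))$total
    expect_equal(e_table, e_full, tolerance = 1e-6)
    ## single-rotamer substitution: incremental delta equals full rescore
    i <- sample.int(sc$n_pos, 1)
    r <- sample.int(sc$n_rot[i], 1)
    d <- sc$delta(state, i, r)
    state2 <- state; state2[i] <- r
    e_full2 <- quiet(total_score(sc$build(state2), tabs, lib, params, w,
                                 assignment = sc$assignment(state2)))$total
    expect_equal(e_full + d, e_full2, tolerance = 1e-6)
  }
})
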
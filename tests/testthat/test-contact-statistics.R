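test_that("candidate enumeration counts follow side-chain combinatorics", {
  expect_equal(nrow(enumerate_candidates("ASN", "GLN")), 6 * 10)
  expect_equal(nrow(enumerate_candidates("GLY", "ALA")), 0)
  expect_equal(nrow(enumerate_candidates("CYS", "CYS")), 1)
  expect_equal(nrow(enumerate_candidates("ALA", "SER")), 1)
  ## homo pairs deduplicate unordered combinations: 6 choices -> 21
  expect_equal(nrow(enumerate_candidates("ASN", "ASN")), 6 * 7 / 2)
})

test_that("the complete type sets count 190 ScSc and 18 ScMc pairs", {
  pt <- all_pair_types()
  expect_equal(length(pt$scsc), 190)
  expect_equal(length(pt$scmc), 18)
  expect_false(any(grepl("GLY", pt$scsc)))
  expect_false(any(grepl("ALA|GLY", pt$scmc)))
})

test_that("atom-pair selection picks the planted combination and breaks ties lexicographically", {
  ## corpus where only the planted amide-pair combination is ever inside 5 A
  pc <- make_planted_corpus(quadruple = c(4.25, 4.75, 4.75, 5.25),
                            n_signal = 3, n_noise = 0, jitter = 0, seed = 1)
  defs <- select_atom_pairs(pc$structures, kind = "scsc")
  d <- defs[defs$key == "ASN|GLN", ]
  ## selection is deterministic: maximal count, ties by atom-name order
  expect_equal(nrow(d), 1)
  cand <- enumerate_candidates("ASN", "GLN")
  counts <- vapply(seq_len(nrow(cand)), function(r) {
    sum(vapply(pc$structures, function(s) {
      xa <- residue_xyz(s, 1); xb <- residue_xyz(s, 2)
      min(quad_dist(xa[cand$a1[r], ], xa[cand$a2[r], ],
                    xb[cand$b1[r], ], xb[cand$b2[r], ])) < 5
    }, logical(1)))
  }, numeric(1))
  lab <- paste(cand$a1, cand$a2, cand$b1, cand$b2)
  best <- lab[order(-counts, lab)][1]
  expect_equal(paste(d$a1, d$a2, d$b1, d$b2), best)
})

test_that("contact extraction respects the strict 5 A cutoff boundary", {
  place_at <- function(gap) {
    ## two parallel amide pairs, closest approach = gap
    make_planted_corpus(quadruple = c(gap, sqrt(gap^2 + 2.247238^2),
                                      sqrt(gap^2 + 2.247238^2), gap),
                        n_signal = 1, n_noise = 0, jitter = 0,
                        seed = 1)$structures[[1]]
  }
  expect_equal(nrow(extract_contacts(place_at(4.9), asn_gln_defs())), 1)
  expect_equal(nrow(extract_contacts(place_at(5.0), asn_gln_defs())), 0)
})

test_that("planted corpora reproduce their quadruples to 1e-6", {
  pc <- make_planted_corpus(n_signal = 3, n_noise = 0, jitter = 0, seed = 7)
  for (k in 1:3) {
    ct <- extract_contacts(pc$structures[[k]], asn_gln_defs())
    expect_equal(nrow(ct), 1)
    expect_equal(as.numeric(ct[1, c("d11", "d12", "d21", "d22")]),
                 pc$quadruple, tolerance = 1e-6)
  }
})

test_that("sequence-adjacent residues are excluded from contacts", {
  s <- make_toy_structure("NQ", conformation = "helix", library = tf_lib())
  expect_equal(nrow(extract_contacts(s, asn_gln_defs())), 0)
})

test_that("histogram binning, normalization and clamping are exact", {
  ct <- data.frame(d11 = 2.8, d12 = 3.1, d21 = 3.3, d22 = 3.5)
  h <- build_histogram(ct)
  expect_equal(dim(h$counts), rep(20, 4))
  expect_equal(length(h$counts), 160000)
  expect_equal(h$prob[6, 7, 7, 8], 1)
  expect_equal(sum(h$prob), 1)
  ## 3:1 split across two bins
  ct4 <- data.frame(d11 = c(2.8, 2.8, 2.8, 4.6), d12 = 3.1, d21 = 3.3,
                    d22 = 3.5)
  h4 <- build_histogram(ct4)
  expect_equal(h4$prob[6, 7, 7, 8], 0.75)
  expect_equal(h4$prob[10, 7, 7, 8], 0.25)
  ## distances beyond the range clamp into the last bin
  ct_far <- data.frame(d11 = 2.8, d12 = 14.0, d21 = 3.3, d22 = 10.0)
  hf <- build_histogram(ct_far)
  expect_equal(hf$total, 1)
  expect_equal(hf$prob[6, 20, 7, 20], 1)
  ## empty contact set -> uninformative
  he <- build_histogram(ct[0, ])
  expect_true(he$uninformative)
  expect_equal(he$total, 0)
  expect_error(build_histogram(ct, bin_size = 0.7), "divide")
})

test_that("smoothing is the truncated 3^4 box mean with mass conservation", {
  ## uniform histogram is a fixed point
  h <- build_histogram(data.frame(d11 = 1, d12 = 1, d21 = 1, d22 = 1))
  h$prob <- array(1 / 160000, dim = rep(20, 4))
  hs <- smooth_histogram(h)
  expect_equal(hs$prob, h$prob, tolerance = 1e-12)
  ## single interior cell spreads to 1/81 over its neighbourhood
  h2 <- build_histogram(data.frame(d11 = 5.1, d12 = 5.1, d21 = 5.1,
                                   d22 = 5.1))
  hs2 <- smooth_histogram(h2)
  nz <- which(hs2$prob > 0)
  expect_equal(length(nz), 81)
  expect_equal(unique(round(hs2$prob[nz], 12)), round(1 / 81, 12))
  expect_equal(sum(hs2$prob), 1, tolerance = 1e-9)
  ## corner mass spreads over 2^4 = 16 cells
  h3 <- build_histogram(data.frame(d11 = 0.1, d12 = 0.1, d21 = 0.1,
                                   d22 = 0.1))
  hs3 <- smooth_histogram(h3)
  expect_equal(sum(hs3$prob > 0), 16)
  expect_equal(sum(hs3$prob), 1, tolerance = 1e-9)
  ## double smoothing is rejected
  expect_error(smooth_histogram(hs2), "already")
})

test_that("side-chain randomization is seed-deterministic and backbone-preserving", {
  s <- make_toy_structure("GANDLE", library = tf_lib())
  r1 <- randomize_side_chains(s, tf_lib(), rng_seed = 5)
  r2 <- randomize_side_chains(s, tf_lib(), rng_seed = 5)
  expect_identical(r1$atoms, r2$atoms)
  bb <- s$atoms$is_backbone
  expect_equal(r1$atoms$x[r1$atoms$is_backbone], s$atoms$x[bb])
  ## Gly untouched; Ala CB rebuilt from backbone geometry (no chi freedom)
  expect_equal(residue_xyz(r1, 1), residue_xyz(s, 1))
  expect_equal(unname(vnorm(atom_xyz(residue_xyz(r1, 2), "CB") -
                              atom_xyz(residue_xyz(r1, 2), "CA"))),
               1.52, tolerance = 1e-6)
  ## single-rotamer library -> output independent of seed
  lib1 <- make_toy_rotamer_library(seed = 1, n_rot = 1)
  a <- randomize_side_chains(s, lib1, rng_seed = 1)
  b <- randomize_side_chains(s, lib1, rng_seed = 99)
  expect_identical(a$atoms, b$atoms)
})

test_that("statistics tables are normalized, deterministic and planted-peaked", {
  tabs <- tf_planted_tables()
  expect_equal(sum(tabs$pair_frequency_real), 1, tolerance = 1e-9)
  expect_equal(sum(tabs$pair_frequency_random), 1, tolerance = 1e-9)
  h <- tabs$real[["ASN|GLN"]]
  expect_equal(sum(h$prob), 1, tolerance = 1e-9)
  pk <- hist_argmax(h)
  pr <- h$prob[pk[1], pk[2], pk[3], pk[4]]
  pq <- tabs$random[["ASN|GLN"]]$prob[pk[1], pk[2], pk[3], pk[4]]
  expect_gt(pr, 3 * pq)
  ## determinism of the whole build
  tabs2 <- quiet(build_statistics(tf_planted()$structures, asn_gln_defs(),
                                  tf_lib(), rng_seed = 2))
  expect_equal(tabs2$real[["ASN|GLN"]]$prob, h$prob)
  expect_equal(tabs2$random[["ASN|GLN"]]$prob,
               tabs$random[["ASN|GLN"]]$prob)
})

test_that("homo-pair tables are invariant to swapping the two residues", {
  ## an Asn-Asn contact with an asymmetric quadruple, fed in both orders
  defs <- data.frame(key = "ASN|ASN", type_a = "ASN", type_b = "ASN",
                     a1 = "ND2", a2 = "OD1", b1 = "ND2", b2 = "OD1",
                     stringsAsFactors = FALSE)
  pc <- make_planted_corpus(type_b = "ASN", atoms_b = c("ND2", "OD1"),
                            quadruple = c(2.75, 3.75, 3.25, 4.25),
                            n_signal = 10, n_noise = 0, jitter = 0, seed = 3)
  mirrored <- lapply(pc$structures, function(s) {
    a <- s$atoms
    a$chain <- ifelse(a$chain == "A", "B", "A")
    a$res_index <- 3 - a$res_index
    new_structure(a[order(a$res_index), ], id = paste0(s$id, "_m"))
  })
  t1 <- quiet(build_statistics(pc$structures, defs, tf_lib(), rng_seed = 1))
  t2 <- quiet(build_statistics(mirrored, defs, tf_lib(), rng_seed = 1))
  expect_equal(t1$real[["ASN|ASN"]]$prob, t2$real[["ASN|ASN"]]$prob)
  ## and scoring a mirrored structure gives the same ScSc term
  s1 <- quiet(score_scsc(pc$structures[[1]], t1))
  s2 <- quiet(score_scsc(mirrored[[1]], t1))
  expect_equal(s1$score, s2$score, tolerance = 1e-9)
})

test_that("statistics containers round-trip bit-exactly", {
  tabs <- tf_planted_tables()
  path <- withr::local_tempfile(fileext = ".rds")
  save_tables(tabs, path)
  tabs2 <- load_tables(path)
  expect_identical(tabs2, tabs)
  saveRDS(list(1), path)
  expect_error(load_tables(path), "container")
})
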
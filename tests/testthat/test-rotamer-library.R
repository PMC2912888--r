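test_that("a toy library file loads, groups and normalizes", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "resid phi psi chi1 chi2 chi3 chi4 sig1 sig2 sig3 sig4 prob",
    "SER -180 -180 62 NA NA NA 9 NA NA NA 0.6",
    "SER -180 -180 -65 NA NA NA 9 NA NA NA 0.4"), path)
  lib <- load_library(path, grid = 360)
  expect_s3_class(lib, "rp_rotlib")
  expect_equal(nrow(lib$entries), 2)
  expect_equal(sum(lib$entries$prob), 1)
  expect_equal(lib$variant, "original")
})

test_that("malformed libraries are rejected; off-sum groups renormalize", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "resid phi psi chi1 chi2 sig1 sig2 prob",
    "SER -180 -180 62 NA 9 NA 1"), path)
  expect_error(load_library(path), "missing column")
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "resid phi psi chi1 chi2 chi3 chi4 sig1 sig2 sig3 sig4 prob",
    "LEU -180 -180 -65 175 NA NA 9 9 NA NA 0.5",
    "LEU -180 -180 -65 NA NA NA 9 9 NA NA 0.5"), path2)
  expect_error(load_library(path2), "missing chi2")
  path3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "resid phi psi chi1 chi2 chi3 chi4 sig1 sig2 sig3 sig4 prob",
    "SER -180 -180 62 NA NA NA 9 NA NA NA 0.3",
    "SER -180 -180 -65 NA NA NA 9 NA NA NA 0.3"), path3)
  expect_error(load_library(path3), "outside")
  path4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "resid phi psi chi1 chi2 chi3 chi4 sig1 sig2 sig3 sig4 prob",
    "SER -180 -180 62 NA NA NA 9 NA NA NA 0.5",
    "SER -180 -180 -65 NA NA NA 9 NA NA NA 0.45"), path4)
  expect_warning(lib4 <- load_library(path4), "renormalized")
  expect_equal(sum(lib4$entries$prob), 1, tolerance = 1e-9)
})

test_that("library text format round-trips through write_library", {
  lib <- tf_lib()
  path <- withr::local_tempfile(fileext = ".txt")
  write_library(lib, path)
  lib2 <- load_library(path, grid = lib$grid)
  expect_equal(lib2$entries$chi1, lib$entries$chi1, tolerance = 1e-9)
  expect_equal(lib2$entries$prob, lib$entries$prob, tolerance = 1e-9)
})

test_that("extension multiplies each rotamer into 3^n offspring", {
  lib <- tf_lib()
  ext <- extend_library(lib)
  e <- lib$entries
  expect_equal(nrow(ext$entries),
               sum(3^vapply(e$resid, function(r) N_CHI[[r]], integer(1))))
  ## a 4-chi residue gives 81 offspring per parent
  n_lys_parent <- sum(e$resid == "LYS")
  expect_equal(sum(ext$entries$resid == "LYS"), 81 * n_lys_parent)
  ## the central offspring carries the largest weight within its family
  key <- group_key(ext$entries$resid, ext$entries$phibin, ext$entries$psibin)
  g1 <- ext$entries[key == key[ext$entries$resid == "SER"][1] &
                      ext$entries$resid == "SER", ]
  parent <- e[e$resid == "SER" & e$phibin == g1$phibin[1] &
                e$psibin == g1$psibin[1], ][1, ]
  fam <- g1[abs(g1$chi1 - parent$chi1) <= parent$sig1 + 1e-9, ]
  central <- fam[which.min(abs(fam$chi1 - parent$chi1)), ]
  expect_true(all(central$prob >= fam$prob - 1e-12))
  ## group normalization preserved
  sums <- tapply(ext$entries$prob, key, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  ## extending a non-original library errors
  expect_error(extend_library(ext), "original")
})

test_that("reduction removes exactly the cumulative tail and renormalizes", {
  g <- data.frame(resid = "SER", phibin = 0, psibin = 0,
                  chi1 = c(60, 180, -60, -175), chi2 = NA_real_,
                  chi3 = NA_real_, chi4 = NA_real_,
                  sig1 = 10, sig2 = NA_real_, sig3 = NA_real_,
                  sig4 = NA_real_,
                  prob = c(0.9, 0.08, 0.015, 0.005))
  lib <- rotlib_new(g, 120)
  red <- reduce_library(lib, 0.03)
  ## 0.015 + 0.005 = 0.02 <= 0.03 removed; adding 0.08 would exceed the tail
  expect_equal(nrow(red$entries), 2)
  expect_equal(sort(red$entries$prob, decreasing = TRUE),
               c(0.9, 0.08) / 0.98, tolerance = 1e-9)
  ## single-rotamer groups survive; tail 0 is the identity
  g1 <- g[1, ]; g1$prob <- 1
  expect_equal(nrow(reduce_library(rotlib_new(g1, 120), 0.5)$entries), 1)
  expect_equal(reduce_library(lib, 0)$entries$prob, g$prob)
  expect_error(reduce_library(lib, 1.2), "tail")
  ## reduced groups are a prefix of the probability-sorted group
  full <- extend_library(tf_lib())
  red2 <- reduce_library(full, 0.03)
  key_f <- group_key(full$entries$resid, full$entries$phibin,
                     full$entries$psibin)
  key_r <- group_key(red2$entries$resid, red2$entries$phibin,
                     red2$entries$psibin)
  k <- key_f[1]
  pf <- sort(full$entries$prob[key_f == k], decreasing = TRUE)
  nr <- sum(key_r == k)
  expect_equal(sort(red2$entries$prob[key_r == k], decreasing = TRUE),
               (pf / sum(pf[seq_len(nr)]))[seq_len(nr)], tolerance = 1e-9)
})

test_that("side chains rebuild to the requested chi angles within 0.01 degrees", {
  for (rt in c("SER", "LEU", "ARG", "TRP", "ILE", "HIS")) {
    chi <- c(-62, 175, -170, 60)[seq_len(N_CHI[[rt]])]
    xyz <- single_residue(rt, chi)
    s <- structure_from_residues(list(
      list(chain = "A", resno = 1, resid = rt, xyz = xyz),
      list(chain = "B", resno = 1, resid = "GLY",
           xyz = build_backbone(NA_real_, NA_real_)[[1]] + 30)))
    expect_equal(measure_chi(s, 1), chi, tolerance = 0.01, label = rt)
  }
  ## Ala: CB placed from backbone, no chi
  cb <- build_side_chain("ALA", c(0, 0, 0), c(1.458, 0, 0),
                         c(2.01, 1.42, 0), numeric(0))
  expect_equal(rownames(cb), "CB")
  expect_equal(vnorm(cb[1, ] - c(1.458, 0, 0)), 1.52, tolerance = 1e-6)
  expect_error(build_side_chain("SER", NULL, c(0, 0, 0), c(1, 0, 0)),
               "backbone")
})

test_that("a Phe ring flipped by 180 in chi2 gives the same atom set", {
  bb <- build_backbone(NA_real_, NA_real_)[[1]]
  r1 <- build_side_chain("PHE", bb["N", ], bb["CA", ], bb["C", ],
                         c(-65, 80))
  r2 <- build_side_chain("PHE", bb["N", ], bb["CA", ], bb["C", ],
                         c(-65, 80 + 180))
  ## name-swapped but geometrically identical ring
  expect_equal(sidechain_rmsd_residue("PHE", r1, r2), 0, tolerance = 1e-6)
  expect_gt(sqrt(mean((r1 - r2)^2)), 0.5)  # raw naming differs
})

test_that("rotamer_group falls back to the nearest populated phi/psi bin", {
  lib <- tf_lib()
  g <- rotamer_group(lib, "SER", NA, NA)
  expect_gt(nrow(g), 0)
  sparse <- lib
  sparse$entries <- lib$entries[!(lib$entries$resid == "SER" &
                                    lib$entries$phibin == 0), ]
  g2 <- rotamer_group(sparse, "SER", -175, -175)
  expect_gt(nrow(g2), 0)
})
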
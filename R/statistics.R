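## Statistics container: real and randomized-reference 4-D histograms plus
## contact-type frequencies, with provenance.

#' Randomize all side chains of a structure
#'
#' Rebuilds every side chain from a rotamer drawn uniformly at random from
#' the residue's backbone-dependent library group: all rotamers are treated
#' equally, ignoring their probabilities and any clashes. The backbone is
#' untouched; Gly is left as is and Ala's CB is rebuilt from backbone
#' geometry. Residues with undefined phi/psi (termini) use the library's
#' fallback bin.
#'
#' @param structure an `rp_structure`.
#' @param library an `rp_rotlib`.
#' @param rng_seed integer seed (NULL uses the current RNG stream).
#' @return the randomized structure.
#' @export
randomize_side_chains <- function(structure, library, rng_seed = NULL) {
  stopifnot(is_structure(structure), is_rotlib(library))
  res <- structure$residues
  build_all <- function() {
    res_list <- lapply(seq_len(nrow(res)), function(i) {
      rt <- res$resid[i]
      xyzm <- residue_xyz(structure, i)
      bb_names <- intersect(rownames(xyzm), BACKBONE_ATOMS)
      bb <- xyzm[bb_names, , drop = FALSE]
      sc <- NULL
      if (rt == "GLY") {
        sc <- NULL
      } else if (rt == "ALA") {
        sc <- build_side_chain(rt, atom_xyz(xyzm, "N"), atom_xyz(xyzm, "CA"),
                               atom_xyz(xyzm, "C"), numeric(0))
      } else {
        grp <- rotamer_group(library, rt, res$phi[i], res$psi[i])
        k <- sample.int(nrow(grp), 1)
        chi <- rotamer_chi(grp[k, , drop = FALSE])
        sc <- build_side_chain(rt, atom_xyz(xyzm, "N"), atom_xyz(xyzm, "CA"),
                               atom_xyz(xyzm, "C"), chi)
      }
      list(chain = res$chain[i], resno = res$resno[i], resid = rt,
           xyz = rbind(bb, sc))
    })
    out <- structure_from_residues(res_list, id = structure$id)
    out$model_index <- structure$model_index
    out$resolution <- structure$resolution
    out
  }
  if (is.null(rng_seed)) build_all() else with_seed(rng_seed, build_all())
}

#' Build the real and randomized-reference contact statistics
#'
#' Harvests four-distance contacts from the corpus (real distribution) and
#' from randomized copies of each corpus structure in which every side
#' chain is a uniformly drawn rotamer (reference distribution), bins them
#' into 4-D histograms per pair type, optionally smooths both, and records
#' contact-type frequencies P(AA) within the ScSc and ScMc families.
#' Homo-type ScSc histograms accumulate both residue orderings of each
#' contact so the stored table is swap-symmetric.
#'
#' @param corpus list of `rp_structure`.
#' @param defs definition table ([select_atom_pairs()]).
#' @param library rotamer library for the randomized reference.
#' @param rng_seed seed for the randomization (determinism contract).
#' @param bin_size,max_distance histogram grid (defaults 0.5 and 10 A).
#' @param smooth smooth both distributions (default TRUE).
#' @param n_random randomized copies per corpus structure (default 1).
#' @param cutoff contact cutoff in Angstrom.
#' @return an `rp_tables` object: per-pair real/random histograms, pair
#'   frequencies, per-pair probability floors and provenance metadata.
#' @export
build_statistics <- function(corpus, defs, library, rng_seed = 1,
                             bin_size = 0.5, max_distance = 10,
                             smooth = TRUE, n_random = 1, cutoff = 5) {
  stopifnot(length(corpus) > 0)
  real_contacts <- do.call(rbind, lapply(corpus, extract_contacts,
                                         defs = defs, cutoff = cutoff))
  rand_contacts <- with_seed(rng_seed, {
    do.call(rbind, lapply(corpus, function(s) {
      do.call(rbind, lapply(seq_len(n_random), function(k) {
        extract_contacts(randomize_side_chains(s, library), defs = defs,
                         cutoff = cutoff)
      }))
    }))
  })
  homo <- defs$key[defs$type_b != "MAINCHAIN" & defs$type_a == defs$type_b]
  hist_set <- function(contacts) {
    out <- list()
    for (k in seq_len(nrow(defs))) {
      key <- defs$key[k]
      sel <- contacts[contacts$key == key, , drop = FALSE]
      if (key %in% homo && nrow(sel) > 0) {
        swapped <- sel
        swapped$d12 <- sel$d21
        swapped$d21 <- sel$d12
        sel <- rbind(sel, swapped)
      }
      h <- build_histogram(sel, bin_size, max_distance, pair_key = key)
      if (smooth && !h$uninformative) h <- smooth_histogram(h)
      out[[key]] <- h
    }
    out
  }
  real_h <- hist_set(real_contacts)
  rand_h <- hist_set(rand_contacts)
  freq_of <- function(contacts) {
    out <- numeric(0)
    for (fam in c("scsc", "scmc")) {
      keys <- defs$key[(defs$type_b == "MAINCHAIN") == (fam == "scmc")]
      cnt <- vapply(keys, function(k) sum(contacts$key == k), numeric(1))
      tot <- sum(cnt)
      out <- c(out, if (tot > 0) cnt / tot else cnt)
    }
    out
  }
  uninformative <- vapply(real_h, function(h) h$uninformative, logical(1))
  if (any(uninformative)) {
    warning("pair(s) with zero real contacts flagged uninformative: ",
            paste(names(real_h)[uninformative], collapse = ", "))
  }
  floors <- vapply(real_h, function(h) {
    if (h$total > 0) 1 / (10 * h$total) else NA_real_
  }, numeric(1))
  structure(list(
    real = real_h, random = rand_h,
    pair_frequency_real = freq_of(real_contacts),
    pair_frequency_random = freq_of(rand_contacts),
    floor_probability = floors,
    defs = defs,
    meta = list(corpus_ids = vapply(corpus, function(s) s$id, character(1)),
                bin_size = bin_size, max_distance = max_distance,
                smooth = smooth, seed = rng_seed, n_random = n_random,
                cutoff = cutoff, library_variant = library$variant)),
    class = "rp_tables")
}

is_tables <- function(x) inherits(x, "rp_tables")

#' @export
print.rp_tables <- function(x, ...) {
  cat(sprintf("<potential tables: %d pair type(s), bin %g A, %s, %d corpus structure(s)>\n",
              length(x$real), x$meta$bin_size,
              if (x$meta$smooth) "smoothed" else "raw",
              length(x$meta$corpus_ids)))
  invisible(x)
}

#' Save / load a statistics container
#'
#' Versioned single-file container (RDS) with bit-exact round trip.
#'
#' @param tables an `rp_tables`.
#' @param path file path.
#' @export
save_tables <- function(tables, path) {
  stopifnot(is_tables(tables))
  saveRDS(list(format = "rotapack-tables", version = 1L, tables = tables),
          path)
  invisible(path)
}

#' @rdname save_tables
#' @export
load_tables <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "rotapack-tables")) {
    stop("not a rotapack statistics container: ", path)
  }
  obj$tables
}
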
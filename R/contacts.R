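## Four-atom contact definitions and contact harvesting. A residue-residue
## interaction is described by 4 distances between a chosen atom pair in
## each residue; two residues are in contact when at least one of the four
## distances is below the cutoff (default 5 A, strict).

## Atom-pair choices for one residue's side: all 2-subsets of its
## side-chain heavy atoms, each sorted lexicographically. Ala has a single
## side-chain atom, so it contributes the (CA, CB) pair, which keeps all 19
## side-chain-bearing types usable (190 ScSc pair types, Gly excluded).
pair_choices <- function(restype) {
  if (restype == "GLY") return(list())
  if (restype == "ALA") return(list(c("CA", "CB")))
  sc <- sidechain_atoms(restype)
  combs <- utils::combn(sc, 2, simplify = FALSE)
  lapply(combs, sort)
}

## Canonical pair key. ScSc: alphabetical type order; ScMc: "<type>|MC".
scsc_key <- function(type_a, type_b) {
  t <- sort(c(type_a, type_b))
  paste(t[1], t[2], sep = "|")
}
scmc_key <- function(type_a) paste(type_a, "MC", sep = "|")

#' All ScSc and ScMc pair types
#'
#' Enumerates the complete interaction-type sets: unordered pairs of the 19
#' side-chain-bearing residue types (190, Gly excluded) and the 18
#' side-chain-to-main-chain types (Gly and Ala excluded).
#'
#' @return list with character vectors `scsc` and `scmc`.
#' @export
all_pair_types <- function() {
  types <- setdiff(AA3, "GLY")
  scsc <- character(0)
  for (i in seq_along(types)) for (j in i:length(types)) {
    scsc <- c(scsc, scsc_key(types[i], types[j]))
  }
  scmc <- vapply(setdiff(types, "ALA"), scmc_key, character(1))
  list(scsc = scsc, scmc = unname(scmc))
}

#' Enumerate candidate 4-atom combinations for a residue-type pair
#'
#' All combinations of one atom pair per residue; for homo-type pairs the
#' two sides are interchangeable and unordered combinations are returned.
#'
#' @param type_a,type_b 3-letter residue types.
#' @return data.frame with columns `a1`, `a2`, `b1`, `b2` (empty when a
#'   type has no usable side-chain pair, i.e. Gly).
#' @export
enumerate_candidates <- function(type_a, type_b) {
  ca <- pair_choices(type_a)
  cb <- pair_choices(type_b)
  empty <- data.frame(a1 = character(0), a2 = character(0),
                      b1 = character(0), b2 = character(0))
  if (length(ca) == 0 || length(cb) == 0) return(empty)
  rows <- list()
  for (p in ca) for (q in cb) {
    if (type_a == type_b) {
      lab_p <- paste(p, collapse = ","); lab_q <- paste(q, collapse = ",")
      if (lab_p > lab_q) next
    }
    rows[[length(rows) + 1]] <- data.frame(a1 = p[1], a2 = p[2],
                                           b1 = q[1], b2 = q[2],
                                           stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## Is residue pair (i, j) excluded as sequence neighbours? Contacts between
## residues closer than 2 positions in the same chain are geometry-
## constrained, not interaction-driven, and are excluded throughout.
seq_excluded <- function(res, i, j) {
  res$chain[i] == res$chain[j] && abs(i - j) < 2
}

quad_dist <- function(A1, A2, B1, B2) {
  c(vnorm(A1 - B1), vnorm(A1 - B2), vnorm(A2 - B1), vnorm(A2 - B2))
}

#' Select contact atom pairs by maximal contact count ("Atom Set 1")
#'
#' For every residue-type pair observed in the corpus, counts, over all
#' candidate 4-atom combinations, the residue pairs with at least one of
#' the four distances below `cutoff`, and selects the combination with the
#' maximal count (ties broken by lexicographic atom-name order). With
#' `kind = "scmc"` the side-chain pair is selected against the backbone
#' (O, N) pair of partner residues.
#'
#' @param corpus list of `rp_structure`.
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @param kind `"scsc"`, `"scmc"` or `"both"`.
#' @return data.frame of definitions: `key`, `type_a`, `type_b`, `a1`,
#'   `a2`, `b1`, `b2`; pairs with zero contacts are omitted with a warning.
#' @export
select_atom_pairs <- function(corpus, cutoff = 5, kind = c("both", "scsc", "scmc")) {
  kind <- match.arg(kind)
  stopifnot(length(corpus) > 0)
  counts <- new.env(parent = emptyenv())
  bump <- function(key, combo_label) {
    cur <- if (!is.null(counts[[key]])) counts[[key]] else integer(0)
    cur[combo_label] <- if (combo_label %in% names(cur))
      cur[[combo_label]] + 1L else 1L
    counts[[key]] <- cur
  }
  cand_cache <- list()
  for (s in corpus) {
    res <- s$residues
    n <- nrow(res)
    xyzs <- lapply(seq_len(n), function(i) residue_xyz(s, i))
    if (kind %in% c("both", "scsc")) {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j <= i || seq_excluded(res, i, j)) next
        ta <- res$resid[i]; tb <- res$resid[j]
        key <- scsc_key(ta, tb)
        ## orient so the first residue carries the alphabetically first type
        if (ta <= tb) { ii <- i; jj <- j } else { ii <- j; jj <- i }
        ck <- key
        if (is.null(cand_cache[[ck]])) {
          cand_cache[[ck]] <- enumerate_candidates(res$resid[ii], res$resid[jj])
        }
        cand <- cand_cache[[ck]]
        if (is.null(cand) || nrow(cand) == 0) next
        for (r in seq_len(nrow(cand))) {
          A1 <- atom_xyz(xyzs[[ii]], cand$a1[r])
          A2 <- atom_xyz(xyzs[[ii]], cand$a2[r])
          B1 <- atom_xyz(xyzs[[jj]], cand$b1[r])
          B2 <- atom_xyz(xyzs[[jj]], cand$b2[r])
          if (is.null(A1) || is.null(A2) || is.null(B1) || is.null(B2)) next
          if (min(quad_dist(A1, A2, B1, B2)) < cutoff) {
            bump(key, paste(cand$a1[r], cand$a2[r], cand$b1[r], cand$b2[r]))
          }
        }
      }
    }
    if (kind %in% c("both", "scmc")) {
      for (i in seq_len(n)) {
        ta <- res$resid[i]
        if (ta %in% c("GLY", "ALA")) next
        choices <- pair_choices(ta)
        for (j in seq_len(n)) {
          if (j == i || seq_excluded(res, i, j)) next
          B1 <- atom_xyz(xyzs[[j]], "O"); B2 <- atom_xyz(xyzs[[j]], "N")
          if (is.null(B1) || is.null(B2)) next
          for (p in choices) {
            A1 <- atom_xyz(xyzs[[i]], p[1]); A2 <- atom_xyz(xyzs[[i]], p[2])
            if (is.null(A1) || is.null(A2)) next
            if (min(quad_dist(A1, A2, B1, B2)) < cutoff) {
              bump(scmc_key(ta), paste(p[1], p[2], "O", "N"))
            }
          }
        }
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) {
    warning("no contacts found in corpus; empty definition set")
    return(data.frame(key = character(0), type_a = character(0),
                      type_b = character(0), a1 = character(0),
                      a2 = character(0), b1 = character(0),
                      b2 = character(0)))
  }
  rows <- lapply(keys, function(key) {
    cnt <- counts[[key]]
    best <- names(cnt)[order(-cnt, names(cnt))][1]
    parts <- strsplit(best, " ")[[1]]
    tp <- strsplit(key, "|", fixed = TRUE)[[1]]
    data.frame(key = key, type_a = tp[1],
               type_b = if (tp[2] == "MC") "MAINCHAIN" else tp[2],
               a1 = parts[1], a2 = parts[2], b1 = parts[3], b2 = parts[4],
               n_contacts = as.integer(cnt[[best]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract four-distance contacts from a structure
#'
#' One record per unique contacting residue pair per definition. Residues
#' fewer than 2 positions apart in the same chain are excluded; hetero-type
#' pairs are oriented to match the definition, homo-type pairs put the
#' lower-index residue first (the statistics builder additionally
#' symmetrizes homo-pair histograms). Residue pairs with required contact
#' atoms missing (truncated side chains) are skipped with a message.
#'
#' @param structure an `rp_structure`.
#' @param defs definition table from [select_atom_pairs()] (or hand-built).
#' @param cutoff contact cutoff in Angstrom (strict `<`, default 5).
#' @return data.frame: `key`, `kind`, `i`, `j`, `d11`, `d12`, `d21`, `d22`.
#' @export
extract_contacts <- function(structure, defs, cutoff = 5) {
  stopifnot(is_structure(structure), is.data.frame(defs))
  res <- structure$residues
  n <- nrow(res)
  xyzs <- lapply(seq_len(n), function(i) residue_xyz(structure, i))
  def_scsc <- defs[defs$type_b != "MAINCHAIN", , drop = FALSE]
  def_scmc <- defs[defs$type_b == "MAINCHAIN", , drop = FALSE]
  out <- list()
  n_skipped <- 0L
  add <- function(key, kind, i, j, q) {
    out[[length(out) + 1]] <<- data.frame(
      key = key, kind = kind, i = i, j = j,
      d11 = q[1], d12 = q[2], d21 = q[3], d22 = q[4],
      stringsAsFactors = FALSE)
  }
  if (nrow(def_scsc) > 0) {
    dmap <- split(seq_len(nrow(def_scsc)), def_scsc$key)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i || seq_excluded(res, i, j)) next
      ta <- res$resid[i]; tb <- res$resid[j]
      key <- scsc_key(ta, tb)
      ridx <- dmap[[key]]
      if (is.null(ridx)) next
      d <- def_scsc[ridx[1], ]
      ## orientation: residue matching type_a goes first; homo pairs keep
      ## the lower index first
      if (ta == d$type_a) { ii <- i; jj <- j } else { ii <- j; jj <- i }
      A1 <- atom_xyz(xyzs[[ii]], d$a1); A2 <- atom_xyz(xyzs[[ii]], d$a2)
      B1 <- atom_xyz(xyzs[[jj]], d$b1); B2 <- atom_xyz(xyzs[[jj]], d$b2)
      if (is.null(A1) || is.null(A2) || is.null(B1) || is.null(B2)) {
        n_skipped <- n_skipped + 1L
        next
      }
      q <- quad_dist(A1, A2, B1, B2)
      if (min(q) < cutoff) add(key, "scsc", ii, jj, q)
    }
  }
  if (nrow(def_scmc) > 0) {
    dmap <- split(seq_len(nrow(def_scmc)), def_scmc$type_a)
    for (i in seq_len(n)) {
      ridx <- dmap[[res$resid[i]]]
      if (is.null(ridx)) next
      d <- def_scmc[ridx[1], ]
      A1 <- atom_xyz(xyzs[[i]], d$a1); A2 <- atom_xyz(xyzs[[i]], d$a2)
      if (is.null(A1) || is.null(A2)) {
        n_skipped <- n_skipped + 1L
        next
      }
      for (j in seq_len(n)) {
        if (j == i || seq_excluded(res, i, j)) next
        B1 <- atom_xyz(xyzs[[j]], d$b1); B2 <- atom_xyz(xyzs[[j]], d$b2)
        if (is.null(B1) || is.null(B2)) next
        q <- quad_dist(A1, A2, B1, B2)
        if (min(q) < cutoff) add(d$key, "scmc", i, j, q)
      }
    }
  }
  if (n_skipped > 0) {
    message(n_skipped, " residue pair(s) skipped: required contact atoms missing")
  }
  if (length(out) == 0) {
    return(data.frame(key = character(0), kind = character(0),
                      i = integer(0), j = integer(0), d11 = numeric(0),
                      d12 = numeric(0), d21 = numeric(0), d22 = numeric(0)))
  }
  do.call(rbind, out)
}
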
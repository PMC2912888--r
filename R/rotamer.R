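## Backbone-dependent rotamer library: loading from a documented text
## format, the extended (3^n, +/- one sigma) and reduced (cumulative-tail)
## variants, and side-chain construction from chi angles.

rotlib_new <- function(entries, grid, variant = "original") {
  stopifnot(is.data.frame(entries))
  structure(list(grid = grid, entries = entries, variant = variant),
            class = "rp_rotlib")
}

is_rotlib <- function(x) inherits(x, "rp_rotlib")

#' @export
print.rp_rotlib <- function(x, ...) {
  cat(sprintf("<rotamer library: %s, %d entries, %d residue type(s), %g deg grid>\n",
              x$variant, nrow(x$entries), length(unique(x$entries$resid)),
              x$grid))
  invisible(x)
}

## phi/psi angle -> integer bin index 0..(360/grid - 1).
phipsi_bin <- function(angle, grid) {
  a <- ((angle + 180) %% 360)
  pmin(as.integer(floor(a / grid)), as.integer(360 / grid) - 1L)
}

group_key <- function(resid, phibin, psibin) {
  paste(resid, phibin, psibin, sep = "|")
}

#' Load a backbone-dependent rotamer library from tabular text
#'
#' Format: whitespace-separated columns `resid phi psi chi1 chi2 chi3 chi4
#' sig1 sig2 sig3 sig4 prob` with a header line; `phi`/`psi` are the lower
#' edges of the phi/psi bin in degrees; unused chi columns hold NA. Within
#' each (residue type, phi bin, psi bin) group probabilities are normalized
#' to 1 (with a warning if they did not already sum to 1); groups whose raw
#' probabilities sum outside [0.9, 1.1] are rejected as malformed.
#'
#' @param path library file.
#' @param grid phi/psi bin width in degrees (default 10).
#' @return an `rp_rotlib` with `variant = "original"`.
#' @export
load_library <- function(path, grid = 10) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("resid", "phi", "psi", paste0("chi", 1:4), paste0("sig", 1:4),
            "prob")
  if (!all(need %in% names(tab))) {
    stop("rotamer library format error: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  bad_type <- setdiff(unique(tab$resid), AA3)
  if (length(bad_type)) {
    stop("rotamer library format error: unknown residue type(s) ",
         paste(bad_type, collapse = ", "))
  }
  nchi <- N_CHI[tab$resid]
  chi <- as.matrix(tab[, paste0("chi", 1:4)])
  for (k in 1:4) {
    need_k <- nchi >= k
    if (any(need_k & is.na(chi[, k]))) {
      stop("rotamer library format error: missing chi", k,
           " for residue(s) requiring it")
    }
  }
  tab$phibin <- phipsi_bin(tab$phi, grid)
  tab$psibin <- phipsi_bin(tab$psi, grid)
  key <- group_key(tab$resid, tab$phibin, tab$psibin)
  sums <- tapply(tab$prob, key, sum)
  if (any(sums < 0.9 | sums > 1.1)) {
    stop("rotamer library format error: group probabilities sum outside [0.9, 1.1]")
  }
  if (any(abs(sums - 1) > 1e-6)) {
    warning("rotamer group probabilities renormalized to 1")
  }
  tab$prob <- tab$prob / as.numeric(sums[key])
  entries <- tab[, c("resid", "phibin", "psibin", paste0("chi", 1:4),
                     paste0("sig", 1:4), "prob")]
  rownames(entries) <- NULL
  rotlib_new(entries, grid, "original")
}

#' Extend a rotamer library by one-sigma chi excursions
#'
#' Every rotamer with n chi angles is replaced by 3^n offspring taking each
#' chi at {chi - sigma, chi, chi + sigma}. Offspring probabilities follow a
#' normal density around the tabulated chi: per angle the three points get
#' weights proportional to exp(0), exp(-1/2), exp(-1/2) (renormalized), and
#' the parent's probability multiplies the product over angles.
#'
#' @param lib an original-variant `rp_rotlib`.
#' @return the extended library.
#' @export
extend_library <- function(lib) {
  stopifnot(is_rotlib(lib))
  if (lib$variant != "original") {
    stop("extend_library requires an original-variant library")
  }
  w_center <- 1 / (1 + 2 * exp(-0.5))
  w_side <- exp(-0.5) / (1 + 2 * exp(-0.5))
  e <- lib$entries
  out <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    n <- N_CHI[[e$resid[i]]]
    if (n == 0) {
      out[[i]] <- e[i, , drop = FALSE]
      next
    }
    offs <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), n)))
    chi <- as.numeric(e[i, paste0("chi", 1:4)])
    sig <- as.numeric(e[i, paste0("sig", 1:4)])
    w <- apply(offs, 1, function(k) prod(ifelse(k == 0, w_center, w_side)))
    kid <- e[rep(i, nrow(offs)), , drop = FALSE]
    for (k in seq_len(n)) {
      kid[[paste0("chi", k)]] <- chi[k] + offs[, k] * sig[k]
    }
    kid$prob <- e$prob[i] * w
    out[[i]] <- kid
  }
  entries <- do.call(rbind, out)
  rownames(entries) <- NULL
  ## per-parent weights already sum to 1; renormalize groups for safety
  key <- group_key(entries$resid, entries$phibin, entries$psibin)
  sums <- tapply(entries$prob, key, sum)
  entries$prob <- entries$prob / as.numeric(sums[key])
  rotlib_new(entries, lib$grid, "extended")
}

#' Reduce a rotamer library by discarding a low-probability tail
#'
#' Within each (residue type, phi/psi bin) group rotamers are ranked by
#' probability and the largest low-probability suffix whose cumulative
#' probability does not exceed `tail` is discarded; survivors are
#' renormalized. At least one rotamer is always kept.
#'
#' @param lib an `rp_rotlib` (any variant).
#' @param tail cumulative probability to discard (default 0.03).
#' @return the reduced library.
#' @export
reduce_library <- function(lib, tail = 0.03) {
  stopifnot(is_rotlib(lib))
  if (!is.numeric(tail) || tail < 0 || tail >= 1) {
    stop("tail must be in [0, 1)")
  }
  e <- lib$entries
  key <- group_key(e$resid, e$phibin, e$psibin)
  keep <- unlist(lapply(split(seq_len(nrow(e)), key), function(idx) {
    p <- e$prob[idx]
    ord <- order(p, decreasing = TRUE)
    csum_from_end <- rev(cumsum(rev(p[ord])))
    ## drop the suffix whose cumulative mass is <= tail, keeping >= 1
    drop <- csum_from_end <= tail + 1e-12
    drop[1] <- FALSE
    idx[ord[!drop]]
  }), use.names = FALSE)
  entries <- e[sort(keep), , drop = FALSE]
  key2 <- group_key(entries$resid, entries$phibin, entries$psibin)
  sums <- tapply(entries$prob, key2, sum)
  entries$prob <- entries$prob / as.numeric(sums[key2])
  rownames(entries) <- NULL
  rotlib_new(entries, lib$grid, "reduced")
}

## Fallback phi/psi for residues whose backbone dihedrals are undefined
## (chain termini): extended-strand region.
PHI_FALLBACK <- -120
PSI_FALLBACK <- 140

#' Rotamer group for a residue type at given backbone dihedrals
#'
#' Returns the library entries of the (residue type, phi/psi bin) group.
#' Undefined dihedrals (termini) fall back to the extended-strand region;
#' if the exact bin holds no entries the nearest populated bin (toroidal
#' phi/psi distance) is used.
#'
#' @param lib an `rp_rotlib`.
#' @param restype 3-letter residue type.
#' @param phi,psi backbone dihedrals in degrees (NA allowed).
#' @return data.frame of rotamers (rows of the library's entry table).
#' @export
rotamer_group <- function(lib, restype, phi, psi) {
  stopifnot(is_rotlib(lib))
  if (is.na(phi)) phi <- PHI_FALLBACK
  if (is.na(psi)) psi <- PSI_FALLBACK
  pb <- phipsi_bin(phi, lib$grid)
  qb <- phipsi_bin(psi, lib$grid)
  e <- lib$entries
  sel <- e$resid == restype & e$phibin == pb & e$psibin == qb
  if (!any(sel)) {
    cand <- e[e$resid == restype, , drop = FALSE]
    if (nrow(cand) == 0) stop("library covers no rotamers for ", restype)
    nbin <- as.integer(360 / lib$grid)
    tor <- function(a, b) pmin((a - b) %% nbin, (b - a) %% nbin)
    d <- tor(cand$phibin, pb)^2 + tor(cand$psibin, qb)^2
    best <- cand[cand$phibin == cand$phibin[which.min(d)] &
                 cand$psibin == cand$psibin[which.min(d)], , drop = FALSE]
    return(best)
  }
  e[sel, , drop = FALSE]
}

## chi vector (length N_CHI[restype]) from one entry row.
rotamer_chi <- function(entry) {
  n <- N_CHI[[entry$resid[1]]]
  if (n == 0) return(numeric(0))
  as.numeric(entry[1, paste0("chi", seq_len(n))])
}

#' Build side-chain heavy-atom coordinates from chi angles
#'
#' Sequential internal-coordinate construction using the package's ideal
#' bond lengths and angles. Recomputing chi from the built coordinates
#' returns the input within 0.01 degrees.
#'
#' @param restype 3-letter residue type.
#' @param N,CA,C backbone coordinates (numeric 3-vectors).
#' @param chi numeric vector of chi angles in degrees (length `N_CHI`).
#' @return matrix of side-chain coordinates (rownames = atom names); a
#'   0-row matrix for Gly.
#' @export
build_side_chain <- function(restype, N, CA, C, chi = numeric(0)) {
  if (is.null(N) || is.null(CA) || is.null(C)) {
    stop("missing backbone atom(s) for side-chain build")
  }
  z <- SIDECHAIN_ZMAT[[restype]]
  if (is.null(z)) stop("unknown residue type: ", restype)
  if (length(chi) < N_CHI[[restype]]) {
    stop("need ", N_CHI[[restype]], " chi angle(s) for ", restype)
  }
  coords <- list(N = N, CA = CA, C = C)
  for (row in z) {
    tor <- row$tor
    if (is.character(tor)) {
      m <- regmatches(tor, regexec("^chi([1-4])([+-][0-9.]+)?$", tor))[[1]]
      k <- as.integer(m[2])
      off <- if (m[3] == "") 0 else as.numeric(m[3])
      tor <- chi[k] + off
    }
    coords[[row$atom]] <- place_atom(coords[[row$a]], coords[[row$b]],
                                     coords[[row$c]], row$bond, row$angle,
                                     tor)
  }
  nm <- vapply(z, function(r) r$atom, character(1))
  out <- do.call(rbind, coords[nm])
  if (is.null(out)) out <- matrix(numeric(0), ncol = 3)
  rownames(out) <- nm
  colnames(out) <- c("x", "y", "z")
  out
}

## Rebuild the side chain of residue `res_index` in a structure from a
## library entry row (or an explicit chi vector). Gly is left untouched;
## Ala's CB is rebuilt from backbone geometry.
set_rotamer <- function(s, res_index, chi) {
  restype <- s$residues$resid[res_index]
  if (restype == "GLY") return(s)
  xyzm <- residue_xyz(s, res_index)
  coords <- build_side_chain(restype, atom_xyz(xyzm, "N"),
                             atom_xyz(xyzm, "CA"), atom_xyz(xyzm, "C"), chi)
  replace_sidechain(s, res_index, coords)
}
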
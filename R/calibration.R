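## Calibration: LJ radii from observed contact-distance distributions, and
## term weights by a hierarchical lambda sweep.

#' Detect atoms in direct contact
#'
#' Two heavy atoms are in direct contact when the gap between their van der
#' Waals surfaces is below twice the probe radius and no third atom's
#' surface occludes the segment between their centers (perpendicular
#' distance from the third atom to the segment below its vdW radius, with
#' the projection inside the segment). Main chain-main chain pairs are
#' included. Symmetric in the pair.
#'
#' @param corpus list of classified `rp_structure`s.
#' @param probe_radius probe radius in Angstrom (default 1.0).
#' @return data.frame: `class_a`, `class_b` (sorted), `d` (distance in
#'   Angstrom); empty for an empty corpus.
#' @export
detect_direct_contacts <- function(corpus, probe_radius = 1.0) {
  out <- list()
  for (s in corpus) {
    a <- s$atoms
    known <- !is.na(a$lj_class) & a$lj_class != "unclassified"
    a <- a[known, , drop = FALSE]
    if (nrow(a) < 2) next
    xyz <- as.matrix(a[, c("x", "y", "z")])
    rad <- vdw_radius(a$element)
    dm <- as.matrix(stats::dist(xyz))
    pair <- which(upper.tri(dm), arr.ind = TRUE)
    i <- pair[, 1]; j <- pair[, 2]
    gap <- dm[cbind(i, j)] - rad[i] - rad[j]
    sel <- gap < 2 * probe_radius & a$res_index[i] != a$res_index[j]
    i <- i[sel]; j <- j[sel]
    for (k in seq_along(i)) {
      p <- xyz[i[k], ]; q <- xyz[j[k], ]
      u <- q - p
      len2 <- sum(u * u)
      occluded <- FALSE
      for (m in seq_len(nrow(a))) {
        if (m == i[k] || m == j[k]) next
        t0 <- sum((xyz[m, ] - p) * u) / len2
        if (t0 <= 0 || t0 >= 1) next
        perp <- vnorm(xyz[m, ] - (p + t0 * u))
        if (perp < rad[m]) {
          occluded <- TRUE
          break
        }
      }
      if (!occluded) {
        cls <- sort(c(a$lj_class[i[k]], a$lj_class[j[k]]))
        out[[length(out) + 1]] <- data.frame(
          class_a = cls[1], class_b = cls[2], d = dm[i[k], j[k]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(class_a = character(0), class_b = character(0),
                      d = numeric(0)))
  }
  do.call(rbind, out)
}

#' Build per-class-pair contact-distance distributions
#'
#' Bins direct-contact distances per (sorted) class pair with a 0.05 A
#' histogram; the peak is the mode after a 3-bin moving average. Pairs with
#' fewer than `min_count` observations are flagged insufficient.
#'
#' @param contacts data.frame from [detect_direct_contacts()] (or an
#'   equivalent with columns `class_a`, `class_b`, `d`).
#' @param bin histogram bin in Angstrom.
#' @param min_count sufficiency threshold (default 10000, the corpus-scale
#'   rule; lower it for synthetic data).
#' @return data.frame: `class_a`, `class_b`, `peak`, `count`,
#'   `sufficient`.
#' @export
contact_distance_distributions <- function(contacts, bin = 0.05,
                                           min_count = 10000) {
  key <- paste(contacts$class_a, contacts$class_b, sep = "|")
  rows <- lapply(split(seq_len(nrow(contacts)), key), function(idx) {
    d <- contacts$d[idx]
    brk <- seq(0, max(d) + bin, by = bin)
    h <- graphics::hist(d, breaks = brk, plot = FALSE)
    cnt <- h$counts
    sm <- stats::filter(cnt, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- cnt[is.na(sm)]
    peak <- h$mids[which.max(sm)]
    data.frame(class_a = contacts$class_a[idx[1]],
               class_b = contacts$class_b[idx[1]],
               peak = peak, count = length(idx),
               sufficient = length(idx) >= min_count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit per-class LJ radii from contact-distance peaks
#'
#' Least-squares fit of the 20 class radii so that `r_i + r_j` reproduces
#' the observed peak distance of each retained class pair. Insufficient
#' pairs are dropped; polar-polar pairs are excluded from the radius fit
#' (hydrogen bonding shortens them) but their peaks are recorded as
#' pair-specific optimal-distance overrides.
#'
#' @param distributions data.frame from
#'   [contact_distance_distributions()].
#' @param polar named logical vector over classes (see
#'   [load_lj_params()]).
#' @return list: `radius` (named numeric over fitted classes), `overrides`
#'   (data.frame `class_a`, `class_b`, `rmin`), `retained` (pairs used).
#' @export
fit_lj_radii <- function(distributions, polar) {
  d <- distributions[distributions$sufficient, , drop = FALSE]
  if (nrow(d) == 0) stop("no sufficient contact-distance distributions")
  pp <- polar[d$class_a] & polar[d$class_b]
  overrides <- data.frame(class_a = d$class_a[pp], class_b = d$class_b[pp],
                          rmin = d$peak[pp], stringsAsFactors = FALSE)
  fitset <- d[!pp, , drop = FALSE]
  classes <- sort(unique(c(fitset$class_a, fitset$class_b)))
  missing_cls <- setdiff(unique(c(d$class_a, d$class_b)), classes)
  if (length(missing_cls) > 0) {
    stop("class(es) with no retained non-polar-polar pair: ",
         paste(missing_cls, collapse = ", "))
  }
  A <- matrix(0, nrow(fitset), length(classes),
              dimnames = list(NULL, classes))
  for (r in seq_len(nrow(fitset))) {
    A[r, fitset$class_a[r]] <- A[r, fitset$class_a[r]] + 1
    A[r, fitset$class_b[r]] <- A[r, fitset$class_b[r]] + 1
  }
  if (qr(A)$rank < length(classes)) {
    stop("contact-distance design is rank-deficient; more pair types needed")
  }
  fit <- stats::lm.fit(A, fitset$peak)
  radius <- fit$coefficients
  list(radius = radius, overrides = overrides, retained = fitset)
}

#' Fit term weights by a hierarchical lambda sweep
#'
#' Three sequential sweeps of lambda over [0, 1] in 0.05 steps: first
#' `E = lambda E_rot + (1 - lambda) E_lj`, then the ScSc term against the
#' rot+LJ block treated as one, then the ScMc term against the rest. The
#' objective (default: mean side-chain RMSD of repacked training structures
#' against their natives) is evaluated on the identical structure list at
#' every lambda.
#'
#' @param training list of native `rp_structure`s (classified).
#' @param tables,library,params potential inputs.
#' @param rng_seed seed (each objective evaluation derives its packing
#'   seeds from it).
#' @param config packing configuration for the objective evaluations.
#' @param objective optional function(weights) -> numeric, replacing the
#'   repack-RMSD objective (used for testing the sweep machinery).
#' @param grid lambda grid (default `seq(0, 1, 0.05)`).
#' @return a `potential_weights()` vector.
#' @export
fit_weights <- function(training = NULL, tables = NULL, library = NULL,
                        params = NULL, rng_seed = 1,
                        config = mcsa_config(cooling_steps = 20,
                                             moves_per_step = 200,
                                             rng_seed = rng_seed),
                        objective = NULL, grid = seq(0, 1, by = 0.05)) {
  if (is.null(objective)) {
    stopifnot(length(training) >= 1)
    objective <- function(w) {
      vals <- vapply(seq_along(training), function(t) {
        s <- training[[t]]
        sc <- potential_scorer(s, tables, library, params, w)
        cfg <- config
        cfg$rng_seed <- rng_seed + t
        res <- tryCatch(mcsa_pack(sc, cfg), error = function(e) NULL)
        if (is.null(res) || is.null(res$structure)) return(NA_real_)
        sidechain_rmsd(res$structure, s)
      }, numeric(1))
      if (all(is.na(vals))) stop("packing failed on every training structure")
      mean(vals, na.rm = TRUE)
    }
  }
  sweep1 <- function(make_w) {
    obj <- vapply(grid, function(l) objective(make_w(l)), numeric(1))
    grid[which.min(obj)]
  }
  ## step 1: rot vs LJ
  l1 <- sweep1(function(l) potential_weights(0, 0, l, 1 - l))
  ## step 2: ScSc vs the (rot, LJ) block
  l2 <- sweep1(function(l) potential_weights(l, 0, (1 - l) * l1,
                                             (1 - l) * (1 - l1)))
  ## step 3: ScMc vs the rest
  l3 <- sweep1(function(l) potential_weights((1 - l) * l2, l,
                                             (1 - l) * (1 - l2) * l1,
                                             (1 - l) * (1 - l2) * (1 - l1)))
  potential_weights((1 - l3) * l2, l3, (1 - l3) * (1 - l2) * l1,
                    (1 - l3) * (1 - l2) * (1 - l1))
}
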
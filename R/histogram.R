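## Four-dimensional distance histograms with box smoothing.

#' Build a 4-D distance histogram from contact records
#'
#' Bins the (d11, d12, d21, d22) quadruples on a regular grid (default
#' 0.5 A bins from 0 to 10 A, i.e. 20^4 cells). Distances at or beyond
#' `max_distance` are clamped into the last bin, so a contact is never
#' dropped for exceeding the range on its non-triggering distances.
#'
#' @param contacts data.frame with columns `d11`, `d12`, `d21`, `d22` (as
#'   from [extract_contacts()]); extra columns ignored.
#' @param bin_size bin width in Angstrom; must divide `max_distance`.
#' @param max_distance histogram range in Angstrom.
#' @param pair_key optional label stored with the histogram.
#' @return an `rp_hist4d`: counts, probabilities (summing to 1 when any
#'   contact was binned), total count, and an `uninformative` flag for the
#'   empty case.
#' @export
build_histogram <- function(contacts, bin_size = 0.5, max_distance = 10,
                            pair_key = NULL) {
  nbin <- max_distance / bin_size
  if (abs(nbin - round(nbin)) > 1e-9) {
    stop("bin_size must divide max_distance")
  }
  nbin <- as.integer(round(nbin))
  counts <- array(0L, dim = rep(nbin, 4))
  total <- nrow(contacts)
  if (total > 0) {
    q <- as.matrix(contacts[, c("d11", "d12", "d21", "d22")])
    idx <- pmin(floor(q / bin_size), nbin - 1)  # clamp into last bin
    idx[idx < 0] <- 0
    lin <- 1 + idx[, 1] + nbin * (idx[, 2] + nbin * (idx[, 3] + nbin * idx[, 4]))
    tab <- tabulate(lin, nbins = nbin^4)
    counts <- array(tab, dim = rep(nbin, 4))
  }
  prob <- if (total > 0) counts / total else array(0, dim = rep(nbin, 4))
  structure(list(pair_key = pair_key, bin_size = bin_size,
                 max_distance = max_distance, counts = counts, prob = prob,
                 total = total, smoothed = FALSE,
                 uninformative = total == 0),
            class = "rp_hist4d")
}

#' @export
print.rp_hist4d <- function(x, ...) {
  cat(sprintf("<4-D histogram%s: %d^4 bins of %g A, %d contact(s)%s%s>\n",
              if (!is.null(x$pair_key)) paste0(" ", x$pair_key) else "",
              dim(x$counts)[1], x$bin_size, x$total,
              if (x$smoothed) ", smoothed" else "",
              if (x$uninformative) ", uninformative" else ""))
  invisible(x)
}

## Truncated 3-point box sum along one axis of a 4-D array.
boxsum_axis <- function(a, axis) {
  perm <- c(axis, setdiff(1:4, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- matrix(ap, d[1], prod(d[-1]))
  y <- m
  if (d[1] > 1) {
    y[1:(d[1] - 1), ] <- y[1:(d[1] - 1), , drop = FALSE] + m[2:d[1], , drop = FALSE]
    y[2:d[1], ] <- y[2:d[1], , drop = FALSE] + m[1:(d[1] - 1), , drop = FALSE]
  }
  aperm(array(y, d), order(perm))
}

#' Smooth a 4-D histogram by neighbourhood averaging
#'
#' Each cell is replaced by the mean over its full 3^4 Chebyshev-1
#' neighbourhood (the cell and all adjacent cells), truncated at the grid
#' boundaries (boundary cells average over fewer neighbours), and the
#' result is renormalized to total mass 1. Smoothing an already-smoothed
#' histogram is an error.
#'
#' @param hist an `rp_hist4d` with normalized probabilities.
#' @return the smoothed histogram (counts retained, `smoothed` flag set).
#' @export
smooth_histogram <- function(hist) {
  stopifnot(inherits(hist, "rp_hist4d"))
  if (hist$smoothed) stop("histogram is already smoothed")
  num <- hist$prob
  den <- array(1, dim = dim(hist$prob))
  for (ax in 1:4) {
    num <- boxsum_axis(num, ax)
    den <- boxsum_axis(den, ax)
  }
  sm <- num / den
  tot <- sum(sm)
  if (tot > 0) sm <- sm / tot
  out <- hist
  out$prob <- sm
  out$smoothed <- TRUE
  out
}

## Linear bin lookup of one quadruple in a histogram.
hist_prob_at <- function(h, q) {
  nbin <- dim(h$prob)[1]
  idx <- pmin(pmax(floor(q / h$bin_size), 0), nbin - 1) + 1
  h$prob[idx[1], idx[2], idx[3], idx[4]]
}

## Index (4-vector, 1-based) of the most populated cell.
hist_argmax <- function(h) {
  arrayInd(which.max(h$prob), dim(h$prob))[1, ]
}
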
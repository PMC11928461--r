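# Internal helpers shared across modules.

# Classed error so callers can distinguish failure modes programmatically.
stop_guv <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "guvphase_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_guv("guvphase_parameter_error", sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop_guv("guvphase_parameter_error", sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0)
    stop_guv("guvphase_parameter_error", sprintf("`%s` must be >= 0", name))
  invisible(x)
}

#' Otsu threshold with deterministic tie handling
#'
#' Histogram-based Otsu threshold on 256 bins spanning the data range. The
#' binning is anchored to the range, so adding a constant to every pixel
#' shifts the threshold by exactly that constant (shift equivariance). Ties in
#' the between-class variance are broken toward the lower threshold.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins number of histogram bins.
#' @return scalar threshold; foreground is `x > threshold`.
#' @keywords internal
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!is.finite(rng[1]) || rng[1] == rng[2])
    stop_guv("guvphase_no_foreground", "image has no intensity variation; cannot threshold")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(as.numeric(counts))   # numeric: wb*wf overflows integers on large images
  m1 <- cumsum(counts * mids)
  total <- w1[n_bins]
  mu <- m1[n_bins]
  # between-class variance for split after bin k (k = 1..n_bins-1)
  k <- seq_len(n_bins - 1L)
  wb <- w1[k]; wf <- total - wb
  valid <- wb > 0 & wf > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu * wb[valid] / total - m1[k][valid])^2 /
    (wb[valid] * wf[valid]) * total^2
  if (!any(is.finite(bcv)))
    stop_guv("guvphase_no_foreground", "degenerate histogram; cannot threshold")
  k_star <- which.max(bcv)          # which.max takes the first (lowest) maximum
  breaks[k_star + 1L]               # upper edge of the background class
}

# Two-pass 8-connected component labelling (union-find).  EBImage::bwlabel is
# 4-connected, whereas condensate counting here requires 8-connectivity.
label_components8 <- function(flags) {
  nr <- nrow(flags); nc <- ncol(flags)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  next_label <- 0L
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (!flags[rr, cc]) next
      # previously-visited 8-neighbours in column-major order
      nbr <- integer(0)
      if (rr > 1L && labels[rr - 1L, cc] > 0L) nbr <- c(nbr, labels[rr - 1L, cc])
      if (cc > 1L) {
        if (labels[rr, cc - 1L] > 0L) nbr <- c(nbr, labels[rr, cc - 1L])
        if (rr > 1L && labels[rr - 1L, cc - 1L] > 0L) nbr <- c(nbr, labels[rr - 1L, cc - 1L])
        if (rr < nr && labels[rr + 1L, cc - 1L] > 0L) nbr <- c(nbr, labels[rr + 1L, cc - 1L])
      }
      if (length(nbr) == 0L) {
        next_label <- next_label + 1L
        parent[next_label] <- next_label
        labels[rr, cc] <- next_label
      } else {
        roots <- vapply(unique(nbr), find_root, integer(1))
        keep <- min(roots)
        labels[rr, cc] <- keep
        for (r2 in roots) parent[r2] <- keep
      }
    }
  }
  if (next_label == 0L) return(labels)
  roots <- vapply(seq_len(next_label), find_root, integer(1))
  remap <- integer(next_label)
  remap[sort(unique(roots))] <- seq_along(unique(roots))
  pos <- labels > 0L
  labels[pos] <- remap[roots[labels[pos]]]
  labels
}

# Trapezoidal integral of y(x) over [lo, hi] with linear interpolation at the
# window edges, so windows need not align with the sampling grid.
integrate_window <- function(x, y, lo, hi) {
  if (lo >= hi) return(0)
  lo <- max(lo, x[1]); hi <- min(hi, x[length(x)])
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- stats::approx(x, y, xout = xs)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

# Additive Gaussian noise clipped at zero (the package-wide noise model).
add_clipped_noise <- function(x, sd) {
  if (sd <= 0) return(x)
  out <- x + stats::rnorm(length(x), 0, sd)
  out[out < 0] <- 0
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}
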
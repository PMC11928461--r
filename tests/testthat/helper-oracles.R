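# Independent oracles used by the suite. None of these call the package
# routines they are checked against.

# Radial high-pass via explicit DFT matrices (matrix-product DFT, no fft()).
dft_highpass_oracle <- function(m, highpass_radius) {
  nr <- nrow(m); nc <- ncol(m)
  wmat <- function(n) {
    jk <- outer(0:(n - 1), 0:(n - 1))
    exp(-2i * pi * jk / n)
  }
  wr <- wmat(nr); wc <- wmat(nc)
  ft <- wr %*% m %*% wc
  fr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[seq_len(nr)]
  fc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[seq_len(nc)]
  keep <- sqrt(outer(fr^2, fc^2, `+`)) >= highpass_radius
  keep[1, 1] <- TRUE
  ft <- ft * keep
  Re(Conj(wr) %*% ft %*% Conj(wc)) / (nr * nc)
}

# Crank-Nicolson solver for 1-D diffusion with no-flux walls on [0, W],
# cell-centred grid, top-hat initial condition with partial-cell weighting.
cn_diffusion_oracle <- function(d_m2_s, width_m, stream_fraction, t_s,
                                nx = 1200L, nt = 1500L) {
  dx <- width_m / nx
  x <- (seq_len(nx) - 0.5) * dx
  edge <- stream_fraction * width_m
  c0 <- pmin(pmax((edge - (x - dx / 2)) / dx, 0), 1)
  dt <- t_s / nt
  lam <- d_m2_s * dt / dx^2
  # Neumann-Laplacian tridiagonal: rows sum to zero at the walls
  main <- c(1, rep(2, nx - 2L), 1)
  a_mat <- Matrix::bandSparse(nx, nx, k = c(-1, 0, 1),
                              diagonals = list(rep(1, nx - 1L), -main,
                                               rep(1, nx - 1L)))
  lhs <- Matrix::Diagonal(nx) - (lam / 2) * a_mat
  rhs <- Matrix::Diagonal(nx) + (lam / 2) * a_mat
  lu <- Matrix::lu(lhs)
  cvec <- c0
  for (k in seq_len(nt)) cvec <- as.numeric(Matrix::solve(lu, rhs %*% cvec))
  list(x_m = x, c = cvec)
}

# Central finite-difference second derivative (interior points only).
fd_second_derivative <- function(y, h) {
  n <- length(y)
  d2 <- rep(NA_real_, n)
  d2[2:(n - 1)] <- (y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]) / h^2
  d2
}

# Analytic area of a Gaussian band of peak amplitude a and FWHM w restricted
# to [lo, hi] (direct integration oracle for the amide windows).
gauss_window_area <- function(centre, fwhm, amp, lo, hi) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  amp * s * sqrt(2 * pi) * (stats::pnorm(hi, centre, s) - stats::pnorm(lo, centre, s))
}

# Trapezoidal integral (independent of the package's integrate_window).
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

expect_guv_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
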
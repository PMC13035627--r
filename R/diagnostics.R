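# Per-pass test statistics on the stress-strain training data: stress
# entropy H(sigma) in bits, strain reversibility eta_eps (normalized mutual
# information), and stress convergence delta-sigma-bar (kPa), plus the
# advisory stop/add-data rule.

#' Freeze histogram binning for a run
#'
#' Equal-width bins per Voigt component, edges taken from the first
#' evaluated pass and reused for every later pass of a run so that
#' inter-pass comparisons share support. Values outside the frozen range
#' are clamped into the edge bins.
#'
#' @param mat n x 6 component samples.
#' @param n_bins number of bins (default 64).
#' @return a `stat_bins` object (list of per-component edge vectors).
#' @export
make_bins <- function(mat, n_bins = 64) {
  mat <- rbind(mat)
  stopifnot(ncol(mat) == 6, nrow(mat) >= 2)
  edges <- lapply(1:6, function(k) {
    r <- range(mat[, k])
    if (diff(r) == 0) r <- r + c(-0.5, 0.5) * max(abs(r[1]), 1) * 1e-12
    seq(r[1], r[2], length.out = n_bins + 1)
  })
  structure(list(edges = edges, n_bins = n_bins), class = "stat_bins")
}

bin_index <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Stress entropy H(sigma)
#'
#' Shannon entropy (bits) of the stress training data: per component a
#' histogram over fixed equal-width binning, entropy in bits, then the
#' equal-weight mean over the six Voigt components.
#'
#' @param sigma n x 6 stress samples (kPa), n >= 2.
#' @param bins optional frozen [make_bins()]; default bins from `sigma`.
#' @return entropy in bits (scalar).
#' @export
stress_entropy <- function(sigma, bins = NULL) {
  sigma <- rbind(sigma)
  if (nrow(sigma) < 2) stop("stress entropy needs at least two samples")
  if (is.null(bins)) bins <- make_bins(sigma)
  h <- vapply(1:6, function(k) {
    idx <- bin_index(sigma[, k], bins$edges[[k]])
    entropy_bits(tabulate(idx, nbins = bins$n_bins))
  }, numeric(1))
  mean(h)
}

#' Strain reversibility eta_eps
#'
#' Normalized mutual information between the strains the force-driven FEA
#' produced and the strains from the displacement-driven FEA, on paired
#' integration points. Per component both fields are discretized on shared
#' bins and `eta_c = I(eps_sigma; eps_eps) / H(eps_eps)`, so identical
#' fields give exactly 1; the equal-weight mean over components is clamped
#' to \[0, 1\]. A value of 1 means the force-driven strain field is a perfect
#' statistical match to the displacement-driven one; values at or below 0.7
#' at convergence signal that more measurement data are needed.
#'
#' @param eps_sigma,eps_eps n x 6 paired strain fields.
#' @param n_bins histogram bins per axis.
#' @return eta in \[0, 1\].
#' @export
strain_reversibility <- function(eps_sigma, eps_eps, n_bins = 64) {
  eps_sigma <- rbind(eps_sigma); eps_eps <- rbind(eps_eps)
  if (!identical(dim(eps_sigma), dim(eps_eps)))
    stop("strain fields are misaligned: dimensions differ")
  if (ncol(eps_sigma) != 6) stop("expected 6 Voigt components")
  etas <- vapply(1:6, function(k) {
    a <- eps_sigma[, k]; b <- eps_eps[, k]
    r <- range(c(a, b))
    if (diff(r) == 0) return(if (all(a == b)) 1 else NA_real_)
    edges <- seq(r[1], r[2], length.out = n_bins + 1)
    ia <- bin_index(a, edges); ib <- bin_index(b, edges)
    joint <- tabulate((ia - 1L) * n_bins + ib, nbins = n_bins^2)
    pj <- joint / sum(joint)
    pa <- tabulate(ia, nbins = n_bins) / length(a)
    pb <- tabulate(ib, nbins = n_bins) / length(b)
    nz <- which(pj > 0)
    ii <- ((nz - 1L) %/% n_bins) + 1L
    jj <- ((nz - 1L) %% n_bins) + 1L
    I <- sum(pj[nz] * log2(pj[nz] / (pa[ii] * pb[jj])))
    Hb <- entropy_bits(tabulate(ib, nbins = n_bins))
    if (Hb == 0) return(if (all(ia == ib)) 1 else NA_real_)
    I / Hb
  }, numeric(1))
  min(max(mean(etas, na.rm = TRUE), 0), 1)
}

#' Stress convergence delta-sigma-bar
#'
#' Spatially averaged absolute change in the stress training data between
#' consecutive passes: the mean over common integration points and the six
#' components of `|sigma_k - sigma_{k-1}|`.
#'
#' @param sigma_k,sigma_km1 n x 6 stress samples aligned on the same points
#'   (use `keys` when the point sets may differ).
#' @param keys_k,keys_km1 optional point identifiers for alignment.
#' @return mean absolute change (kPa).
#' @export
stress_convergence <- function(sigma_k, sigma_km1, keys_k = NULL, keys_km1 = NULL) {
  if (!is.null(keys_k)) {
    common <- intersect(keys_k, keys_km1)
    if (length(common) == 0) return(NA_real_)
    sigma_k <- sigma_k[match(common, keys_k), , drop = FALSE]
    sigma_km1 <- sigma_km1[match(common, keys_km1), , drop = FALSE]
  }
  stopifnot(identical(dim(sigma_k), dim(sigma_km1)))
  mean(abs(sigma_k - sigma_km1))
}

#' Advisory stop/add-data rule
#'
#' Reads the per-pass statistic history: once the stress data have
#' converged (the last `consecutive` passes each changed by less than
#' `tol_frac` of the volume-mean absolute stress), a strain reversibility
#' at or below `eta_threshold` advises acquiring additional measurement
#' data, while higher reversibility advises stopping. Otherwise training
#' continues. Advisory only; never mutates state.
#'
#' @param history tibble of per-pass records with columns
#'   `delta_sigma_bar`, `mean_abs_sigma`, `eta_eps` (see [run_schedule()]).
#' @param eta_threshold reversibility threshold (default 0.7).
#' @param tol_frac convergence tolerance as a fraction of mean |stress|.
#' @param consecutive how many consecutive converged passes are required.
#' @return `"continue"`, `"add_data"` or `"stop"`.
#' @export
advise <- function(history, eta_threshold = 0.7, tol_frac = 0.01, consecutive = 2) {
  n <- nrow(history)
  if (n < consecutive + 1) return("continue")
  recent <- history[(n - consecutive + 1):n, ]
  conv <- all(is.finite(recent$delta_sigma_bar)) &&
    all(recent$delta_sigma_bar < tol_frac * recent$mean_abs_sigma)
  if (!conv) return("continue")
  if (history$eta_eps[n] <= eta_threshold) "add_data" else "stop"
}

#' Write a statistic history to CSV
#'
#' Columns `pass, H_sigma_bits, eta_eps, delta_sigma_kPa, advice`.
#' @param history the `history` tibble from [run_schedule()].
#' @param path output file.
#' @export
write_stats_csv <- function(history, path) {
  df <- data.frame(pass = history$pass,
                   H_sigma_bits = history$H_sigma,
                   eta_eps = history$eta_eps,
                   delta_sigma_kPa = history$delta_sigma_bar,
                   mean_abs_sigma_kPa = history$mean_abs_sigma,
                   planes_active = history$planes_active,
                   advice = history$advice)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Re-derive the advice column from a statistics CSV
#' @param path CSV written by [write_stats_csv()].
#' @export
read_stats_csv <- function(path) {
  df <- utils::read.csv(path)
  tibble::as_tibble(data.frame(
    pass = df$pass, H_sigma = df$H_sigma_bits, eta_eps = df$eta_eps,
    delta_sigma_bar = df$delta_sigma_kPa,
    mean_abs_sigma = df$mean_abs_sigma_kPa,
    planes_active = df$planes_active, advice = df$advice))
}
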
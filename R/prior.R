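# Well prior P(M) over hidden long molecules: existence probability,
# end-marker state table P(B), a 2-D kernel density estimate of
# (size, read density) conditioned on the marker state, the shared SNP-rate
# parameter theta, and the lambda grid used for variable elimination.

.B_STATES <- c("00", "01", "10", "11")

.b_key <- function(left, right) paste0(as.integer(left), as.integer(right))

#' Extract training features from uniquely mapped candidate clouds
#'
#' One feature record per retained cloud: size in bp, read count, read
#' density (reads/bp) and the observed end-marker pair. Outlier clouds are
#' dropped: density above the 99th percentile (copy-number pileups) and
#' clouds overlapping another training cloud (low-mappability regions where
#' distinct fragments collapse).
#'
#' @param clouds data frame from [cluster_pass1()]; if a `unique_frac`
#'   column is present (fraction of members uniquely mapped in pass 1),
#'   clouds below `min_unique_frac` are dropped first.
#' @param min_unique_frac minimum fraction of uniquely mapped members.
#' @param density_quantile upper density quantile retained.
#' @return data frame with `size_bp`, `read_count`, `lambda`, `left_marker`,
#'   `right_marker`.
#' @export
extract_features <- function(clouds, min_unique_frac = 0.95,
                             density_quantile = 0.99) {
  cl <- clouds
  if (!is.null(cl$unique_frac)) cl <- cl[cl$unique_frac >= min_unique_frac, ]
  if (nrow(cl)) {
    lam <- cl$n_reads / (cl$end - cl$start)
    keep_dens <- lam <= stats::quantile(lam, density_quantile)
    # drop clouds overlapping another training cloud of the same well (two
    # colliding fragments, or low-mappability pileups); clouds of different
    # wells legitimately overlap on the genome
    keep_ovl <- rep(TRUE, nrow(cl))
    wells <- if (!is.null(cl$well)) cl$well else rep(1L, nrow(cl))
    for (grp in split(seq_len(nrow(cl)), list(wells, cl$chrom), drop = TRUE)) {
      if (length(grp) < 2) next
      ir <- IRanges::IRanges(cl$start[grp] + 1L, cl$end[grp])
      keep_ovl[grp] <- IRanges::countOverlaps(ir, ir) == 1L
    }
    cl <- cl[keep_dens & keep_ovl, , drop = FALSE]
  }
  if (nrow(cl) < 50)
    stop("fewer than 50 training clouds after filtering; ",
         "supply more training wells")
  data.frame(size_bp = cl$end - cl$start, read_count = cl$n_reads,
             lambda = cl$n_reads / (cl$end - cl$start),
             left_marker = cl$left_marker, right_marker = cl$right_marker)
}

# Scott's-rule bandwidth with a floor (heavy right tails in fragment size).
.bw_scott <- function(x, floor = 0.05) {
  n <- length(x)
  max(floor, stats::sd(x) * n^(-1 / 6))
}

# Deterministically thin a point set to at most k support points.
.thin_points <- function(m, k = 256L) {
  n <- nrow(m)
  if (n <= k) return(m)
  m[unique(as.integer(round(seq(1, n, length.out = k)))), , drop = FALSE]
}

#' Fit the well prior from training cloud features
#'
#' * `pB`: empirical end-marker state frequencies with add-one smoothing.
#' * `pSl`: per marker state, a 2-D Gaussian KDE over (log size, log density)
#'   with Scott's-rule bandwidths floored at 0.05; states with fewer than 20
#'   observations fall back to the pooled estimate.
#' * `marker_eff`: fraction of the 2 x n marker slots observed.
#' * `p_exist`: expected true fragments per well
#'   (`well_fraction * genome_length / mean(size)`) divided by the number of
#'   candidate clouds per well — the prior that a seeded candidate is real.
#' * `lambda_grid`: 64 log-spaced points spanning the 1st-99th percentile of
#'   training density, with trapezoid integration weights.
#'
#' @param features data frame from [extract_features()].
#' @param genome_length usable genome size in bp (location prior is uniform).
#' @param well_fraction fraction of the genome received per well.
#' @param n_wells number of training wells behind `features`.
#' @param clouds_per_well candidate clouds per well before training filters;
#'   defaults to `nrow(features) / n_wells`.
#' @param theta shared per-base alternative-allele (SNP-rate) prior.
#' @param p_offtarget per-read probability of the unassigned state
#'   (contaminant/artefact reads).
#' @param kde_points KDE support-point cap per marker state.
#' @return a `well_prior` list.
#' @export
fit_prior <- function(features, genome_length, well_fraction = 0.02,
                      n_wells = 1, clouds_per_well = NULL, theta = 1e-3,
                      p_offtarget = 1e-5, kde_points = 256L) {
  stopifnot(nrow(features) >= 50)
  b_obs <- .b_key(features$left_marker, features$right_marker)
  counts <- table(factor(b_obs, levels = .B_STATES))
  pB <- (as.numeric(counts) + 1) / (sum(counts) + 4)
  names(pB) <- .B_STATES

  pts_all <- cbind(log(features$size_bp), log(features$lambda))
  fit_state <- function(pts) {
    if (stats::sd(pts[, 1]) < 1e-12 && stats::sd(pts[, 2]) < 1e-12)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, 1e-6), nrow(pts))
    list(points = .thin_points(pts, kde_points),
         bw = c(.bw_scott(pts[, 1]), .bw_scott(pts[, 2])))
  }
  pooled <- fit_state(pts_all)
  pSl <- lapply(.B_STATES, function(b) {
    i <- b_obs == b
    if (sum(i) < 20) pooled else fit_state(pts_all[i, , drop = FALSE])
  })
  names(pSl) <- .B_STATES

  marker_eff <- mean(c(features$left_marker, features$right_marker))
  mean_s <- mean(features$size_bp)
  if (is.null(clouds_per_well)) clouds_per_well <- nrow(features) / n_wells
  expected_frags <- well_fraction * genome_length / mean_s
  p_exist <- min(0.95, max(0.05, expected_frags / clouds_per_well))

  lam_q <- stats::quantile(features$lambda, c(0.01, 0.99))
  grid <- exp(seq(log(lam_q[1]), log(lam_q[2]), length.out = 64))
  w <- diff(grid)
  trap <- c(w[1] / 2, (w[-1] + w[-length(w)]) / 2, w[length(w)] / 2)

  structure(list(
    p_exist = p_exist, theta = theta, marker_eff = marker_eff,
    p_offtarget = p_offtarget, pB = pB, pSl = pSl,
    genome_length = genome_length, well_fraction = well_fraction,
    mean_size = mean_s, lambda_grid = as.numeric(grid),
    lambda_weights = as.numeric(trap),
    cache = new.env(parent = emptyenv())
  ), class = "well_prior")
}

#' Evaluate the (log) joint KDE density of (size, density) given marker state
#'
#' Density on the natural (S, lambda) scale: the Gaussian KDE lives on
#' (log S, log lambda) and the log-scale Jacobian `1/(S * lambda)` is
#' applied.
#' @param prior a `well_prior`.
#' @param b_key marker state `"00"`, `"01"`, `"10"` or `"11"`.
#' @param s size in bp (scalar).
#' @param lambda numeric vector of densities (reads/bp).
#' @return log-density vector along `lambda`.
#' @export
prior_slambda_logdens <- function(prior, b_key, s, lambda) {
  kde <- prior$pSl[[b_key]]
  ls <- log(s); ll <- log(lambda)
  zs <- (ls - kde$points[, 1]) / kde$bw[1]
  d <- vapply(ll, function(l) {
    zl <- (l - kde$points[, 2]) / kde$bw[2]
    logsumexp(-0.5 * (zs^2 + zl^2))
  }, 0)
  d - log(nrow(kde$points)) - log(2 * pi) - sum(log(kde$bw)) - ls - ll
}

# Memoised count/size/density term: log sum_i w_i P(s, lambda_i | b)
# Pois(n; lambda_i * s). Size is binned on a 128-point log grid for the
# density part; the Poisson part uses the exact size.
.count_logterm <- function(prior, b_key, n, s) {
  kbin <- round(log(s) * 32)                # ~3% log-size bins
  key <- paste0(b_key, "@", kbin, "@", n, "@", round(s))
  v <- prior$cache[[key]]
  if (!is.null(v)) return(v)
  dkey <- paste0(b_key, "@", kbin)
  dens <- prior$cache[[dkey]]
  if (is.null(dens)) {
    dens <- prior_slambda_logdens(prior, b_key, exp(kbin / 32),
                                  prior$lambda_grid)
    assign(dkey, dens, envir = prior$cache)
  }
  v <- logsumexp(log(prior$lambda_weights) + dens +
                 stats::dpois(n, prior$lambda_grid * s, log = TRUE))
  assign(key, v, envir = prior$cache)
  v
}

#' Log-probability of the (E, B, location) part of the molecule prior
#'
#' For an inactive molecule the conditional prior is identically 1, so the
#' value is exactly `log(1 - p_exist)`. For an active molecule:
#' `log p_exist + log pB(b) + log(1/G)` with a uniform location prior over
#' the usable genome; the (size, density) part is integrated later, inside
#' the potential, together with the read count.
#'
#' @param molecule list with `E` (logical), `B` (logical length-2
#'   left/right marker pair); location is irrelevant under the uniform prior.
#' @param prior a `well_prior`.
#' @return scalar log-probability.
#' @export
prior_logprob <- function(molecule, prior) {
  if (!isTRUE(molecule$E)) return(log(1 - prior$p_exist))
  log(prior$p_exist) + log(prior$pB[[.b_key(molecule$B[1], molecule$B[2])]]) -
    log(prior$genome_length)
}

#' Serialise a well prior to JSON
#' @param prior a `well_prior`.
#' @param path output file.
#' @export
write_prior <- function(prior, path) {
  x <- prior[setdiff(names(prior), "cache")]
  x$pB <- as.list(x$pB)
  x$pSl <- lapply(x$pSl, function(k)
    list(points = unname(k$points), bw = unname(k$bw)))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a well prior back from JSON
#' @param path JSON file from [write_prior()].
#' @return a `well_prior`.
#' @export
read_prior <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pB <- unlist(x$pB)[.B_STATES]
  x$pSl <- lapply(x$pSl[.B_STATES], function(k) {
    pts <- k$points
    if (is.list(pts)) pts <- do.call(rbind, lapply(pts, unlist))
    list(points = matrix(as.numeric(pts), ncol = 2),
         bw = as.numeric(unlist(k$bw)))
  })
  names(x$pSl) <- .B_STATES
  x$cache <- new.env(parent = emptyenv())
  structure(x, class = "well_prior")
}
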
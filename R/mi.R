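#' Binned mutual information between two variables
#'
#' Plug-in estimator on a 2-D histogram: each variable is split into
#' `n_bins` equally spaced bins over its observed range, and
#' `I(X, Y) = sum_ij p(i, j) log( p(i, j) / (px(i) py(j)) )` in nats.
#' Discrete variables with fewer than `n_bins` distinct values (e.g. allele
#' dosages in `{0, 1, 2}`) use their observed values as bins, since
#' equal-width binning would only introduce empty bins without changing the
#' probabilities.  The normalized value `I / sqrt(H(X) H(Y))` lies in
#' \[0, 1\] and equals 1 for identical variables.
#'
#' Pairs with missing values are dropped (pairwise-complete).  A
#' zero-variance input yields `mi = 0` and `normalized_mi = 0`, flagged
#' degenerate rather than raising an error.
#'
#' @param x,y numeric vectors of equal length (>= 5 complete pairs).
#' @param n_bins number of equally spaced bins (default 10).
#' @return list with `mi` (nats), `normalized_mi`, and `degenerate` flag.
#' @export
mutual_information <- function(x, y, n_bins = 10L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L) stop("need at least 5 complete pairs")
  ix <- bin_indices(x, n_bins)
  iy <- bin_indices(y, n_bins)
  if (is.null(ix) || is.null(iy)) {
    return(list(mi = 0, normalized_mi = 0, degenerate = TRUE))
  }
  mi_parts <- mi_from_indices(ix$idx, iy$idx, ix$n_levels, iy$n_levels)
  hx <- mi_parts$hx; hy <- mi_parts$hy
  nmi <- if (hx > 0 && hy > 0) mi_parts$mi / sqrt(hx * hy) else 0
  list(mi = mi_parts$mi, normalized_mi = min(max(nmi, 0), 1),
       degenerate = (hx == 0 || hy == 0))
}

# Equal-width bin assignment; observed-value bins for low-cardinality
# discrete data.  Returns NULL for zero-variance input.
bin_indices <- function(x, n_bins) {
  ux <- unique(x)
  if (length(ux) == 1L) return(NULL)
  if (length(ux) < n_bins) {
    lev <- sort(ux)
    return(list(idx = match(x, lev), n_levels = length(lev)))
  }
  r <- range(x)
  brk <- seq(r[1L], r[2L], length.out = n_bins + 1L)
  idx <- findInterval(x, brk, rightmost.closed = TRUE, all.inside = TRUE)
  list(idx = idx, n_levels = n_bins)
}

# MI (nats) and marginal entropies from bin-index vectors
mi_from_indices <- function(ix, iy, nx, ny) {
  n <- length(ix)
  joint <- tabulate(ix + nx * (iy - 1L), nx * ny)
  px <- tabulate(ix, nx) / n
  py <- tabulate(iy, ny) / n
  pj <- joint / n
  lp_marg <- log(px)[rep.int(seq_len(nx), ny)] +
    rep(log(py), each = nx)
  nz <- pj > 0
  mi <- sum(pj[nz] * (log(pj[nz]) - lp_marg[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  list(mi = max(mi, 0), hx = hx, hy = hy)
}

#' Surrogate-permutation significance test for a mutual-information edge
#'
#' The observed MI is compared against a null distribution of MI values
#' computed on `n_surrogates` independent subject permutations (subject
#' order permuted separately for both variables).  The surrogate
#' distribution is treated as Gaussian and the edge is accepted when the
#' one-sided z-test gives `p < alpha` (the observed value significantly
#' exceeds the null).  Accepted edges carry the normalized MI as weight.
#'
#' @inheritParams mutual_information
#' @param n_surrogates number of permutation surrogates (default 1000).
#' @param alpha per-pair significance level (default 0.05; no
#'   multiple-testing correction).
#' @param seed optional RNG seed for the permutations.
#' @return list with `mi`, `normalized_mi`, `surrogate_mean`,
#'   `surrogate_sd`, `z`, `p_value`, `accepted`, `degenerate`.
#' @export
surrogate_edge_test <- function(x, y, n_bins = 10L, n_surrogates = 1000L,
                                alpha = 0.05, seed = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L) stop("need at least 5 complete pairs")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  bx <- bin_indices(x, n_bins)
  by <- bin_indices(y, n_bins)
  reject <- list(mi = 0, normalized_mi = 0, surrogate_mean = NA_real_,
                 surrogate_sd = NA_real_, z = NA_real_, p_value = NA_real_,
                 accepted = FALSE, degenerate = TRUE)
  if (is.null(bx) || is.null(by)) return(reject)
  obs <- mi_from_indices(bx$idx, by$idx, bx$n_levels, by$n_levels)
  nmi <- if (obs$hx > 0 && obs$hy > 0) obs$mi / sqrt(obs$hx * obs$hy) else 0

  # marginals are invariant under permutation, so only the joint counts
  # need recomputing per surrogate
  nx <- bx$n_levels; ny <- by$n_levels
  px <- tabulate(bx$idx, nx) / n
  py <- tabulate(by$idx, ny) / n
  lp_marg <- log(px)[rep.int(seq_len(nx), ny)] + rep(log(py), each = nx)
  sims <- numeric(n_surrogates)
  iy0 <- by$idx
  ix0 <- bx$idx
  for (s in seq_len(n_surrogates)) {
    jx <- ix0[sample.int(n)]
    jy <- iy0[sample.int(n)]
    pj <- tabulate(jx + nx * (jy - 1L), nx * ny) / n
    nz <- pj > 0
    sims[s] <- sum(pj[nz] * (log(pj[nz]) - lp_marg[nz]))
  }
  mu <- mean(sims)
  sdv <- stats::sd(sims)
  if (!is.finite(sdv) || sdv == 0) {
    reject$mi <- obs$mi
    reject$normalized_mi <- min(max(nmi, 0), 1)
    reject$surrogate_mean <- mu
    reject$surrogate_sd <- sdv
    return(reject)
  }
  z <- (obs$mi - mu) / sdv
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(mi = obs$mi, normalized_mi = min(max(nmi, 0), 1),
       surrogate_mean = mu, surrogate_sd = sdv, z = z, p_value = p,
       accepted = (p < alpha && z > 0), degenerate = FALSE)
}
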
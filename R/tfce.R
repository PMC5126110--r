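#' TFCE parameters
#'
#' Defaults follow random-field-theory-derived practice for threshold-free
#' cluster enhancement: extent exponent e = 0.66, height exponent h = 2,
#' 100 integration steps, 1000 Monte-Carlo permutations, familywise alpha
#' 0.05.
#'
#' @param e_exponent extent (cluster size) exponent.
#' @param h_exponent height (statistic) exponent.
#' @param n_steps threshold-integration steps (equal increments from 0 to
#'   the map's maximum |t|, midpoint rule).
#' @param n_perm Monte-Carlo permutations, at least 100.
#' @param alpha familywise significance level.
#' @param seed integer seed for the permutation stream.
#' @return an object of class `tfce_params`.
#' @export
tfce_params <- function(e_exponent = 0.66, h_exponent = 2, n_steps = 100L,
                        n_perm = 1000L, alpha = 0.05, seed = NULL) {
  if (e_exponent <= 0 || h_exponent <= 0) stop("exponents must be positive")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (n_steps < 1L) stop("n_steps must be positive")
  structure(list(e_exponent = e_exponent, h_exponent = h_exponent,
                 n_steps = as.integer(n_steps), n_perm = as.integer(n_perm),
                 alpha = alpha, seed = seed),
            class = "tfce_params")
}

#' Combined spatio-spectral bin adjacency
#'
#' Bins are (electrode, band) cells. Two bins are adjacent when they share
#' the band and the electrodes are montage neighbours, or share the
#' electrode and the bands are consecutive in the spectral chain (theta -
#' alpha - sigma - beta-1 - beta-2).
#'
#' @param montage a [generate_montage()] result (or any object with a
#'   logical `adjacency` matrix).
#' @param n_bands number of bands in the chain.
#' @return object of class `bin_adjacency`: list with `neighbors` (list of
#'   integer bin indices, 1-based; bin index = electrode + (band-1) *
#'   n_electrodes), `n_electrodes`, `n_bands`.
#' @export
bin_adjacency <- function(montage, n_bands) {
  adj <- montage$adjacency
  ne <- nrow(adj)
  n_bands <- as.integer(n_bands)
  nbins <- ne * n_bands
  spatial <- lapply(seq_len(ne), function(e) which(adj[e, ]))
  neighbors <- vector("list", nbins)
  for (b in seq_len(n_bands)) {
    off <- (b - 1L) * ne
    for (e in seq_len(ne)) {
      nb <- spatial[[e]] + off
      if (b > 1L) nb <- c(nb, e + off - ne)
      if (b < n_bands) nb <- c(nb, e + off + ne)
      neighbors[[e + off]] <- as.integer(nb)
    }
  }
  structure(list(neighbors = neighbors, n_electrodes = ne, n_bands = n_bands),
            class = "bin_adjacency")
}

#' Per-bin Spearman correlation map
#'
#' Correlates ISI with H separately for every (electrode, band) bin of one
#' group's H matrix, assembling rho and t matrices. Bins with constant H
#' are flagged, set to zero and excluded from enhancement, with a warning.
#'
#' @param hm an [h_matrix()] (participants of one group).
#' @param isi ISI scores, one per participant.
#' @return object of class `stat_map`: `rho` and `t` matrices (electrodes
#'   x bands), `n`, `df`, `flagged` (logical matrix).
#' @export
correlation_stat_map <- function(hm, isi) {
  stopifnot(inherits(hm, "h_matrix"))
  n <- dim(hm)[1]
  if (length(isi) != n) stop("participant counts do not match")
  ne <- dim(hm)[2]; nb <- dim(hm)[3]
  rho <- matrix(NA_real_, ne, nb,
                dimnames = dimnames(hm)[2:3])
  tmat <- rho
  flagged <- matrix(FALSE, ne, nb, dimnames = dimnames(hm)[2:3])
  for (e in seq_len(ne)) {
    for (b in seq_len(nb)) {
      h <- hm[, e, b]
      if (stats::sd(h) == 0 || stats::sd(isi) == 0) {
        flagged[e, b] <- TRUE
        rho[e, b] <- 0; tmat[e, b] <- 0
      } else {
        st <- spearman_test(isi, h)
        rho[e, b] <- st$rho
        tmat[e, b] <- st$statistic
      }
    }
  }
  if (any(flagged)) {
    warning(sum(flagged), " constant bin(s) flagged and excluded from enhancement")
  }
  structure(list(rho = rho, t = tmat, n = n, df = n - 2L, flagged = flagged),
            class = "stat_map")
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Each bin's statistic is enhanced by integrating, over thresholds h'
#' from 0 to the map's maximum |t| (`n_steps` equal increments, midpoint
#' rule), the term `extent(h')^e * h'^h * dh`, where extent is the size of
#' the connected supra-threshold component (under the combined
#' spatio-spectral adjacency) containing the bin. Negative statistics are
#' enhanced sign-symmetrically: |t| is enhanced within same-sign
#' components and the sign reattached.
#'
#' @param t_map numeric electrodes x bands matrix (or a `stat_map`, whose
#'   `t` matrix with flagged bins zeroed is used).
#' @param adj a [bin_adjacency()].
#' @param params a [tfce_params()].
#' @return matrix of enhanced statistics, same shape and dimnames.
#' @export
tfce_enhance <- function(t_map, adj, params = tfce_params()) {
  if (inherits(t_map, "stat_map")) t_map <- t_map$t
  stopifnot(is.matrix(t_map), inherits(adj, "bin_adjacency"))
  if (nrow(t_map) != adj$n_electrodes || ncol(t_map) != adj$n_bands) {
    stop("map shape does not match adjacency")
  }
  nb0 <- lapply(adj$neighbors, function(v) v - 1L)
  enh <- .tfce_enhance_cpp(as.numeric(t_map), nb0, params$n_steps,
                           params$e_exponent, params$h_exponent)
  matrix(enh, nrow = nrow(t_map), dimnames = dimnames(t_map))
}

# Centered, unit-variance column ranks; the workhorse for fast permutation
# Spearman maps (Pearson of standardised ranks = Spearman rho).
.std_ranks <- function(x) {
  r <- rank(x)
  r <- r - mean(r)
  s <- sqrt(sum(r^2))
  if (s == 0) return(rep(0, length(x)))
  r / s
}

#' Permutation null distribution of the maximum enhanced statistic
#'
#' Under the null of no ISI-H association, ISI is exchangeable across
#' participants: each permutation shuffles ISI, recomputes the Spearman
#' t map for every bin (by rank pre-computation), enhances it, and records
#' the maximum |t_tfce| over all bins. The resulting max-statistic null
#' controls the familywise error of the corrected p values.
#'
#' @param hm an [h_matrix()].
#' @param isi ISI scores.
#' @param adj a [bin_adjacency()].
#' @param params a [tfce_params()]; `params$seed` seeds the permutations.
#' @return numeric vector of length `params$n_perm`.
#' @export
permutation_null <- function(hm, isi, adj, params = tfce_params()) {
  stopifnot(inherits(hm, "h_matrix"))
  n <- dim(hm)[1]
  if (length(isi) != n) stop("participant counts do not match")
  ne <- dim(hm)[2]; nb <- dim(hm)[3]
  flat <- matrix(unclass(hm), nrow = n)      # n x (ne*nb), electrode-fastest
  zh <- apply(flat, 2L, .std_ranks)          # standardised ranks per bin
  const_bin <- apply(flat, 2L, function(v) stats::sd(v) == 0)
  zi <- .std_ranks(isi)
  if (!is.null(params$seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(as.integer(params$seed))
  }
  nb0 <- lapply(adj$neighbors, function(v) v - 1L)
  df <- n - 2L
  null_max <- numeric(params$n_perm)
  for (p in seq_len(params$n_perm)) {
    rho <- as.numeric(crossprod(zh, zi[sample.int(n)]))
    rho[const_bin] <- 0
    rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
    tv <- rho * sqrt(df / (1 - rho^2))
    enh <- .tfce_enhance_cpp(tv, nb0, params$n_steps,
                             params$e_exponent, params$h_exponent)
    null_max[p] <- max(abs(enh))
  }
  null_max
}

#' Monte-Carlo corrected p values
#'
#' `p(bin) = (1 + #\{null >= |t_tfce(bin)|\}) / (n_perm + 1)` — the add-one
#' estimator, which can never return zero and is a valid Monte-Carlo p.
#'
#' @param enhanced enhanced-statistic matrix from [tfce_enhance()].
#' @param null_max null vector from [permutation_null()].
#' @return matrix of corrected p values in (0, 1].
#' @export
corrected_pvalues <- function(enhanced, null_max) {
  if (!length(null_max)) stop("empty null distribution")
  p <- vapply(abs(as.numeric(enhanced)),
              function(v) (1 + sum(null_max >= v)) / (length(null_max) + 1),
              numeric(1))
  matrix(p, nrow = nrow(enhanced), dimnames = dimnames(enhanced))
}

#' Spatio-spectral TFCE correlation inference
#'
#' The full chain for one group: per-bin Spearman map, TFCE enhancement,
#' max-statistic permutation null, corrected p values.
#'
#' @param hm an [h_matrix()] restricted to one group's participants.
#' @param isi that group's ISI scores.
#' @param adj a [bin_adjacency()]; defaults to the montage carried by `hm`
#'   with its band count.
#' @param params a [tfce_params()].
#' @return object of class `tfce_result`: `rho`, `t`, `t_tfce`, `p`
#'   matrices, `null_max`, `n`, `params`.
#' @export
tfce_correlation <- function(hm, isi, adj = NULL, params = tfce_params()) {
  if (is.null(adj)) {
    montage <- attr(hm, "montage")
    if (is.null(montage)) stop("no adjacency given and h_matrix carries no montage")
    adj <- bin_adjacency(montage, dim(hm)[3])
  }
  sm <- correlation_stat_map(hm, isi)
  enh <- tfce_enhance(sm, adj, params)
  null_max <- permutation_null(hm, isi, adj, params)
  p <- corrected_pvalues(enh, null_max)
  structure(list(rho = sm$rho, t = sm$t, t_tfce = enh, p = p,
                 flagged = sm$flagged, null_max = null_max,
                 n = sm$n, params = params),
            class = "tfce_result")
}

#' @export
print.tfce_result <- function(x, ...) {
  cat(sprintf("<tfce_result: %d electrodes x %d bands, %d permutations, %d bin(s) with p < %.2g>\n",
              nrow(x$p), ncol(x$p), length(x$null_max),
              sum(x$p < x$params$alpha), x$params$alpha))
  invisible(x)
}

#' Per-band cluster summary of a TFCE result
#'
#' For each band: the spatial extent (number of electrodes with corrected
#' p below `alpha`), the peak bin — minimal p, ties broken by larger
#' |t_tfce| — with its rho, t, t_tfce and p, and the count of marginal
#' electrodes (alpha <= p < 0.1).
#'
#' @param result a `tfce_result`.
#' @param alpha significance level for the extent count.
#' @return data frame, one row per band.
#' @export
summarize_spatiospectral <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "tfce_result"))
  bands <- colnames(result$p)
  electrodes <- rownames(result$p)
  out <- lapply(seq_along(bands), function(b) {
    pb <- result$p[, b]
    eb <- result$t_tfce[, b]
    peak <- order(pb, -abs(eb))[1L]
    data.frame(band = bands[b],
               extent = sum(pb < alpha),
               marginal = sum(pb >= alpha & pb < 0.1),
               peak_electrode = electrodes[peak],
               peak_rho = result$rho[peak, b],
               peak_t = result$t[peak, b],
               peak_t_tfce = eb[peak],
               peak_p = pb[peak],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
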
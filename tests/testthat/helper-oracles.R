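# Shared fixtures and independent brute-force oracles for the test suite.

# Naive DFA fluctuation: explicit per-segment loop with lm() polynomial fits.
# Deliberately slow and simple; the fast matrix implementation must agree.
brute_fluctuation <- function(profile, scale, poly_order = 3L) {
  n <- length(profile)
  nseg <- n %/% scale
  rms <- numeric(nseg)
  for (s in seq_len(nseg)) {
    seg <- profile[((s - 1) * scale + 1):(s * scale)]
    t <- seq_len(scale)
    fit <- stats::lm(seg ~ stats::poly(t, poly_order))
    rms[s] <- sqrt(mean(stats::residuals(fit)^2))
  }
  mean(rms)
}

# Naive TFCE: explicit threshold loop with igraph connected components.
# Must equal the Rcpp kernel exactly at the same midpoint thresholds.
brute_tfce <- function(t_map, adj, n_steps, e_exp = 0.66, h_exp = 2) {
  tv <- as.numeric(t_map)
  nbins <- length(tv)
  edges <- do.call(rbind, lapply(seq_len(nbins), function(i) {
    v <- adj$neighbors[[i]]
    v <- v[v > i]
    if (!length(v)) return(NULL)
    matrix(c(rep.int(i, length(v)), v), ncol = 2)
  }))
  out <- numeric(nbins)
  tmax <- max(abs(tv))
  if (tmax == 0) return(matrix(out, nrow = nrow(t_map)))
  dh <- tmax / n_steps
  for (sgn in c(1, -1)) {
    for (j in seq_len(n_steps)) {
      h <- (j - 0.5) * dh
      active <- which(sgn * tv >= h)
      if (!length(active)) break
      sub_edges <- edges[edges[, 1] %in% active & edges[, 2] %in% active, ,
                         drop = FALSE]
      g <- igraph::graph_from_data_frame(
        data.frame(from = match(sub_edges[, 1], active),
                   to = match(sub_edges[, 2], active)),
        directed = FALSE,
        vertices = data.frame(name = seq_along(active)))
      comp <- igraph::components(g)
      ext <- comp$csize[comp$membership]
      out[active] <- out[active] + sgn * ext^e_exp * h^h_exp * dh
    }
  }
  matrix(out, nrow = nrow(t_map), dimnames = dimnames(t_map))
}

# Small shared fixtures.
tiny_montage <- function() generate_montage(9L, "grid")
two_bands <- function() default_bands(c("theta", "alpha"))
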
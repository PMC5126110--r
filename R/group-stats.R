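#' Spearman rank correlation coefficient
#'
#' Pearson correlation of midranks. Errors on constant input, where the
#' coefficient is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for constant input")
  }
  stats::cor(x, y, method = "spearman")
}

#' Spearman correlation with t-approximation test
#'
#' The test statistic is `t = rho * sqrt((n - 2) / (1 - rho^2))`, referred
#' to a t distribution with `n - 2` degrees of freedom (two-sided). For a
#' 52-participant group this gives df = 50; for 43 participants, df = 41.
#'
#' @param x,y numeric vectors.
#' @return object of class `correlation_result`: `rho`, `n`, `df`,
#'   `statistic` (t), `p`.
#' @export
spearman_test <- function(x, y) {
  rho <- spearman_rho(x, y)
  n <- length(x)
  df <- n - 2L
  if (abs(rho) >= 1 - 1e-12) {
    rho <- round(rho)                # perfectly monotone up to rank rounding
    t <- sign(rho) * Inf
    p <- 0
    warning("|rho| = 1: infinite t statistic")
  } else {
    t <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(rho = rho, n = n, df = df, statistic = t, p = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<spearman: rho = %.3f, t(%d) = %.3f, p = %.4g%s>\n",
              x$rho, x$df, x$statistic, x$p,
              if (!is.null(x$ci_lower)) {
                sprintf(", %g%% CI [%.3f, %.3f]", 100 * x$level,
                        x$ci_lower, x$ci_upper)
              } else ""))
  invisible(x)
}

#' Bootstrap confidence interval for a Spearman correlation
#'
#' Percentile interval from paired resampling with replacement. A
#' correlation is flagged `robust` when more than 97.5% of the bootstrap
#' replicates share the sign of the point estimate. Degenerate resamples
#' (either variable constant) are redrawn and counted.
#'
#' @param x,y numeric vectors, length >= 5.
#' @param n_boot bootstrap iterations.
#' @param level confidence level.
#' @param seed integer seed.
#' @return a `correlation_result` with `ci_lower`, `ci_upper`, `n_boot`,
#'   `robust`, `boot_rhos` and `n_redrawn` added.
#' @export
bootstrap_rho_ci <- function(x, y, n_boot = 1000L, level = 0.95, seed = NULL) {
  if (length(x) < 5L) stop("need at least 5 observations for the bootstrap")
  res <- spearman_test(x, y)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  n <- length(x)
  rhos <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) > 0 && stats::sd(y[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    rhos[b] <- stats::cor(x[idx], y[idx], method = "spearman")
  }
  qs <- stats::quantile(rhos, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 6)
  res$ci_lower <- qs[1]
  res$ci_upper <- qs[2]
  res$level <- level
  res$n_boot <- n_boot
  res$robust <- mean(sign(rhos) == sign(res$rho)) > 0.975
  res$boot_rhos <- rhos
  res$n_redrawn <- n_redrawn
  res
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum z test with midranks, tie-corrected variance and
#' continuity correction — the large-sample form appropriate for groups of
#' 40+ participants. An exact small-sample path is deliberately not
#' provided.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list with `z`, `p`, `n_a`, `n_b`.
#' @export
ranksum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])          # rank sum of the first sample
  mu <- na * (nb + na + 1) / 2
  ties <- table(r)
  n <- na + nb
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 == 0) {
    return(list(z = 0, p = 1, n_a = na, n_b = nb))  # everything tied
  }
  d <- w - mu
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), n_a = na, n_b = nb)
}

#' Type-II GLM of a per-participant response on group, ISI and interaction
#'
#' Fits `response ~ group + isi + group:isi` by least squares and computes
#' type-II sums of squares (each main effect adjusted for the other main
#' effect, the interaction adjusted for both), the standard test when
#' group sizes are unequal and effects should respect marginality.
#'
#' @param response numeric vector, one value per participant (typically
#'   the grand-median H).
#' @param cohort data frame with columns `group` (factor) and `isi`.
#' @return object of class `glm_result`: data frame with one row per term
#'   (`group`, `isi`, `group:isi`) and columns `F`, `df1`, `df2`, `p`.
#' @export
glm_type2 <- function(response, cohort) {
  stopifnot(length(response) == nrow(cohort))
  if (nrow(cohort) <= 4L) stop("more observations than model terms required")
  dat <- data.frame(y = response, group = factor(cohort$group), isi = cohort$isi)
  if (nlevels(dat$group) < 2L) stop("rank-deficient design: a single group")
  if (stats::sd(dat$isi) == 0) stop("rank-deficient design: constant ISI")
  fit <- stats::lm(y ~ group * isi, data = dat)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design matrix")
  aov2 <- car::Anova(fit, type = "II")
  terms <- c("group", "isi", "group:isi")
  idx <- match(terms, rownames(aov2))
  df2 <- aov2$Df[rownames(aov2) == "Residuals"]
  out <- data.frame(
    term = terms,
    F = aov2$`F value`[idx],
    df1 = aov2$Df[idx],
    df2 = df2,
    p = aov2$`Pr(>F)`[idx],
    stringsAsFactors = FALSE
  )
  structure(out, class = c("glm_result", "data.frame"))
}

#' Eyes-open versus eyes-closed contrasts
#'
#' Per band: a paired Wilcoxon signed-rank test on the across-electrode
#' median H (EO minus EC), plus a dispersion contrast — a paired
#' signed-rank test on each participant's across-electrode interquartile
#' range of H, probing whether between-participant spatial variation
#' differs between conditions.
#'
#' @param hm_eo,hm_ec [h_matrix()] objects for the same participants.
#' @return data frame with one row per band: median paired difference,
#'   signed-rank `V` and `p` for level and for IQR dispersion.
#' @export
condition_contrast <- function(hm_eo, hm_ec) {
  stopifnot(inherits(hm_eo, "h_matrix"), inherits(hm_ec, "h_matrix"))
  if (!identical(dimnames(hm_eo)[[1]], dimnames(hm_ec)[[1]])) {
    stop("participant sets differ between conditions")
  }
  if (!identical(dim(hm_eo), dim(hm_ec))) stop("dimension mismatch")
  bm_eo <- band_median_h(hm_eo)
  bm_ec <- band_median_h(hm_ec)
  iqr_eo <- apply(unclass(hm_eo), c(1L, 3L), stats::IQR)
  iqr_ec <- apply(unclass(hm_ec), c(1L, 3L), stats::IQR)
  bands <- dimnames(hm_eo)[[3]]
  out <- lapply(seq_along(bands), function(b) {
    d <- bm_eo[, b] - bm_ec[, b]
    lev <- if (all(d == 0)) list(statistic = c(V = 0), p.value = 1) else {
      suppressWarnings(stats::wilcox.test(bm_eo[, b], bm_ec[, b],
                                          paired = TRUE, exact = FALSE))
    }
    dd <- iqr_eo[, b] - iqr_ec[, b]
    dis <- if (all(dd == 0)) list(statistic = c(V = 0), p.value = 1) else {
      suppressWarnings(stats::wilcox.test(iqr_eo[, b], iqr_ec[, b],
                                          paired = TRUE, exact = FALSE))
    }
    data.frame(band = bands[b],
               median_diff = stats::median(d),
               V = unname(lev$statistic), p = lev$p.value,
               iqr_median_diff = stats::median(dd),
               V_dispersion = unname(dis$statistic),
               p_dispersion = dis$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Within-group versus across-group correlation comparison
#'
#' Computes the ISI-response Spearman correlation within each group and
#' pooled across groups, plus a bootstrap distribution of the difference
#' (within-group minus pooled) to judge whether the association holds
#' more strongly within groups than across them — as happens when the
#' groups occupy offset ISI ranges with group-specific slopes.
#'
#' @param cohort data frame with `group` and `isi`.
#' @param response per-participant values (e.g., grand-median H).
#' @param n_boot bootstrap iterations for the difference distribution.
#' @param seed integer seed.
#' @return list with `within` (named rho per group), `pooled` rho, and
#'   `boot_diff` (matrix, one column per group, of within-minus-pooled
#'   bootstrap differences).
#' @export
within_vs_across_correlation <- function(cohort, response, n_boot = 1000L,
                                         seed = NULL) {
  stopifnot(nrow(cohort) == length(response))
  groups <- levels(factor(cohort$group))
  if (length(groups) < 2L) stop("need both groups")
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  within <- vapply(groups, function(g) {
    i <- cohort$group == g
    spearman_rho(cohort$isi[i], response[i])
  }, numeric(1))
  pooled <- spearman_rho(cohort$isi, response)
  boot_diff <- matrix(NA_real_, nrow = n_boot, ncol = length(groups),
                      dimnames = list(NULL, groups))
  n <- nrow(cohort)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- cohort$isi[idx]; yb <- response[idx]; gb <- cohort$group[idx]
    if (stats::sd(xb) == 0 || stats::sd(yb) == 0) next
    pb <- stats::cor(xb, yb, method = "spearman")
    for (gi in seq_along(groups)) {
      i <- gb == groups[gi]
      if (sum(i) >= 3L && stats::sd(xb[i]) > 0 && stats::sd(yb[i]) > 0) {
        boot_diff[b, gi] <- stats::cor(xb[i], yb[i], method = "spearman") - pb
      }
    }
  }
  list(within = within, pooled = pooled, boot_diff = boot_diff)
}
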
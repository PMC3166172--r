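#' Gene-wise mixed-effects dose model (maximum likelihood)
#'
#' Fits, for one gene (deletion strain), the model
#' `Y_ij = mu + u_i + delta * [tag = DOWN] + beta_d(i) + e_ij`
#' where `i` indexes chips and `j` the UP/DOWN barcode measurement: `mu` is
#' the mean UP-barcode control signal, `u_i ~ N(0, sigma_chip^2)` a random
#' chip effect capturing the correlation between the two barcode
#' measurements on a chip, `delta` the average DOWN-minus-UP offset (fixed),
#' and `beta_d` categorical dose effects relative to control (fixed). The
#' reduced model omits all `beta_d`. Fitting is by full ML (not REML) so
#' likelihoods are comparable across fixed-effect structures.
#'
#' For complete data (both tags on every chip) the ML problem separates
#' exactly into two independent regressions -- chip means carry the dose
#' effects with variance `sigma_chip^2 + sigma_res^2 / 2`, within-chip tag
#' differences carry `delta` with variance `2 sigma_res^2` -- so estimates
#' are closed form, with the boundary `sigma_chip = 0` handled explicitly.
#' Chips with one masked tag are kept via a one-dimensional profile of the
#' variance ratio; measurements are never imputed.
#'
#' @param up,down numeric vectors of log2 values per chip (NA = masked).
#' @param dose factor/character of dose groups per chip, `"control"` plus
#'   the dose levels.
#' @param full logical: fit the full (dose) model or the reduced one.
#' @return list: `loglik`, `mu`, `delta`, `beta` (named, full model only),
#'   `sigma_chip`, `sigma_res`, `n_obs`, `fitted_by` ("closed_form" or
#'   "profiled").
#' @export
fit_gene_model <- function(up, down, dose, full = TRUE) {
  stopifnot(length(up) == length(down), length(dose) == length(up))
  dose <- droplevels(factor(dose, levels = c("control",
                                             setdiff(unique(as.character(dose)),
                                                     "control"))))
  keep <- !(is.na(up) & is.na(down))
  up <- up[keep]; down <- down[keep]; dose <- droplevels(dose[keep])
  if (any(table(dose) < 2L)) stop("need >=2 chips per dose group")
  if (!any(is.na(up)) && !any(is.na(down))) {
    fit_balanced(up, down, dose, full)
  } else {
    fit_profiled(up, down, dose, full)
  }
}

## exact ML for complete data via the mean/difference decomposition
fit_balanced <- function(up, down, dose, full) {
  n <- length(up)
  m <- (up + down) / 2           # chip means: mu + delta/2 + beta + u + eb
  d <- down - up                 # tag differences: delta + noise
  x <- if (full && nlevels(dose) > 1L) stats::model.matrix(~dose) else
    matrix(1, n, 1L)
  qr_x <- qr(x)
  res_m <- qr.resid(qr_x, m)
  coef_m <- qr.coef(qr_x, m)
  ss_m <- sum(res_m^2)
  delta <- mean(d)
  ss_d <- sum((d - delta)^2)
  v_m <- ss_m / n                # = sigma_chip^2 + sigma_res^2/2 at ML
  v_d <- ss_d / n                # = 2 sigma_res^2 at ML
  if (v_m >= v_d / 4) {
    sigma_res2 <- v_d / 2
    sigma_chip2 <- v_m - v_d / 4
  } else {                       # boundary: sigma_chip = 0, pooled residual
    sigma_res2 <- (ss_m + ss_d / 4) / n
    sigma_chip2 <- 0
    v_m <- sigma_res2 / 2
    v_d <- 2 * sigma_res2
  }
  ll <- gaussian_profile_ll(ss_m, v_m, n) + gaussian_profile_ll(ss_d, v_d, n)
  beta <- NULL
  if (full && nlevels(dose) > 1L) {
    beta <- coef_m[-1L]
    names(beta) <- levels(dose)[-1L]
  }
  list(loglik = ll, mu = unname(coef_m[1L]) - delta / 2, delta = delta,
       beta = beta, sigma_chip = sqrt(sigma_chip2),
       sigma_res = sqrt(sigma_res2), n_obs = 2L * n, n_chips = n,
       ss_m = ss_m, rank_m = ncol(x), fitted_by = "closed_form")
}

## -n/2 log(2 pi v) - ss / (2 v); the variance floor keeps degenerate
## zero-variance fits finite and makes their LRTs cancel exactly (sums of
## squares at rounding-noise scale would otherwise produce spurious LRTs)
gaussian_profile_ll <- function(ss, v, n) {
  v <- max(v, 1e-12)
  -n / 2 * log(2 * pi * v) - ss / (2 * v)
}

## general ML with single-tag chips: profile lambda = sigma_chip^2/sigma_res^2
fit_profiled <- function(up, down, dose, full) {
  y <- c(up, down)
  tag_down <- rep(c(0, 1), each = length(up))
  chip <- rep(seq_along(up), 2L)
  dd <- rep(as.character(dose), 2L)
  ok <- !is.na(y)
  y <- y[ok]; tag_down <- tag_down[ok]; chip <- chip[ok]; dd <- dd[ok]
  dd <- factor(dd, levels = levels(dose))
  x <- if (full && nlevels(dose) > 1L)
    stats::model.matrix(~tag_down + dd) else stats::model.matrix(~tag_down)
  nll <- function(log_lambda) neg_prof_ll(exp(log_lambda), y, x, chip)$nll
  opt <- stats::optimize(nll, c(-12, 12))
  cand <- neg_prof_ll(exp(opt$minimum), y, x, chip)
  at0 <- neg_prof_ll(0, y, x, chip)
  best <- if (at0$nll <= cand$nll) at0 else cand
  cf <- best$coef
  beta <- NULL
  if (full && nlevels(dose) > 1L) {
    beta <- cf[-(1:2)]
    names(beta) <- levels(dose)[-1L]
  }
  list(loglik = -best$nll, mu = unname(cf[1L]), delta = unname(cf[2L]),
       beta = beta, sigma_chip = sqrt(best$lambda * best$sigma2),
       sigma_res = sqrt(best$sigma2), n_obs = length(y),
       n_chips = length(unique(chip)), ss_m = NA_real_, rank_m = ncol(x),
       fitted_by = "profiled")
}

## negative profiled log-likelihood at fixed variance ratio lambda:
## whiten each chip block of I + lambda * J, then GLS + profiled sigma^2
neg_prof_ll <- function(lambda, y, x, chip) {
  logdet <- 0
  yt <- y; xt <- x
  for (cid in unique(chip)) {
    idx <- which(chip == cid)
    k <- length(idx)
    if (k == 1L) {
      w <- 1 / sqrt(1 + lambda)
      logdet <- logdet + log(1 + lambda)
      yt[idx] <- y[idx] * w
      xt[idx, ] <- x[idx, , drop = FALSE] * w
    } else {                     # k == 2: sum/difference directions
      s <- (y[idx[1L]] + y[idx[2L]]) / sqrt(2)
      ddf <- (y[idx[1L]] - y[idx[2L]]) / sqrt(2)
      xs <- (x[idx[1L], ] + x[idx[2L], ]) / sqrt(2)
      xd <- (x[idx[1L], ] - x[idx[2L], ]) / sqrt(2)
      ws <- 1 / sqrt(1 + 2 * lambda)
      logdet <- logdet + log(1 + 2 * lambda)
      yt[idx] <- c(s * ws, ddf)
      xt[idx, ] <- rbind(xs * ws, xd)
    }
  }
  fit <- stats::lm.fit(xt, yt)
  n <- length(y)
  rss <- sum(fit$residuals^2)
  sigma2 <- max(rss / n, 1e-300)
  nll <- n / 2 * log(2 * pi * sigma2) + rss / (2 * sigma2) + logdet / 2
  list(nll = nll, coef = fit$coefficients, sigma2 = sigma2, lambda = lambda)
}

#' Likelihood-ratio test for dose effects in one gene
#'
#' Compares the full mixed model against the reduced model without dose
#' effects: `LRT = 2 (loglik_full - loglik_reduced)`, clipped at zero.
#' Two p-values are computed: `p_chisq` refers the statistic to a
#' chi-square with df = number of dose levels (the large-sample reference),
#' and the default `p_raw` uses the exact finite-sample distribution of the
#' same statistic -- for complete balanced data the LRT is a monotone
#' transform of the dose F statistic on the chip means, so
#' `F = ((exp(LRT/n) - 1) * (n - p)) / q` follows `F(q, n - p)` under the
#' null. At 21 chips the chi-square reference is noticeably anticonservative
#' while the F reference is exact; see the methods vignette.
#'
#' @inheritParams fit_gene_model
#' @param p_method `"f"` (finite-sample, default) or `"chisq"`.
#' @return list: `lrt`, `df`, `p_raw`, `p_chisq`, `full`, `reduced`.
#' @export
lrt_dose <- function(up, down, dose, p_method = c("f", "chisq")) {
  p_method <- match.arg(p_method)
  f_full <- fit_gene_model(up, down, dose, full = TRUE)
  f_red <- fit_gene_model(up, down, dose, full = FALSE)
  q <- length(f_full$beta)
  lrt <- max(0, 2 * (f_full$loglik - f_red$loglik))
  p_chisq <- stats::pchisq(lrt, df = q, lower.tail = FALSE)
  if (f_full$fitted_by == "closed_form" && f_full$ss_m >= 0) {
    n <- f_full$n_chips
    p_f <- f_stat_p(f_red$ss_m, f_full$ss_m, q, n - f_full$rank_m)
  } else {
    p_f <- p_chisq
  }
  p_raw <- if (p_method == "f") p_f else p_chisq
  list(lrt = lrt, df = q, p_raw = p_raw, p_chisq = p_chisq,
       full = f_full, reduced = f_red)
}

f_stat_p <- function(ss_red, ss_full, q, df2) {
  if (ss_full <= 1e-12) return(if (ss_red <= 1e-12) 1 else 0)
  fstat <- ((ss_red - ss_full) / q) / (ss_full / df2)
  stats::pf(pmax(fstat, 0), q, df2, lower.tail = FALSE)
}

#' Vectorized dose-model LRT over many genes
#'
#' Closed-form version of [lrt_dose()] for complete balanced data, applied
#' to whole matrices at once (one row per gene). Used by the calibration
#' and power simulations; agrees with the per-gene fit exactly.
#'
#' @param up,down numeric matrices, rows genes, columns chips.
#' @param dose dose group per chip (length = ncol).
#' @param p_method `"f"` (finite-sample, default) or `"chisq"`.
#' @return data.frame: gene, mu, delta, beta columns, sigma_chip, sigma_res,
#'   lrt, df, p_raw, p_chisq.
#' @export
lrt_dose_matrix <- function(up, down, dose, p_method = c("f", "chisq")) {
  p_method <- match.arg(p_method)
  stopifnot(is.matrix(up), is.matrix(down), all(dim(up) == dim(down)),
            ncol(up) == length(dose), !anyNA(up), !anyNA(down))
  dose <- droplevels(factor(dose, levels = c("control",
                                             setdiff(unique(as.character(dose)),
                                                     "control"))))
  n <- ncol(up)
  g <- nrow(up)
  m <- (up + down) / 2
  d <- down - up
  x <- stats::model.matrix(~dose)
  q <- ncol(x) - 1L
  qr_x <- qr(x)
  res_full <- t(qr.resid(qr_x, t(m)))
  coefs <- qr.coef(qr_x, t(m))
  ss_m_full <- rowSums(res_full^2)
  mbar <- rowMeans(m)
  ss_m_red <- rowSums((m - mbar)^2)
  delta <- rowMeans(d)
  ss_d <- rowSums((d - delta)^2)

  ll <- function(ss_m, ss_d) {
    v_m <- ss_m / n
    v_d <- ss_d / n
    bound <- v_m < v_d / 4
    s2 <- ifelse(bound, (ss_m + ss_d / 4) / n, v_d / 2)
    v_m2 <- ifelse(bound, s2 / 2, v_m)
    v_d2 <- ifelse(bound, 2 * s2, v_d)
    sigma_chip <- sqrt(pmax(v_m2 - v_d2 / 4, 0))
    list(ll = gaussian_profile_ll_vec(ss_m, v_m2, n) +
           gaussian_profile_ll_vec(ss_d, v_d2, n),
         sigma_chip = sigma_chip, sigma_res = sqrt(v_d2 / 2))
  }
  lf <- ll(ss_m_full, ss_d)
  lr <- ll(ss_m_red, ss_d)
  lrt <- pmax(0, 2 * (lf$ll - lr$ll))
  p_chisq <- stats::pchisq(lrt, df = q, lower.tail = FALSE)
  df2 <- n - ncol(x)
  fstat <- ((ss_m_red - ss_m_full) / q) / pmax(ss_m_full / df2, 1e-300)
  p_f <- stats::pf(pmax(fstat, 0), q, df2, lower.tail = FALSE)
  degen <- ss_m_full <= 1e-12 & ss_m_red <= 1e-12
  p_f[degen] <- 1
  out <- data.frame(gene = rownames(up) %||% sprintf("g%05d", seq_len(g)),
                    mu = coefs[1L, ] - delta / 2, delta = delta,
                    stringsAsFactors = FALSE)
  if (q > 0) {
    b <- t(coefs)[, -1L, drop = FALSE]
    colnames(b) <- paste0("beta_", levels(dose)[-1L])
    out <- cbind(out, b)
  }
  out$sigma_chip <- lf$sigma_chip
  out$sigma_res <- lf$sigma_res
  out$lrt <- lrt
  out$df <- q
  out$p_raw <- if (p_method == "f") p_f else p_chisq
  out$p_chisq <- p_chisq
  rownames(out) <- NULL
  out
}

gaussian_profile_ll_vec <- function(ss, v, n) {
  v <- pmax(v, 1e-12)
  -n / 2 * log(2 * pi * v) - ss / (2 * v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Holm step-down familywise error correction
#'
#' Adjusts p-values by the Holm step-down procedure: sort ascending,
#' multiply the i-th smallest by (m - i + 1), enforce monotonicity, cap at
#' one, and return in the input order. Genes are `selected` at an adjusted
#' 0.05 downstream.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
holm_correct <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Kruskal-Wallis dose-response statistic for one gene
#'
#' Rank-based k-group statistic (tie corrected) comparing chip-level values
#' across the control and dose groups; used as the gene-level statistic for
#' graph-aware pathway enrichment. `H = 0` when all observations tie.
#'
#' @param values numeric vector of chip-level values for one gene.
#' @param groups group label per value (control + dose levels).
#' @return list: `H`, `df`, `group_sizes`, `tie_corrected`, `p_chisq`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 1L)) stop("every group needs >=1 observation")
  h <- kw_statistic(matrix(values, nrow = 1L), groups)
  list(H = h, df = nlevels(groups) - 1L,
       group_sizes = as.integer(sizes),
       tie_corrected = anyDuplicated(values) > 0L,
       p_chisq = stats::pchisq(h, nlevels(groups) - 1L, lower.tail = FALSE))
}

#' Row-wise Kruskal-Wallis statistics
#'
#' Tie-corrected Kruskal-Wallis H for every row of a matrix against a
#' common grouping; the workhorse behind [kruskal_wallis()] and the
#' per-gene statistics fed to [sepea_test()]. Rows where all values tie
#' return 0.
#'
#' @param m numeric matrix, rows genes, columns observations (chips).
#' @param groups group label per column.
#' @return numeric vector of H statistics, one per row.
#' @export
kw_statistic <- function(m, groups) {
  stopifnot(is.matrix(m), ncol(m) == length(groups))
  groups <- factor(groups)
  n <- ncol(m)
  idx <- split(seq_len(n), groups)
  h <- apply(m, 1L, function(v) {
    r <- rank(v)
    stat <- 12 / (n * (n + 1)) *
      sum(vapply(idx, function(i) length(i) * (mean(r[i]) - (n + 1) / 2)^2,
                 numeric(1)))
    ties <- table(v)
    corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    if (corr <= 0) 0 else stat / corr
  })
  unname(h)
}
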
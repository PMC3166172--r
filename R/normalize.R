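#' Faster cyclic loess (fastlo) normalization of chip signals
#'
#' Iteratively removes intensity-dependent chip effects from a matrix of
#' log2 signals. In each sweep the reference "pseudo-chip" A is the row-wise
#' mean across chips; for every chip the deviation M = chip - A is smoothed
#' against A with a robust local regression (tricube weights, two
#' robustifying iterations) and the fitted trend is subtracted. Sweeps
#' repeat until the largest absolute adjustment falls below `tol` or
#' `max_iter` is reached. One fit per chip per sweep -- rather than a fit
#' for every chip pair -- is what makes the cyclic loess "faster".
#'
#' UP and DOWN barcode measurements of a strain are normalized as separate
#' rows; average them afterwards with [regroup_tags()]. `NA` cells are
#' treated as masked: they are excluded from the reference mean and from the
#' fits, and are never modified.
#'
#' @param m numeric matrix, rows measurements (e.g. `strain|tag`), columns
#'   chips. `NA` allowed; infinite values are an error.
#' @param span loess span in (0, 1].
#' @param max_iter maximum number of sweeps.
#' @param tol convergence threshold on the maximum absolute adjustment,
#'   log2 units.
#' @return list: `matrix` (normalized, same dimnames), `report` (list with
#'   `iterations`, `max_adjustment` per sweep, `converged`).
#' @export
fastlo_normalize <- function(m, span = 0.4, max_iter = 10L, tol = 0.01) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2L) stop("need at least 2 chips to normalize against")
  if (!(span > 0 && span <= 1)) stop("span must lie in (0, 1]")
  if (any(is.infinite(m))) stop("non-finite (infinite) values in input")
  x <- m
  max_adj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    a <- rowMeans(x, na.rm = TRUE)
    adj <- matrix(NA_real_, nrow(x), ncol(x))
    for (j in seq_len(ncol(x))) {
      ok <- !is.na(x[, j]) & !is.na(a)
      if (sum(ok) < 4L) next
      mm <- x[ok, j] - a[ok]
      fit <- stats::lowess(a[ok], mm, f = span, iter = 2L)
      adj[ok, j] <- stats::approx(fit$x, fit$y, xout = a[ok], rule = 2L,
                                  ties = mean)$y
    }
    ## remove the common-mode component: a curve subtracted from every chip
    ## would only shift the reference A, not the deviations M, so it can
    ## never converge away -- only between-chip differences are corrected
    adj <- adj - rowMeans(adj, na.rm = TRUE)
    adj[is.na(adj)] <- 0
    x <- x - adj
    sweep_max <- max(abs(adj))
    max_adj <- c(max_adj, sweep_max)
    if (sweep_max < tol) {
      converged <- TRUE
      break
    }
  }
  list(matrix = x,
       report = list(iterations = length(max_adj),
                     max_adjustment = max_adj,
                     converged = converged))
}

#' Regroup UP/DOWN tag measurements to per-strain chip values
#'
#' After normalization the two barcode measurements of each strain are
#' averaged per chip. If one tag is masked (`NA`) the other is used alone;
#' if both are masked the strain stays masked on that chip.
#'
#' @param m matrix as produced by [generate_pool()] / [fastlo_normalize()]:
#'   rows named `<strain>|<tag>`, or carrying `strain`/`tag` attributes.
#' @return numeric matrix, one row per strain, same chip columns.
#' @export
regroup_tags <- function(m) {
  stopifnot(is.matrix(m))
  strain <- attr(m, "strain")
  if (is.null(strain)) {
    parts <- strsplit(rownames(m), "|", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("rownames must look like '<strain>|<tag>' when no strain attribute")
    strain <- vapply(parts, `[[`, "", 1L)
  }
  idx <- split(seq_len(nrow(m)), factor(strain, levels = unique(strain)))
  vals <- vapply(idx, function(i) colMeans(m[i, , drop = FALSE], na.rm = TRUE),
                 numeric(ncol(m)))
  out <- t(matrix(vals, nrow = ncol(m)))
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(names(idx), colnames(m))
  out
}
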
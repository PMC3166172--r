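#' Per-strain fitness scores for one treatment condition
#'
#' The fitness score of a deletion strain under a treatment is the
#' difference in mean log2 hybridization signal between treated and control
#' chips: `mean(log2 treated) - mean(log2 control)`. Negative scores mean
#' the strain depleted from the pool, i.e. the deleted gene is required for
#' tolerance of the compound.
#'
#' @param values numeric matrix of chip-level log2 values, rows strains,
#'   columns chips (typically from [regroup_tags()]).
#' @param design design table with columns chip, compound, dose_group,
#'   generation.
#' @param condition list or one-row data.frame with `compound`,
#'   `dose_group`, `generation` identifying the treatment.
#' @return named numeric vector of fitness scores, one per strain.
#' @export
fitness_scores <- function(values, design, condition) {
  grp <- condition_columns(values, design, condition)
  rowMeans(values[, grp$treated, drop = FALSE], na.rm = TRUE) -
    rowMeans(values[, grp$control, drop = FALSE], na.rm = TRUE)
}

## resolve treated/control chip columns for a condition; controls share the
## compound's normalization batch and the condition's generation point
condition_columns <- function(values, design, condition) {
  stopifnot(all(c("chip", "dose_group", "generation") %in% names(design)))
  comp_ok <- if (is.null(condition$compound)) TRUE else
    design$compound == condition$compound
  treated <- design$chip[design$dose_group == condition$dose_group &
                           design$generation == condition$generation &
                           comp_ok]
  control <- design$chip[design$dose_group == "control" &
                           design$generation == condition$generation]
  treated <- intersect(treated, colnames(values))
  control <- intersect(control, colnames(values))
  if (length(treated) < 2L || length(control) < 2L)
    stop("condition needs >=2 treated and >=2 control chips (found ",
         length(treated), "/", length(control), ")")
  list(treated = treated, control = control)
}

#' Per-strain significance of a treatment effect
#'
#' Compares treated against control chip-level values strain by strain with
#' a two-sample t statistic, two-sided p-values, and Benjamini-Hochberg
#' q-values within the condition. The default pools the group variances
#' (df = n_t + n_c - 2): with only three treated chips the Welch statistic
#' has about two effective degrees of freedom, which is far too few for any
#' strain to survive a q-value cutoff however large its depletion, while
#' the generative model gives both groups the same variance by symmetry.
#' `method = "welch"` selects the unequal-variance statistic instead.
#' Strains with identical constant values in both groups get p = 1 by
#' convention.
#'
#' @inheritParams fitness_scores
#' @param alpha q-value significance cutoff (default 0.05).
#' @param method `"pooled"` (default) or `"welch"`.
#' @return data.frame: strain, score, t, df, p_value, q_value, significant.
#' @export
dssa_significance <- function(values, design, condition, alpha = 0.05,
                              method = c("pooled", "welch")) {
  method <- match.arg(method)
  grp <- condition_columns(values, design, condition)
  xt <- values[, grp$treated, drop = FALSE]
  xc <- values[, grp$control, drop = FALSE]
  wt <- ttest_rows(xt, xc, method)
  q <- stats::p.adjust(wt$p, method = "BH")
  data.frame(strain = rownames(values),
             score = wt$mean_x - wt$mean_y,
             t = wt$t, df = wt$df, p_value = wt$p, q_value = q,
             significant = q < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

## row-wise two-sample t test (pooled or Welch); degenerate rows (zero
## variance in both groups) fall back to p = 1 when means are equal, p = 0
## if they differ exactly
ttest_rows <- function(x, y, method = "pooled") {
  nx <- rowSums(!is.na(x))
  ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE)
  my <- rowMeans(y, na.rm = TRUE)
  vx <- apply(x, 1L, stats::var, na.rm = TRUE)
  vy <- apply(y, 1L, stats::var, na.rm = TRUE)
  if (method == "pooled") {
    sp2 <- ((nx - 1L) * vx + (ny - 1L) * vy) / (nx + ny - 2L)
    se2 <- sp2 * (1 / nx + 1 / ny)
    df <- nx + ny - 2L
  } else {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
  }
  tstat <- (mx - my) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero <- se2 == 0 | !is.finite(tstat)
  p[zero] <- ifelse(abs(mx - my)[zero] < .Machine$double.eps^0.5, 1, 0)
  list(t = tstat, df = df, p = p, mean_x = mx, mean_y = my)
}

#' Differential strain sensitivity analysis over all conditions
#'
#' Runs [dssa_significance()] for every (dose_group, generation)
#' combination of a compound present in the design and stacks the results
#' into one long fitness table.
#'
#' @inheritParams fitness_scores
#' @param compound compound label; defaults to the single non-control
#'   compound in the design.
#' @param alpha q-value cutoff per condition.
#' @param method t statistic flavor, see [dssa_significance()].
#' @return data.frame: strain, compound, dose_group, generation, score, t,
#'   df, p_value, q_value, significant.
#' @export
dssa <- function(values, design, compound = NULL, alpha = 0.05,
                 method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (is.null(compound)) {
    comp <- unique(design$compound[design$dose_group != "control"])
    if (length(comp) != 1L)
      stop("specify 'compound'; design contains: ", paste(comp, collapse = ", "))
    compound <- comp
  }
  conds <- unique(design[design$dose_group != "control" &
                           design$compound == compound,
                         c("dose_group", "generation")])
  conds <- conds[order(conds$generation, conds$dose_group), ]
  out <- lapply(seq_len(nrow(conds)), function(i) {
    cond <- list(compound = compound, dose_group = conds$dose_group[i],
                 generation = conds$generation[i])
    res <- dssa_significance(values, design, cond, alpha = alpha,
                             method = method)
    cbind(data.frame(strain = res$strain, compound = compound,
                     dose_group = cond$dose_group,
                     generation = cond$generation,
                     stringsAsFactors = FALSE),
          res[, setdiff(names(res), "strain")])
  })
  do.call(rbind, out)
}

#' Consensus filter: genes significant in at least k of a compound's conditions
#'
#' Flags genes whose number of significant conditions reaches `k_min` out of
#' the compound's six (3 doses x 2 generations) treatments. With
#' `sign = "negative_only"` only significant conditions with negative
#' fitness scores are counted (the sensitive-gene framing); the default
#' `"any"` counts significance of either sign, since resistant
#' (positive-score) calls can appear among consensus genes.
#'
#' Accepts either a long DSSA table (from [dssa()]) or a wide fixture table
#' (from [read_consensus_fixture()]), where a non-missing score cell means
#' the gene was significant in that condition.
#'
#' @param tab long fitness table or wide fixture table.
#' @param k_min minimum number of significant conditions (default 3).
#' @param sign `"any"` or `"negative_only"`.
#' @return list: `genes` (character vector of consensus genes), `counts`
#'   (data.frame gene / n_significant_conditions for all genes with >= 1).
#' @export
consensus_filter <- function(tab, k_min = 3L, sign = c("any", "negative_only")) {
  sign <- match.arg(sign)
  if (all(c("strain", "significant", "score") %in% names(tab))) {
    hit <- tab$significant & (sign == "any" | tab$score < 0)
    counts <- tapply(hit, tab$strain, sum)
  } else {
    score_cols <- grep("^g[0-9]+_dose", names(tab), value = TRUE)
    if (!length(score_cols)) stop("unrecognized table layout")
    sc <- as.matrix(tab[, score_cols])
    hit <- !is.na(sc) & (sign == "any" | sc < 0)
    counts <- rowSums(hit)
    names(counts) <- if (!is.null(tab$orf)) tab$orf else rownames(tab)
  }
  counts <- counts[counts > 0L]
  counts <- sort(counts, decreasing = TRUE)
  list(genes = names(counts)[counts >= k_min],
       counts = data.frame(gene = names(counts),
                           n_significant_conditions = as.integer(counts),
                           row.names = NULL, stringsAsFactors = FALSE))
}
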
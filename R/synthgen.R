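#' Pool design for a synthetic deletion-collection screen
#'
#' Describes the layout of a pooled fitness screen: how many deletion strains
#' are in the pool, how many untreated control chips are hybridized, and how
#' many replicate chips are grown at each dose level and generation point.
#' The defaults emulate a genome-scale screen of the homozygous diploid
#' deletion collection: 4,607 strains, 12 rich-media control chips, three
#' biological replicates at each of three doses (25/50/100 percent of the
#' IC20), harvested after 5 and 15 population doublings.
#'
#' Signals are simulated directly on the log2 scale as an additive model:
#' strain baseline + chip random effect + tag offset (DOWN tags are shifted
#' by a systematic amount relative to UP tags) + planted depletion + noise.
#' A planted growth-rate defect `d` (fraction per doubling) depletes the
#' strain by `d * generations` log2 units, i.e. one doubling of unaffected
#' competitors costs a fully blocked strain one log2 unit of signal.
#'
#' @param n_strains number of deletion strains in the pool.
#' @param n_controls number of control chips per generation point.
#' @param n_reps_per_dose replicate chips per (dose, generation).
#' @param dose_levels character vector of dose-group labels (no control label).
#' @param generations numeric vector of generation (doubling) counts.
#' @param tag_offset systematic DOWN-minus-UP offset, log2 units.
#' @param chip_sd SD of the per-chip random effect, log2 units.
#' @param noise_sd SD of the per-measurement noise, log2 units.
#' @param baseline_mean,baseline_sd distribution of per-strain baseline
#'   log2 signal.
#' @param compound label recorded in the design table.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return An object of class `pool_design` (a list of the above).
#' @export
pool_design <- function(n_strains = 4607L,
                        n_controls = 12L,
                        n_reps_per_dose = 3L,
                        dose_levels = c("25", "50", "100"),
                        generations = c(5, 15),
                        tag_offset = 0.5,
                        chip_sd = 0.2,
                        noise_sd = 0.3,
                        baseline_mean = 10,
                        baseline_sd = 1,
                        compound = "HQ",
                        seed = 1L) {
  stopifnot(n_strains >= 1, n_controls >= 2, n_reps_per_dose >= 2,
            length(dose_levels) >= 1, length(generations) >= 1,
            chip_sd >= 0, noise_sd >= 0, baseline_sd >= 0)
  if ("control" %in% dose_levels)
    stop("'control' is reserved; dose_levels must not include it")
  if (anyDuplicated(dose_levels))
    stop("duplicate dose levels")
  structure(list(n_strains = as.integer(n_strains),
                 n_controls = as.integer(n_controls),
                 n_reps_per_dose = as.integer(n_reps_per_dose),
                 dose_levels = as.character(dose_levels),
                 generations = as.numeric(generations),
                 tag_offset = tag_offset, chip_sd = chip_sd,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, compound = compound,
                 seed = as.integer(seed)),
            class = "pool_design")
}

#' Planted ground truth for sensitive strains
#'
#' Builds the truth table for strains that are planted as sensitive: a
#' growth-rate defect per dose group, expanded to the expected log2
#' depletion at every (dose, generation) combination of a design.
#'
#' @param strain_id character vector of strain ids.
#' @param defect numeric, fraction of growth lost per doubling, in `[0, 1]`.
#'   Recycled against `strain_id`. Alternatively a matrix with one column
#'   per dose level for dose-specific defects.
#' @param design a [pool_design()].
#' @return data.frame with columns strain_id, dose_group, generation,
#'   defect, expected_log2_depletion.
#' @export
planted_truth <- function(strain_id, defect, design) {
  stopifnot(inherits(design, "pool_design"))
  if (anyDuplicated(strain_id)) stop("duplicate strain ids in planted set")
  if (is.matrix(defect)) {
    stopifnot(ncol(defect) == length(design$dose_levels),
              nrow(defect) == length(strain_id))
  } else {
    defect <- matrix(rep_len(defect, length(strain_id) * length(design$dose_levels)),
                     nrow = length(strain_id))
  }
  if (any(defect < 0 | defect > 1)) stop("defect must lie in [0, 1]")
  grid <- expand.grid(i = seq_along(strain_id),
                      d = seq_along(design$dose_levels),
                      generation = design$generations,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(strain_id = strain_id[grid$i],
             dose_group = design$dose_levels[grid$d],
             generation = grid$generation,
             defect = defect[cbind(grid$i, grid$d)],
             expected_log2_depletion = defect[cbind(grid$i, grid$d)] * grid$generation,
             stringsAsFactors = FALSE)
}

chip_ids <- function(design) {
  rows <- list()
  for (g in design$generations) {
    rows[[length(rows) + 1L]] <- data.frame(
      chip = sprintf("ctrl_g%g_r%02d", g, seq_len(design$n_controls)),
      compound = design$compound, dose_group = "control",
      generation = g, replicate = seq_len(design$n_controls),
      stringsAsFactors = FALSE)
    for (d in design$dose_levels) {
      rows[[length(rows) + 1L]] <- data.frame(
        chip = sprintf("%s_d%s_g%g_r%02d", design$compound, d, g,
                       seq_len(design$n_reps_per_dose)),
        compound = design$compound, dose_group = d,
        generation = g, replicate = seq_len(design$n_reps_per_dose),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic pooled-screen intensity matrix
#'
#' Simulates log2 barcode hybridization signals for every strain (one UP and
#' one DOWN tag measurement per chip) under the layout of `design`, with
#' planted strains depleted on treated chips according to their expected
#' log2 depletion. Output is byte-identical for identical seeds; the global
#' RNG state is left untouched.
#'
#' @param design a [pool_design()].
#' @param planted optional truth table from [planted_truth()] (its strain
#'   ids must exist in the pool).
#' @return list with elements `intensity` (numeric matrix, rows named
#'   `<strain>|UP` / `<strain>|DOWN`, columns chips; attributes `strain` and
#'   `tag`), `design_table` (chip annotations: chip, compound, dose_group,
#'   generation, replicate) and `truth` (the expanded planted table, empty
#'   if nothing planted).
#' @export
generate_pool <- function(design, planted = NULL) {
  stopifnot(inherits(design, "pool_design"))
  strains <- sprintf("S%04d", seq_len(design$n_strains))
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("strain_id", "dose_group", "generation",
                    "expected_log2_depletion") %in% names(planted)))
    bad <- setdiff(unique(planted$strain_id), strains)
    if (length(bad))
      stop("planted strain ids not in pool: ", paste(utils::head(bad, 3), collapse = ", "))
  } else {
    planted <- data.frame(strain_id = character(), dose_group = character(),
                          generation = numeric(),
                          expected_log2_depletion = numeric())
  }
  dtab <- chip_ids(design)
  n_chip <- nrow(dtab)
  tags <- c("UP", "DOWN")
  rn <- as.vector(t(outer(strains, tags, paste, sep = "|")))
  strain_of_row <- rep(strains, each = 2L)
  tag_of_row <- rep(tags, times = design$n_strains)

  y <- withr::with_seed(design$seed, {
    baseline <- stats::rnorm(design$n_strains, design$baseline_mean,
                             design$baseline_sd)
    chip_eff <- stats::rnorm(n_chip, 0, design$chip_sd)
    m <- matrix(rep(baseline, each = 2L), nrow = 2L * design$n_strains,
                ncol = n_chip)
    m <- m + rep(chip_eff, each = 2L * design$n_strains)
    m[tag_of_row == "DOWN", ] <- m[tag_of_row == "DOWN", ] + design$tag_offset
    if (nrow(planted)) {
      ridx <- match(planted$strain_id, strains)
      for (k in seq_len(nrow(planted))) {
        cols <- which(dtab$dose_group == planted$dose_group[k] &
                        dtab$generation == planted$generation[k])
        rows <- c(2L * ridx[k] - 1L, 2L * ridx[k])
        m[rows, cols] <- m[rows, cols] - planted$expected_log2_depletion[k]
      }
    }
    m + stats::rnorm(length(m), 0, design$noise_sd)
  })
  dimnames(y) <- list(rn, dtab$chip)
  attr(y, "strain") <- strain_of_row
  attr(y, "tag") <- tag_of_row
  list(intensity = y, design_table = dtab, truth = planted)
}

#' Generate synthetic pathway graphs with planted perturbation structure
#'
#' Builds a collection of connected undirected pathway graphs over a shared
#' gene universe. One pathway carries a planted set of perturbed genes that
#' is either `clustered` (the planted genes induce a connected subgraph) or
#' `scattered` (pairwise non-adjacent), used to probe topology-aware
#' enrichment tests.
#'
#' @param n_pathways number of pathways.
#' @param sizes integer vector of candidate pathway sizes (each >= 3);
#'   sampled with replacement.
#' @param n_genes size of the gene universe.
#' @param planted_pathway index (1-based) of the pathway holding the planted
#'   genes, or `NA` for none.
#' @param n_planted number of planted perturbed genes.
#' @param adjacency_mode `"clustered"` or `"scattered"`.
#' @param seed integer seed.
#' @return list with `pathways` (list of lists: id, nodes, edges two-column
#'   matrix), `universe` (gene ids) and `planted_genes`.
#' @export
generate_pathways <- function(n_pathways = 10L, sizes = 8:20,
                              n_genes = 200L, planted_pathway = 1L,
                              n_planted = 3L,
                              adjacency_mode = c("clustered", "scattered"),
                              seed = 1L) {
  adjacency_mode <- match.arg(adjacency_mode)
  stopifnot(all(sizes >= 3), n_pathways >= 1)
  universe <- sprintf("G%04d", seq_len(n_genes))
  withr::with_seed(seed, {
    pws <- vector("list", n_pathways)
    planted_genes <- character()
    for (i in seq_len(n_pathways)) {
      sz <- if (length(sizes) == 1L) sizes else sample(sizes, 1L)
      nodes <- sample(universe, sz)
      ## random spanning tree keeps each pathway connected, plus a few
      ## extra edges for realistic cyclic structure
      parent <- vapply(2:sz, function(k) sample.int(k - 1L, 1L), integer(1))
      edges <- cbind(nodes[parent], nodes[2:sz])
      n_extra <- max(0L, round(sz / 4))
      if (n_extra > 0) {
        for (e in seq_len(n_extra)) {
          pair <- sample(nodes, 2L)
          edges <- rbind(edges, pair)
        }
        edges <- unique(t(apply(edges, 1L, sort)))
        edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
      }
      pws[[i]] <- list(id = sprintf("pw%02d", i), nodes = nodes,
                       edges = unname(edges))
      if (!is.na(planted_pathway) && i == planted_pathway) {
        if (n_planted > sz) stop("planted set larger than pathway")
        g <- igraph::graph_from_edgelist(pws[[i]]$edges, directed = FALSE)
        g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                                  name = setdiff(nodes, igraph::V(g)$name))
        planted_genes <- pick_planted(g, nodes, n_planted, adjacency_mode)
        pws[[i]]$planted <- planted_genes
      }
    }
    list(pathways = pws, universe = universe, planted_genes = planted_genes)
  })
}

## choose a planted node set that is connected (clustered) or an
## independent set (scattered) within pathway graph g
pick_planted <- function(g, nodes, n_planted, mode) {
  if (mode == "clustered") {
    start <- sample(nodes, 1L)
    sel <- start
    while (length(sel) < n_planted) {
      nb <- unlist(lapply(igraph::adjacent_vertices(g, sel), names),
                   use.names = FALSE)
      nb <- intersect(unique(setdiff(nb, sel)), nodes)
      if (!length(nb)) stop("cannot grow connected planted set")
      sel <- c(sel, sample(nb, 1L))
    }
    sel
  } else {
    sel <- character()
    cand <- nodes
    while (length(sel) < n_planted) {
      if (!length(cand)) stop("cannot place scattered planted set")
      pick <- sample(cand, 1L)
      sel <- c(sel, pick)
      nb <- names(igraph::adjacent_vertices(g, pick)[[1L]])
      cand <- setdiff(cand, c(pick, nb))
    }
    sel
  }
}

#' Generate a scored interaction network with a planted dense module
#'
#' Grows a preferential-attachment (Barabasi-Albert) graph, whose degree
#' distribution is heavy tailed like curated protein-interaction networks,
#' then plants a densely interconnected module of `planted_module_size`
#' nodes. Edge confidence scores are drawn uniformly in `[700, 1000]` so the
#' whole network survives a high-confidence score cutoff.
#'
#' @param n_nodes number of nodes.
#' @param m_attach edges added per step of preferential attachment.
#' @param degree_exponent power of preferential attachment (1 = linear).
#' @param planted_module_size size of the planted module (< n_nodes).
#' @param module_density fraction of within-module pairs connected.
#' @param seed integer seed.
#' @return list with `edges` (data.frame node_a, node_b, combined_score) and
#'   `module` (ids of planted module nodes).
#' @export
generate_network <- function(n_nodes = 500L, m_attach = 3L,
                             degree_exponent = 1,
                             planted_module_size = 12L,
                             module_density = 0.8, seed = 1L) {
  stopifnot(planted_module_size < n_nodes, module_density > 0,
            module_density <= 1)
  withr::with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, power = degree_exponent, m = m_attach,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("P%04d", seq_len(n_nodes))
    module <- sample(igraph::V(g)$name, planted_module_size)
    pairs <- t(utils::combn(module, 2L))
    keep <- stats::runif(nrow(pairs)) < module_density
    if (any(keep))
      g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(node_a = el[, 1L], node_b = el[, 2L],
                        combined_score = round(stats::runif(nrow(el), 700, 1000)),
                        stringsAsFactors = FALSE)
    list(edges = edges, module = sort(module))
  })
}

#' Generate logistic growth curves sampled like a plate reader
#'
#' Simulates optical-density time courses on a 15-minute grid over 24 hours
#' (97 points per well). Each well follows a lagged logistic curve
#' `od(t) = od0 + (capacity - od0) / (1 + exp(-rate * (t - lag - t_half)))`
#' re-anchored so growth starts from `od0`; dose acts multiplicatively on
#' the growth rate. Replicate wells share kinetic parameters and differ only
#' in measurement noise.
#'
#' @param wells data.frame with columns well, strain, compound, dose and
#'   optionally rate (1/h), lag (h), capacity, od0, rate_factor (dose
#'   multiplier on rate; default derived as `1 - dose_effect * dose`).
#' @param dose_effect fractional rate loss per unit dose when no explicit
#'   rate_factor column is given.
#' @param noise_sd OD measurement noise SD.
#' @param t_end,dt time span and step, hours.
#' @param seed integer seed.
#' @return long data.frame: well, strain, compound, dose, time_h, od.
#' @export
generate_growth_curves <- function(wells, dose_effect = 0, noise_sd = 0.003,
                                   t_end = 24, dt = 0.25, seed = 1L) {
  stopifnot(is.data.frame(wells), all(c("well", "dose") %in% names(wells)))
  defaults <- list(strain = "WT", compound = "none", rate = 0.45, lag = 2,
                   capacity = 1.2, od0 = 0.0165)
  for (nm in names(defaults))
    if (is.null(wells[[nm]])) wells[[nm]] <- defaults[[nm]]
  if (is.null(wells$rate_factor))
    wells$rate_factor <- pmax(0, 1 - dose_effect * wells$dose)
  if (any(wells$rate <= 0) || any(wells$capacity <= 0) || any(wells$od0 <= 0) ||
      any(wells$lag < 0))
    stop("kinetic parameters must be positive (lag may be zero)")
  times <- seq(0, t_end, by = dt)
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(wells)), function(i) {
      w <- wells[i, ]
      r <- w$rate * w$rate_factor
      od <- logistic_od(times, w$od0, w$capacity, r, w$lag)
      od <- od + stats::rnorm(length(times), 0, noise_sd)
      data.frame(well = w$well, strain = w$strain, compound = w$compound,
                 dose = w$dose, time_h = times, od = od,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

## noiseless lagged logistic; flat at od0 until lag, then logistic rise to
## capacity with specific rate r
logistic_od <- function(t, od0, capacity, r, lag) {
  if (r <= 0) return(rep(od0, length(t)))
  tt <- pmax(t - lag, 0)
  od0 * capacity / (od0 + (capacity - od0) * exp(-r * tt))
}

#' Read a shipped consensus-hit fixture table
#'
#' Loads one of the package's curated example tables of consensus-sensitive
#' genes from a benzene-metabolite deletion-pool screen (hydroquinone,
#' catechol or 1,2,4-benzenetriol). Each table lists one gene per row with
#' its fitness score (log2 ratio) in each of the six treatment conditions
#' (3 doses x 2 generation points); empty cells mean the gene was not
#' significant in that condition and are read as `NA`.
#'
#' @param compound one of `"HQ"`, `"CAT"`, `"BT"`.
#' @param path optional explicit path to a fixture in the same layout.
#' @return data.frame: orf, gene, and six score columns
#'   (g5_dose25 ... g15_dose100), `NA` where not significant.
#' @export
read_consensus_fixture <- function(compound = c("HQ", "CAT", "BT"),
                                   path = NULL) {
  if (is.null(path)) {
    compound <- match.arg(compound)
    fname <- c(HQ = "hq_consensus_hits.tsv", CAT = "cat_consensus_hits.tsv",
               BT = "bt_consensus_hits.tsv")[[compound]]
    path <- system.file("extdata", fname, package = "poolscreen",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = "",
                           check.names = FALSE, fileEncoding = "UTF-8")
  score_cols <- c("g5_dose25", "g5_dose50", "g5_dose100",
                  "g15_dose25", "g15_dose50", "g15_dose100")
  if (!all(c("orf", score_cols) %in% names(tab)))
    stop("malformed fixture: expected columns orf, gene, ",
         paste(score_cols, collapse = ", "))
  for (cc in score_cols) {
    v <- gsub("−", "-", tab[[cc]])
    tab[[cc]] <- as.numeric(v)
  }
  if (anyDuplicated(tab$orf)) stop("malformed fixture: duplicate ORFs")
  tab
}
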
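#' @title File formats: intensity and design tables, gene sets, edge lists,
#'   growth curves, linkage trees
#' @description Readers and writers for the plain-text formats used across
#'   the pipeline. All tables are UTF-8, tab-separated with a header row;
#'   missing values are written as empty fields and Unicode minus signs are
#'   normalized to ASCII on read. Writers and readers round-trip: reading a
#'   written file reproduces the object up to canonical ordering.
#' @name poolscreen-io
NULL

norm_minus <- function(x) gsub("−", "-", x)

#' Write / read an intensity matrix TSV
#'
#' Rows are `<strain>|<tag>` measurements, columns chips; the first column
#' holds the row ids. Masked cells are empty.
#'
#' @param m intensity matrix (rownames `<strain>|<tag>`).
#' @param path file path.
#' @return `read_intensity_tsv()` returns the matrix with `strain` and
#'   `tag` attributes restored.
#' @export
write_intensity_tsv <- function(m, path) {
  df <- data.frame(measurement = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_intensity_tsv
#' @export
read_intensity_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          na.strings = "", fileEncoding = "UTF-8",
                          colClasses = "character")
  rn <- df[[1L]]
  parts <- strsplit(rn, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed measurement id(s) at data row(s): ",
         paste(utils::head(which(lengths(parts) != 2L), 5L), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  m <- apply(m, 2L, function(col) as.numeric(norm_minus(col)))
  rownames(m) <- rn
  attr(m, "strain") <- vapply(parts, `[[`, "", 1L)
  attr(m, "tag") <- vapply(parts, `[[`, "", 2L)
  m
}

#' Write / read a chip design table TSV
#'
#' Columns: chip, compound, dose_group, generation, replicate.
#'
#' @param design design data.frame.
#' @param path file path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          na.strings = "", fileEncoding = "UTF-8")
  need <- c("chip", "compound", "dose_group", "generation", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$dose_group <- as.character(df$dose_group)
  df
}

#' Read / write GMT gene-set files
#'
#' Standard GMT dialect: one set per line, `name <tab> description <tab>
#' member1 <tab> member2 ...`; trailing tabs tolerated, members
#' deduplicated.
#'
#' @param path file path.
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `description` attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT at line ", i, ": need name, description, members")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    sets <- structure(list(members), names = f[1L])
    attr(sets[[1L]], "description") <- f[2L]
    out <- c(out, sets)
  }
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors (optionally with
#'   `description` attributes).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read / write pathway edge lists
#'
#' Tab-separated with header `pathway_id <tab> gene_a <tab> gene_b`;
#' isolated pathway nodes may be recorded with an empty `gene_b`.
#'
#' @param path file path.
#' @return list of pathways (id, nodes, edges matrix) as used by
#'   [sepea_test()] and [coverage_filter()].
#' @export
read_pathway_edges <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          na.strings = "", fileEncoding = "UTF-8",
                          colClasses = "character")
  need <- c("pathway_id", "gene_a", "gene_b")
  if (!all(need %in% names(df)))
    stop("pathway edge list needs columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$pathway_id), function(dd) {
    edges <- as.matrix(dd[!is.na(dd$gene_b), c("gene_a", "gene_b")])
    dimnames(edges) <- NULL
    list(id = dd$pathway_id[1L],
         nodes = sort(unique(c(dd$gene_a, dd$gene_b[!is.na(dd$gene_b)]))),
         edges = edges)
  })
}

#' @rdname read_pathway_edges
#' @param pathways list of pathways (id, nodes, edges).
#' @export
write_pathway_edges <- function(pathways, path) {
  rows <- lapply(pathways, function(pw) {
    edges <- pw$edges
    iso <- setdiff(pw$nodes, unique(c(edges)))
    rbind(if (!is.null(edges) && nrow(edges))
      data.frame(pathway_id = pw$id, gene_a = edges[, 1L],
                 gene_b = edges[, 2L], stringsAsFactors = FALSE),
      if (length(iso))
        data.frame(pathway_id = pw$id, gene_a = iso, gene_b = NA_character_,
                   stringsAsFactors = FALSE))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a STRING-style scored edge list
#'
#' Tab- or space-separated columns `node_a node_b combined_score` (header
#' optional, `protein1 protein2 combined_score` also accepted). Malformed
#' rows are reported with their line numbers.
#'
#' @param path file path.
#' @return data.frame node_a, node_b, combined_score.
#' @export
read_string_edges <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("node_a|protein1", first)
  df <- utils::read.table(path, header = has_header, sep = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 3L) stop("need 3 columns: node_a node_b combined_score")
  df <- df[, 1:3]
  names(df) <- c("node_a", "node_b", "combined_score")
  score <- suppressWarnings(as.numeric(norm_minus(as.character(df$combined_score))))
  bad <- which(is.na(score))
  if (length(bad))
    stop("malformed score at line(s): ",
         paste(utils::head(bad + has_header, 5L), collapse = ", "))
  df$combined_score <- score
  df
}

#' Write / read growth-curve CSV
#'
#' Long format with columns well, strain, compound, dose, time_h, od
#' (strain/compound optional on read).
#'
#' @param curves long growth data.frame.
#' @param path file path.
#' @export
write_growth_csv <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_growth_csv
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("well", "dose", "time_h", "od")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("growth CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Export a pathway linkage tree as Newick
#'
#' Serializes the average-linkage tree from [cluster_pathways()] so the
#' clustergram topology can be archived or re-read with any tree reader.
#'
#' @param tree an `hclust` object.
#' @param path file path.
#' @return `read_linkage_newick()` returns an [ape::phylo] tree.
#' @export
write_linkage_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname write_linkage_newick
#' @export
read_linkage_newick <- function(path) {
  ape::read.tree(path)
}
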
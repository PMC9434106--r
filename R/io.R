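#' Read an OTU table from a tab-separated file
#'
#' Expected layout: first row holds taxon ids (optionally preceded by a corner
#' label for the id column), first column holds sample ids, body is numeric.
#' Parse errors name the offending line and cell.
#'
#' @param path path to a TSV file.
#' @param taxa_as_rows set to \code{TRUE} for the transposed dialect in which
#'   rows are taxa and columns are samples; the returned table always has
#'   samples as rows.
#' @return an [otu_table].
#' @seealso [write_otu_table()]
#' @export
read_otu_table <- function(path, taxa_as_rows = FALSE) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) < 2) stop(sprintf("'%s': need a header line and at least one data row", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  width <- length(body[[1]])
  col_ids <- if (length(header) == width) header[-1] else header
  if (length(col_ids) != width - 1)
    stop(sprintf("line 1: header has %d fields but data rows have %d", length(header), width))
  n <- length(body)
  row_ids <- character(n)
  mat <- matrix(NA_real_, n, width - 1L)
  for (i in seq_len(n)) {
    f <- body[[i]]
    if (length(f) != width)
      stop(sprintf("line %d: expected %d fields, found %d", i + 1L, width, length(f)))
    row_ids[i] <- f[1]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      stop(sprintf("line %d, column '%s': non-numeric value '%s'",
                   i + 1L, col_ids[j], f[j + 1L]))
    }
    if (any(vals < 0)) {
      j <- which(vals < 0)[1]
      stop(sprintf("line %d, column '%s': negative value '%s'",
                   i + 1L, col_ids[j], f[j + 1L]))
    }
    mat[i, ] <- vals
  }
  if (taxa_as_rows) {
    otu_table(t(mat), sample_ids = col_ids, taxon_ids = row_ids)
  } else {
    otu_table(mat, sample_ids = row_ids, taxon_ids = col_ids)
  }
}

#' Write an OTU table as TSV
#'
#' Inverse of [read_otu_table()]: round-trips ids exactly and values up to
#' numeric formatting (15 significant digits).
#'
#' @param x an [otu_table].
#' @param path output file path.
#' @export
write_otu_table <- function(x, path) {
  x <- as_otu_table(x)
  header <- paste(c("sample_id", colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a rooted phylogeny from a newick file
#'
#' Wraps \code{ape::read.tree} and enforces the invariants the downstream
#' phylogenetic metrics need: unique tip labels, branch lengths present and
#' non-negative on every edge leading to a tip, rooted topology.  Missing
#' internal branch lengths are set to zero.
#'
#' @param path newick file path.
#' @return an \code{ape::phylo} object.
#' @export
read_tree <- function(path) {
  phy <- tryCatch(suppressWarnings(ape::read.tree(path)), error = function(e)
    stop(sprintf("'%s': unparsable newick (%s)", path, conditionMessage(e)), call. = FALSE))
  if (is.null(phy)) stop(sprintf("'%s': unparsable newick", path))
  validate_tree(phy)
}

#' Validate a phylogeny for use in the pipeline
#' @param phy an \code{ape::phylo}.
#' @return the validated tree (internal NA branch lengths replaced by 0).
#' @export
validate_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(phy$tip.label))
    stop(sprintf("duplicate tip label '%s'", phy$tip.label[duplicated(phy$tip.label)][1]))
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  ntip <- length(phy$tip.label)
  tip_edge <- phy$edge[, 2] <= ntip
  if (anyNA(phy$edge.length[tip_edge]))
    stop("missing branch length on an edge leading to a tip")
  phy$edge.length[is.na(phy$edge.length)] <- 0
  if (any(phy$edge.length < 0)) stop("negative branch length in tree")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  phy
}

#' Write a phylogeny as newick
#' @param phy an \code{ape::phylo}.
#' @param path output file path.
#' @export
write_tree <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with a header; must contain columns \code{sample_id}, \code{reservoir}
#' and \code{event}.  The season is derived from the event code (\code{D*} is
#' dry, \code{R*} is rainy); an explicit \code{season} column, if present,
#' must agree.  The string \code{"NA"} is a reservoir name (Nova Avanhandava),
#' never a missing value.
#'
#' @param path TSV file path.
#' @return a data.frame of character columns with a derived \code{season}.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, colClasses = "character", na.strings = NULL,
                   check.names = FALSE)
  required <- c("sample_id", "reservoir", "event")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop(sprintf("metadata is missing column(s): %s", paste(missing, collapse = ", ")))
  if (anyDuplicated(md$sample_id))
    stop(sprintf("duplicate sample id '%s' in metadata",
                 md$sample_id[duplicated(md$sample_id)][1]))
  season <- season_of_event(md$event)
  if ("season" %in% names(md)) {
    bad <- md$season != season
    if (any(bad))
      stop(sprintf("sample '%s': season '%s' inconsistent with event '%s'",
                   md$sample_id[bad][1], md$season[bad][1], md$event[bad][1]))
  }
  md$season <- season
  md
}

#' Season implied by a sampling-event code
#' @param event character vector of event codes (\code{D1..D3}, \code{R1..R3}).
#' @return \code{"dry"} or \code{"rainy"} per element.
#' @export
season_of_event <- function(event) {
  pre <- substr(event, 1, 1)
  if (any(!pre %in% c("D", "R")))
    stop(sprintf("unrecognized event code '%s' (must start with D or R)",
                 event[!pre %in% c("D", "R")][1]))
  ifelse(pre == "D", "dry", "rainy")
}

#' Check that every sample in an OTU table has metadata
#' @param metadata metadata data.frame (see [read_metadata()]).
#' @param table an [otu_table].
#' @return the metadata rows aligned to the table's sample order.
#' @export
align_metadata <- function(metadata, table) {
  table <- as_otu_table(table)
  idx <- match(rownames(table), metadata$sample_id)
  if (anyNA(idx))
    stop(sprintf("no metadata row for sample(s): %s",
                 paste(rownames(table)[is.na(idx)], collapse = ", ")))
  metadata[idx, , drop = FALSE]
}

#' Read a taxonomy table
#'
#' TSV with a header; first column \code{taxon_id}, remaining columns ranked
#' lineage fields (e.g. domain, phylum, ..., genus).
#'
#' @param path TSV file path.
#' @return a character data.frame.
#' @export
read_taxonomy <- function(path) {
  tx <- read.delim(path, colClasses = "character", na.strings = NULL,
                   check.names = FALSE)
  if (names(tx)[1] != "taxon_id") names(tx)[1] <- "taxon_id"
  if (anyDuplicated(tx$taxon_id))
    stop(sprintf("duplicate taxon id '%s' in taxonomy",
                 tx$taxon_id[duplicated(tx$taxon_id)][1]))
  tx
}

#' Read an environmental-variable table
#'
#' TSV with a header; first column \code{sample_id}, remaining columns
#' numeric environmental variables.
#'
#' @param path TSV file path.
#' @return numeric matrix with sample ids as rownames.
#' @export
read_env_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = NULL,
                   colClasses = "character")
  ids <- df[[1]]
  m <- vapply(df[-1], function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) stop("non-numeric cell in environmental table")
    v
  }, numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df), dimnames = list(ids, names(df)[-1]))
  m
}

#' Restrict an OTU table to the tips of a tree
#'
#' By default a table containing taxa absent from the tree is an error, since
#' silent pruning hides upstream mistakes.  With \code{prune = TRUE} such taxa
#' are dropped and their number reported in a warning.
#'
#' @param table an [otu_table].
#' @param tree an \code{ape::phylo}.
#' @param prune drop taxa not found among the tree tips instead of erroring.
#' @return the (possibly pruned) [otu_table].
#' @export
prune_to_tree <- function(table, tree, prune = FALSE) {
  table <- as_otu_table(table)
  missing <- setdiff(colnames(table), tree$tip.label)
  if (!length(missing)) return(table)
  if (!prune)
    stop(sprintf("%d taxa absent from the tree (e.g. '%s'); use prune = TRUE to drop them",
                 length(missing), missing[1]))
  warning(sprintf("pruned %d taxa absent from the tree", length(missing)))
  otu_table(.otu_counts(table)[, setdiff(colnames(table), missing), drop = FALSE])
}
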
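#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement down to \code{depth}.
#' Samples whose total is below the depth are dropped with a warning.  Each
#' sample draws from its own random stream derived from the master seed and
#' the sample id, so removing one sample never changes the subsample obtained
#' for another.  Taxa left with an all-zero column are removed.
#'
#' @param table an [otu_table] of integer counts.
#' @param depth target depth (reads per sample); defaults to the minimum
#'   sample total in the table.
#' @param seed master seed for the subsampling streams.
#' @return a rarefied [otu_table]; every row sums exactly to \code{depth}.
#' @examples
#' x <- otu_table(matrix(c(5, 5, 10, 0), 2, 2))
#' rarefy(x, depth = 5, seed = 1)
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  table <- as_otu_table(table)
  counts <- .otu_counts(table)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("rarefaction requires integer counts")
  counts <- round(counts)
  totals <- rowSums(counts)
  if (is.null(depth)) depth <- min(totals)
  if (length(depth) != 1 || is.na(depth) || depth <= 0)
    stop("rarefaction depth must be a single positive integer")
  depth <- as.integer(round(depth))
  drop <- totals < depth
  if (any(drop))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth, paste(rownames(counts)[drop], collapse = ", ")))
  keep <- which(!drop)
  if (!length(keep)) stop("no sample reaches the rarefaction depth")
  out <- matrix(0, length(keep), ncol(counts),
                dimnames = list(rownames(counts)[keep], colnames(counts)))
  for (r in seq_along(keep)) {
    i <- keep[r]
    x <- counts[i, ]
    if (totals[i] == depth) {            # exhaustive draw: unchanged
      out[r, ] <- x
      next
    }
    set.seed(derive_seed(seed, "rarefy", rownames(counts)[i]))
    reads <- rep.int(seq_along(x), x)
    picked <- sample(reads, depth)
    out[r, ] <- tabulate(picked, nbins = length(x))
  }
  out <- out[, colSums(out) > 0, drop = FALSE]
  otu_table(out)
}

#' Extract a taxonomically defined subcommunity
#'
#' Restricts an OTU table to the taxa whose lineage matches
#' \code{rank == value} in the taxonomy table (e.g. \code{phylum ==
#' "Cyanobacteria"}).  Samples left with zero total are dropped with a
#' warning; output cells are copied verbatim from the input.
#'
#' @param table an [otu_table].
#' @param taxonomy data.frame from [read_taxonomy()].
#' @param rank name of the taxonomy column to match on.
#' @param value lineage value selecting the subcommunity.
#' @return the restricted [otu_table].
#' @export
extract_subcommunity <- function(table, taxonomy, rank, value) {
  table <- as_otu_table(table)
  if (!rank %in% names(taxonomy))
    stop(sprintf("rank '%s' not present in taxonomy (have: %s)",
                 rank, paste(setdiff(names(taxonomy), "taxon_id"), collapse = ", ")))
  known <- setdiff(colnames(table), taxonomy$taxon_id)
  if (length(known))
    stop(sprintf("%d table taxa missing from taxonomy (e.g. '%s')",
                 length(known), known[1]))
  hit <- taxonomy$taxon_id[taxonomy[[rank]] == value]
  sel <- intersect(colnames(table), hit)
  if (!length(sel))
    stop(sprintf("rule %s == '%s' matches no taxon in the table", rank, value))
  out <- .otu_counts(table)[, sel, drop = FALSE]
  empty <- rowSums(out) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d sample(s) with zero total after extraction: %s",
                    sum(empty), paste(rownames(out)[empty], collapse = ", ")))
    out <- out[!empty, , drop = FALSE]
  }
  if (!nrow(out)) stop("no sample retains any reads after extraction")
  otu_table(out)
}
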
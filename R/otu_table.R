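#' OTU abundance tables
#'
#' An \code{otu_table} is a numeric matrix of non-negative abundances with
#' samples as rows and taxa as columns; row and column names are the sample
#' and taxon identifiers.  The constructor enforces the container invariants
#' (no negative or missing entries, unique non-empty identifiers).
#'
#' @param counts numeric matrix (or object coercible to one), samples x taxa.
#' @param sample_ids,taxon_ids identifier character vectors; default to the
#'   dimnames of \code{counts}.
#' @return an object of class \code{otu_table} (a named numeric matrix).
#' @examples
#' otu_table(matrix(1:4, 2, 2), c("s1", "s2"), c("OTU1", "OTU2"))
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      taxon_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("OTU counts must be numeric")
  storage.mode(counts) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("OTU", seq_len(ncol(counts)))
  dimnames(counts) <- list(as.character(sample_ids), as.character(taxon_ids))
  class(counts) <- c("otu_table", class(counts))
  validate_otu_table(counts)
}

#' Validate an OTU table against its invariants
#'
#' @param x an \code{otu_table} (or named numeric matrix).
#' @return \code{x}, invisibly compatible (returned for chaining); errors on
#'   any violated invariant.
#' @export
validate_otu_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("OTU table must be a numeric matrix")
  if (anyNA(x)) stop("OTU table contains missing values")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  sid <- rownames(x); tid <- colnames(x)
  if (is.null(sid) || is.null(tid)) stop("OTU table must carry sample and taxon ids")
  if (anyDuplicated(sid)) stop(sprintf("duplicate sample id '%s'", sid[duplicated(sid)][1]))
  if (anyDuplicated(tid)) stop(sprintf("duplicate taxon id '%s'", tid[duplicated(tid)][1]))
  if (any(!nzchar(sid)) || any(!nzchar(tid))) stop("empty identifier in OTU table")
  x
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d taxa (total count %.6g)\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Test/coerce OTU tables
#' @param x object to test or coerce.
#' @rdname otu_table_coerce
#' @export
is_otu_table <- function(x) inherits(x, "otu_table")

#' @rdname otu_table_coerce
#' @export
as_otu_table <- function(x) {
  if (is_otu_table(x)) return(validate_otu_table(x))
  otu_table(x)
}

# plain matrix view (drops class, keeps dimnames)
.otu_counts <- function(x) {
  m <- unclass(x)
  attr(m, "class") <- NULL
  m
}
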
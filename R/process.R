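#' Classify sample pairs into assembly processes
#'
#' Applies the two-stage null-model rule: \code{|betaNTI| > 2} assigns
#' selection (S); otherwise \code{RC < -0.95} assigns homogenizing dispersal
#' (HD), \code{RC > 0.95} dispersal limitation (DL) and \code{|RC| < 0.95}
#' drift (D).  Inequalities are strict, so boundary values fall through to
#' the less specific process.  A pair with \code{|betaNTI| <= 2} (or an
#' undefined betaNTI) must supply an RC value.  The betaNTI sign (variable
#' vs. homogeneous selection) is not used for labeling but remains available
#' in the inputs.
#'
#' @param bnti numeric vector of betaNTI values (\code{NA} allowed: a
#'   degenerate null forwards the pair to the RC stage).
#' @param rc_bray numeric vector of RC-bray values; may be \code{NA} for
#'   pairs already classified by selection.
#' @param bnti_cut,rc_cut thresholds (defaults 2 and 0.95).
#' @return factor with levels \code{S}, \code{HD}, \code{DL}, \code{D}.
#' @examples
#' classify_pair(c(3.1, -1.0, 0.5, 1.2), c(NA, -0.97, 0.2, 0.96))
#' @export
classify_pair <- function(bnti, rc_bray = NA_real_, bnti_cut = 2, rc_cut = 0.95) {
  n <- max(length(bnti), length(rc_bray))
  bnti <- rep_len(bnti, n)
  rc_bray <- rep_len(rc_bray, n)
  selected <- !is.na(bnti) & abs(bnti) > bnti_cut
  need_rc <- !selected
  if (any(need_rc & is.na(rc_bray)))
    stop("RC-bray value required for every pair with |betaNTI| <= threshold")
  label <- character(n)
  label[selected] <- "S"
  label[need_rc & rc_bray < -rc_cut] <- "HD"
  label[need_rc & rc_bray > rc_cut] <- "DL"
  label[need_rc & abs(rc_bray) <= rc_cut] <- "D"
  factor(label, levels = c("S", "HD", "DL", "D"))
}

#' Cascade sampling design
#'
#' An ordered chain of reservoirs with the sampling events of each season.
#' Adjacent pairs are consecutive reservoirs; with the default four-reservoir
#' cascade and three events per season this yields 3 x 3 = 9 comparisons per
#' season.
#'
#' @param reservoirs ordered reservoir codes, upstream first.
#' @param events event codes; season is implied by the code prefix
#'   ([season_of_event()]).
#' @return an object of class \code{cascade_design}.
#' @export
cascade_design <- function(reservoirs = c("BB", "Pr", "NA", "TI"),
                           events = c("D1", "D2", "D3", "R1", "R2", "R3")) {
  if (length(reservoirs) < 2) stop("a cascade needs at least 2 reservoirs")
  if (anyDuplicated(reservoirs)) stop("duplicate reservoir in cascade")
  season_of_event(events)  # validates codes
  structure(list(reservoirs = reservoirs, events = events),
            class = "cascade_design")
}

#' Adjacent reservoir pairs of a cascade design
#' @param design a [cascade_design()].
#' @return two-column character matrix (upstream, downstream).
#' @export
adjacent_reservoirs <- function(design) {
  r <- design$reservoirs
  cbind(upstream = r[-length(r)], downstream = r[-1])
}

#' Sample pairs between directly connected reservoirs
#'
#' For every sampling event of the design, pairs the sample of each reservoir
#' with the sample of the next reservoir downstream.  Each (reservoir, event)
#' cell must hold exactly one sample.
#'
#' @param metadata sample metadata (see [read_metadata()]); only its
#'   \code{sample_id}, \code{reservoir} and \code{event} columns are used.
#' @param design a [cascade_design()].
#' @return data.frame with columns \code{event}, \code{season},
#'   \code{reservoir_a}, \code{reservoir_b}, \code{sample_a},
#'   \code{sample_b}.
#' @export
connected_pairs <- function(metadata, design = cascade_design()) {
  adj <- adjacent_reservoirs(design)
  cells <- expand.grid(reservoir = design$reservoirs, event = design$events,
                       stringsAsFactors = FALSE)
  lookup <- function(res, ev) {
    hit <- metadata$sample_id[metadata$reservoir == res & metadata$event == ev]
    if (length(hit) == 0)
      stop(sprintf("missing sample for reservoir=%s, event=%s", res, ev))
    if (length(hit) > 1)
      stop(sprintf("multiple samples for reservoir=%s, event=%s", res, ev))
    hit
  }
  for (i in seq_len(nrow(cells))) lookup(cells$reservoir[i], cells$event[i])
  out <- do.call(rbind, lapply(design$events, function(ev) {
    data.frame(event = ev, season = season_of_event(ev),
               reservoir_a = adj[, 1], reservoir_b = adj[, 2],
               sample_a = vapply(adj[, 1], lookup, character(1), ev = ev),
               sample_b = vapply(adj[, 2], lookup, character(1), ev = ev),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Summarize process labels into Local / Regional / Stochastic percentages
#'
#' Local = selection (S); Regional = homogenizing dispersal + dispersal
#' limitation (HD + DL); Stochastic = drift (D).  Display percentages are
#' rounded half away from zero; the raw fractions are retained and always
#' sum to 1.
#'
#' @param labels vector (or factor) of labels in \code{S}, \code{HD},
#'   \code{DL}, \code{D}.
#' @return object of class \code{process_summary}: list with \code{counts},
#'   \code{n_pairs}, \code{fractions} (local/regional/stochastic) and
#'   \code{percents} (rounded integers).
#' @examples
#' summarize_processes(c("DL", "HD", "HD", "S", "S", "S", "DL", "HD", "S"))
#' @export
summarize_processes <- function(labels) {
  labels <- as.character(labels)
  if (!length(labels)) stop("empty label list")
  bad <- setdiff(unique(labels), c("S", "HD", "DL", "D"))
  if (length(bad)) stop(sprintf("unknown process label '%s'", bad[1]))
  counts <- table(factor(labels, levels = c("S", "HD", "DL", "D")))
  n <- length(labels)
  fractions <- c(local = unname(counts["S"]) / n,
                 regional = unname(counts["HD"] + counts["DL"]) / n,
                 stochastic = unname(counts["D"]) / n)
  percents <- .round_half_away(100 * fractions)
  structure(list(counts = counts, n_pairs = n, fractions = fractions,
                 percents = percents),
            class = "process_summary")
}

#' @export
print.process_summary <- function(x, ...) {
  cat(sprintf("%d pairs: S=%d HD=%d DL=%d D=%d\n", x$n_pairs,
              x$counts["S"], x$counts["HD"], x$counts["DL"], x$counts["D"]))
  cat(sprintf("Local: %d%%  Regional: %d%%  Stochastic: %d%%\n",
              x$percents["local"], x$percents["regional"], x$percents["stochastic"]))
  invisible(x)
}
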
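# Haplotype-sharing ancestry: each marker of each line is attributed to
# the ancestor with the longest run of agreeing flanking markers, subject
# to a margin over the runner-up; attributions aggregate to fractional
# genome contributions per ancestor.

AMBIGUOUS <- "AMBIGUOUS"

# Per-marker match extent of a line against one ancestor: the length of
# the maximal run of agreeing markers containing each marker (runs break
# at chromosome boundaries), 0 where the focal marker itself disagrees.
# Line HET calls agree with either ancestor allele; missing calls on
# either side break the run.
.match_extents <- function(line_calls, anc_calls, new_chrom) {
  agree <- (line_calls == anc_calls | line_calls == CALL_HET |
              anc_calls == CALL_HET) &
    !is.na(line_calls) & !is.na(anc_calls)
  agree[is.na(agree)] <- FALSE
  M <- length(agree)
  brk <- c(TRUE, agree[-1] != agree[-M] | new_chrom[-1])
  runid <- cumsum(brk)
  runlen <- tabulate(runid)
  runlen[runid] * agree
}

#' Assign per-marker ancestry for one line by the margin rule
#'
#' For every marker the match extent to each ancestor is the number of
#' consecutive agreeing markers in the maximal run containing that marker
#' (flanks truncate at chromosome ends). The marker is attributed to the
#' ancestor with the longest extent if that extent exceeds the second
#' longest by strictly more than `margin_threshold` markers; otherwise it
#' is `AMBIGUOUS`.
#'
#' @param line Integer call vector for one line (coded 0/1/2/NA), e.g. a
#'   row of `g$calls`, on the ancestors' marker map.
#' @param ancestors Ancestor `genotype_matrix`.
#' @param margin_threshold Required winning margin in markers (default 5).
#' @return `data.frame` with `donor`, `match_length` (best extent) and
#'   `margin` (best minus second best) per marker.
#' @export
assign_marker_ancestry <- function(line, ancestors, margin_threshold = 5) {
  if (nrow(ancestors$calls) == 0) stop("assign_marker_ancestry: no ancestors")
  stopifnot(margin_threshold >= 0, length(line) == ncol(ancestors$calls))
  chrom <- ancestors$map$chrom
  M <- length(chrom)
  new_chrom <- c(TRUE, chrom[-1] != chrom[-M])
  E <- vapply(seq_len(nrow(ancestors$calls)), function(a)
    .match_extents(line, ancestors$calls[a, ], new_chrom), numeric(M))
  # E: markers x ancestors
  best_a <- max.col(E, ties.method = "first")
  best <- E[cbind(seq_len(M), best_a)]
  E2 <- E
  E2[cbind(seq_len(M), best_a)] <- -Inf
  second <- do.call(pmax, as.data.frame(E2))
  margin <- best - second
  donor <- rownames(ancestors$calls)[best_a]
  donor[!(margin > margin_threshold)] <- AMBIGUOUS
  data.frame(marker = ancestors$map$marker, donor = donor,
             match_length = best, margin = margin, stringsAsFactors = FALSE)
}

#' Assign per-marker ancestry for every line of a panel
#'
#' Applies [assign_marker_ancestry()] to each line.
#'
#' @param g `genotype_matrix` of descendant lines sharing the ancestors'
#'   marker map.
#' @param ancestors Ancestor `genotype_matrix`.
#' @param margin_threshold Required winning margin in markers (default 5).
#' @return An `ancestry_assignment`: list with `donor` (character matrix
#'   lines x markers, values ancestor ids or `"AMBIGUOUS"`),
#'   `match_length`, `margin`, `margin_threshold`, `ancestors`.
#' @export
assign_ancestry <- function(g, ancestors, margin_threshold = 5) {
  if (!identical(g$map$marker, ancestors$map$marker))
    stop("assign_ancestry: marker maps differ")
  n <- nrow(g$calls)
  donor <- matrix(NA_character_, n, ncol(g$calls),
                  dimnames = dimnames(g$calls))
  mlen <- margin <- matrix(NA_real_, n, ncol(g$calls),
                           dimnames = dimnames(g$calls))
  for (i in seq_len(n)) {
    row <- assign_marker_ancestry(g$calls[i, ], ancestors, margin_threshold)
    donor[i, ] <- row$donor
    mlen[i, ] <- row$match_length
    margin[i, ] <- row$margin
  }
  structure(list(donor = donor, match_length = mlen, margin = margin,
                 margin_threshold = margin_threshold,
                 ancestors = rownames(ancestors$calls)),
            class = "ancestry_assignment")
}

#' Fractional ancestral contributions
#'
#' Pools per-marker attributions over lines: the fraction attributed to an
#' ancestor is its attributed-marker count divided by all unambiguous
#' attributions; the ambiguous fraction is reported separately (it is not
#' part of the denominator).
#'
#' @param assignment An `ancestry_assignment` (optionally subset to one
#'   population's lines first).
#' @param founding_threshold Fraction above which an ancestor is flagged
#'   as founding (default 0.03).
#' @return A `contribution_table`: `data.frame(ancestor, fraction,
#'   founding)` sorted by descending fraction, with attributes
#'   `ambiguous_fraction` and `all_ambiguous`.
#' @export
fractional_contribution <- function(assignment, founding_threshold = 0.03) {
  stopifnot(inherits(assignment, "ancestry_assignment"))
  d <- as.vector(assignment$donor)
  n_amb <- sum(d == AMBIGUOUS)
  n_tot <- length(d)
  tallies <- table(factor(d[d != AMBIGUOUS], levels = assignment$ancestors))
  all_amb <- sum(tallies) == 0
  frac <- if (all_amb) rep(NA_real_, length(tallies))
          else as.numeric(tallies) / sum(tallies)
  out <- data.frame(ancestor = names(tallies), fraction = frac,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$ancestor), , drop = FALSE]
  out$founding <- !is.na(out$fraction) & out$fraction > founding_threshold
  rownames(out) <- NULL
  if (all_amb) warning("fractional_contribution: all markers ambiguous")
  structure(out, ambiguous_fraction = n_amb / n_tot, all_ambiguous = all_amb,
            class = c("contribution_table", "data.frame"))
}

#' Founding ancestors of a population
#'
#' Ancestors whose fractional contribution strictly exceeds the threshold.
#'
#' @param table A `contribution_table` from [fractional_contribution()].
#' @param threshold Contribution threshold (default 0.03).
#' @return Character vector of ancestor ids.
#' @export
founding_ancestors <- function(table, threshold = 0.03) {
  stopifnot(is.data.frame(table))
  table$ancestor[!is.na(table$fraction) & table$fraction > threshold]
}
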
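#' Label windows from an annotation track
#'
#' A window receives the class of the annotated interval with the largest
#' temporal intersection, provided that intersection covers at least
#' `min_cover` of the window length; otherwise it is labeled `"none"`
#' (background). Ties go to the earlier-starting interval.
#'
#' @param grid Window grid (data frame with `start_ms`, `end_ms`).
#' @param track An [annotation_track()] on the same timeline.
#' @param min_cover Minimum covered fraction of the window (default 0.5).
#' @param none_class Background label (default `"none"`).
#' @return Character vector of labels, one per window.
#' @export
label_windows <- function(grid, track, min_cover = 0.5,
                          none_class = "none") {
  n <- nrow(grid)
  out <- rep(none_class, n)
  if (nrow(track) == 0L || n == 0L) return(out)
  for (i in seq_len(n)) {
    inter <- pmin(grid$end_ms[i], track$end_ms) -
      pmax(grid$start_ms[i], track$start_ms)
    inter[inter < 0] <- 0
    best <- which.max(inter)  # ties: intervals sorted by start, first wins
    if (inter[best] >= min_cover * (grid$end_ms[i] - grid$start_ms[i])) {
      out[i] <- track$class[best]
    }
  }
  out
}

#' Reduce a compound activity label to its verb
#'
#' Annotation dialects of kitchen-activity corpora write labels as
#' `verb-object1-preposition-object2` (e.g. `open-brownie_box`,
#' `fill-oil-oil_bottle-pan`). Learning every compound is infeasible, so the
#' first token — the verb — becomes the target class. A label without a
#' delimiter is returned unchanged.
#'
#' @param label Character vector of non-empty labels.
#' @return Character vector of verbs.
#' @examples
#' reduce_label_to_verb(c("open-brownie_box", "fill-oil-oil_bottle-pan", "stir"))
#' @export
reduce_label_to_verb <- function(label) {
  if (length(label) == 0L) return(character(0))
  if (any(is.na(label) | !nzchar(label))) stop("labels must be non-empty")
  vapply(strsplit(label, "-", fixed = TRUE), `[[`, character(1), 1L)
}
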
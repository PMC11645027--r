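#' Assign a locomotive-syndrome stage from a GLFS-25 score
#'
#' Maps a GLFS-25 total score (25 items scored 0-4, so 0-100) to the
#' clinical staging used for older adults: scores below 7 are non-LS
#' ("NonLS"), scores from 7 to 15 are LS stage 1 ("Stage1"), and scores of
#' 16 or higher are LS stage 2 ("Stage2").
#'
#' @param glfs_score Integer vector of GLFS-25 total scores in `[0, 100]`.
#'
#' @return A factor with levels `NonLS`, `Stage1`, `Stage2`, same length as
#'   the input.
#'
#' @examples
#' assign_stage(c(0, 6, 7, 15, 16, 40))
#' @export
assign_stage <- function(glfs_score) {
  if (!is.numeric(glfs_score) || any(!is.finite(glfs_score))) {
    abort("`glfs_score` must be numeric and finite.")
  }
  if (any(glfs_score != round(glfs_score))) {
    abort("`glfs_score` must be whole numbers (GLFS-25 items are integers).")
  }
  if (any(glfs_score < 0 | glfs_score > 100)) {
    abort("`glfs_score` must lie in [0, 100] (25 items x max grade 4).")
  }
  cut(glfs_score,
    breaks = c(-Inf, 6.5, 15.5, Inf),
    labels = c("NonLS", "Stage1", "Stage2")
  )
}

# Canonical group levels, youngest to most affected.
ls_group_levels <- function() c("Young", "NonLS", "Stage1", "Stage2")
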
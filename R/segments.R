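# Single source of truth for trajectory segmentation, shared by the
# exposure and contact analyses so their halves always agree.

#' Split frames into segments
#'
#' `"halves"` splits an n-frame trajectory into first / second half; when
#' n is odd the extra frame goes to the first half.  Custom segmentation
#' is a list of integer frame vectors (1-based) that must partition
#' `1:n_frames` without overlap.
#'
#' @param n_frames total frame count.
#' @param segmentation `"halves"` or a named list of frame-index vectors.
#' @return named list of integer frame vectors covering all frames.
#' @export
segment_frames <- function(n_frames, segmentation = "halves") {
  stopifnot(n_frames >= 1)
  if (identical(segmentation, "halves")) {
    split_at <- ceiling(n_frames / 2)
    if (split_at == n_frames && n_frames > 1) split_at <- n_frames - 1
    segs <- list(first_half = seq_len(split_at),
                 second_half = seq.int(split_at + 1, n_frames))
    if (n_frames == 1) segs <- list(first_half = 1L)
    return(segs)
  }
  if (!is.list(segmentation) || !length(segmentation)) {
    stop("segmentation must be \"halves\" or a non-empty list of frame vectors")
  }
  if (is.null(names(segmentation)) || any(!nzchar(names(segmentation)))) {
    names(segmentation) <- paste0("segment_", seq_along(segmentation))
  }
  segs <- lapply(segmentation, function(s) sort(as.integer(s)))
  if (any(vapply(segs, length, 1L) == 0)) stop("empty segment")
  all_frames <- sort(unlist(segs, use.names = FALSE))
  if (anyDuplicated(all_frames)) stop("segments overlap")
  if (!identical(all_frames, seq_len(n_frames))) {
    stop("segments must cover frames 1..", n_frames, " exactly")
  }
  segs
}
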
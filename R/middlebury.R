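## Reproduction of the 2D interpolation-error benchmark on the public
## optical-flow training pairs with ground-truth .flo fields. The data are
## not shipped with the package: point `data_dir` at a local copy laid out
## as <data_dir>/other-data/<name>/frame10.png, frame11.png and
## <data_dir>/other-gt-flow/<name>/flow10.flo.

MIDDLEBURY_PAIRS <- c("Dimetrodon", "Grove2", "Grove3", "Urban3", "Venus")

#' 2D interpolation-error benchmark
#'
#' For each image pair, measures the interpolation error (IE) and normalized
#' interpolation error (NE) of (a) the published ground-truth flow and (b)
#' the package's 2D Hermite optical-flow estimate, on the 0-255 intensity
#' scale: the second frame is reconstructed from the first through the flow
#' and compared with the true second frame.
#'
#' @param data_dir Directory containing `other-data/` and `other-gt-flow/`
#'   subdirectories of the benchmark training set.
#' @param pairs Character vector of sequence names (default the five
#'   standard pairs).
#' @param params A [flow_params()] object for the HOF2D runs.
#' @param run_hof If `FALSE`, only the ground-truth-flow errors (a pure
#'   warp + metric check) are computed.
#' @return A data.frame with one row per pair: `ie_gt`, `ne_gt` and (if
#'   requested) `ie_hof2d`, `ne_hof2d`.
#' @export
middlebury_benchmark <- function(data_dir, pairs = MIDDLEBURY_PAIRS,
                                 params = flow_params(iterations = 50),
                                 run_hof = TRUE) {
  if (!dir.exists(data_dir)) {
    stop("benchmark data directory not found: ", data_dir, call. = FALSE)
  }
  rows <- lapply(pairs, function(name) {
    f10 <- file.path(data_dir, "other-data", name, "frame10.png")
    f11 <- file.path(data_dir, "other-data", name, "frame11.png")
    fgt <- file.path(data_dir, "other-gt-flow", name, "flow10.flo")
    if (!file.exists(f10) || !file.exists(f11) || !file.exists(fgt)) {
      stop("missing files for pair '", name, "' under ", data_dir,
           call. = FALSE)
    }
    i10 <- read_volume(f10)
    i11 <- read_volume(f11)
    gt <- read_flo(fgt)
    valid <- attr(gt, "valid")
    rep_gt <- evaluate_pair(i10, i11, gt, mask = valid)
    out <- data.frame(pair = name, ie_gt = rep_gt$ie, ne_gt = rep_gt$ne,
                      stringsAsFactors = FALSE)
    if (run_hof) {
      fl <- estimate_flow(i10, i11, params)
      rep_h <- evaluate_pair(i10, i11, fl, mask = valid)
      out$ie_hof2d <- rep_h$ie
      out$ne_hof2d <- rep_h$ne
    }
    out
  })
  do.call(rbind, rows)
}
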
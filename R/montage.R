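#' Load an electrode montage
#'
#' Reads a tab-separated montage file with columns `channel`, `x`, `y`
#' and `scalp` (1 for scalp channels entering the common-average
#' reference). Positions are approximate top-view head coordinates on a
#' unit circle and are used only for synthetic topographies and
#' quick-look plots, never for inference.
#'
#' @param path path to a montage TSV. Default: the 64-channel 10-10
#'   montage shipped with the package.
#' @return a data.frame with class `montage`.
#' @export
load_montage <- function(path = system.file("extdata", "montage_1010_64.tsv",
                                            package = "confclust")) {
  m <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "x", "y", "scalp") %in% names(m)))
  if (anyDuplicated(m$channel)) stop("duplicate channel names in montage")
  class(m) <- c("montage", "data.frame")
  m
}

#' Default montages
#'
#' `default_montage(64)` returns the full 64-channel 10-10 montage.
#' `n = 8` and `n = 16` return whole-head low-density subsets (in the
#' spirit of a 10-20 cap) containing both region-of-interest channels
#' (Fz/FCz/Cz and neighbours) and distant sites, so the common-average
#' reference behaves as on a full cap. Simulations at 64-channel density
#' are supported but memory-hungry; the subsets keep the statistical
#' structure intact.
#'
#' @param n number of channels: 8, 16 or 64.
#' @return a `montage` data.frame.
#' @export
default_montage <- function(n = 8) {
  m <- load_montage()
  keep <- switch(as.character(n),
    "8"  = c("Fz", "FCz", "Cz", "T7", "T8", "P7", "Pz", "Oz"),
    "16" = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7",
             "C1", "Cz", "C2", "T8", "P7", "Pz", "P8", "Oz"),
    "64" = m$channel,
    stop("n must be 8, 16 or 64"))
  out <- m[match(keep, m$channel), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("montage", "data.frame")
  out
}

#' Fronto-central region of interest
#'
#' The a-priori scalp region of interest for performance-monitoring
#' potentials: central and fronto-central electrodes. Used to restrict
#' step-1 electrode selection before cluster analyses.
#'
#' @return character vector of channel names.
#' @export
roi_frontocentral <- function() {
  c("F3", "F1", "Fz", "F2", "F4",
    "FC3", "FC1", "FCz", "FC2", "FC4",
    "C3", "C1", "Cz", "C2", "C4")
}
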
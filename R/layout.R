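#' Standard 19-channel 10-20 electrode layout
#'
#' Returns the montage used throughout the package: 19 electrodes of the
#' international 10-20 system grouped into three scalp regions implicated in
#' standing-balance control -- the frontal area (information integration),
#' the central area (proprioception) and the occipital area (vision).
#'
#' @param labels Character vector of channel labels. Defaults to the full
#'   19-channel montage.
#' @param regions Named character vector mapping each label to a region in
#'   `c("frontal", "central", "occipital")`. Defaults to the standard
#'   assignment for the 19-channel montage.
#' @return An object of class `eeg_layout`: a list with `labels` (ordered
#'   character vector) and `region_of` (named character vector).
#' @examples
#' lay <- channel_layout()
#' lay$region_of[["Fz"]]
#' @export
channel_layout <- function(labels = NULL, regions = NULL) {
  if (is.null(labels)) {
    frontal   <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")
    central   <- c("T7", "C3", "Cz", "C4", "T8")
    occipital <- c("P7", "P3", "Pz", "P4", "P8", "O1", "O2")
    labels <- c(frontal, central, occipital)
    regions <- stats::setNames(
      rep(c("frontal", "central", "occipital"),
          c(length(frontal), length(central), length(occipital))),
      labels)
  }
  if (is.null(regions)) {
    stop("`regions` must be supplied when `labels` is not the default montage")
  }
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!all(labels %in% names(regions))) {
    stop("every label needs a region assignment")
  }
  regions <- regions[labels]
  bad <- setdiff(unique(regions), c("frontal", "central", "occipital"))
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  structure(list(labels = labels, region_of = regions), class = "eeg_layout")
}

#' Channels belonging to one region of a layout
#'
#' @param layout An `eeg_layout`.
#' @param region One of `"frontal"`, `"central"`, `"occipital"`.
#' @return Character vector of channel labels.
#' @export
region_channels <- function(layout, region) {
  stopifnot(inherits(layout, "eeg_layout"))
  region <- match.arg(region, c("frontal", "central", "occipital"))
  layout$labels[layout$region_of == region]
}

#' Core node of a region
#'
#' The core electrodes of the frontal, central and occipital areas are Fz,
#' Cz and Pz; their pairings Fz-Cz and Fz-Pz drive window screening.
#'
#' @param region One of `"frontal"`, `"central"`, `"occipital"`.
#' @return A channel label.
#' @export
core_node <- function(region) {
  switch(match.arg(region, c("frontal", "central", "occipital")),
         frontal = "Fz", central = "Cz", occipital = "Pz")
}

#' Default core screening pairs (Fz-Cz and Fz-Pz)
#' @return List of length-2 character vectors.
#' @export
core_pairs <- function() {
  list(c("Fz", "Cz"), c("Fz", "Pz"))
}

#' @export
print.eeg_layout <- function(x, ...) {
  cat("<eeg_layout> ", length(x$labels), " channels\n", sep = "")
  for (r in c("frontal", "central", "occipital")) {
    ch <- x$labels[x$region_of == r]
    if (length(ch)) cat(sprintf("  %-9s %s\n", r, paste(ch, collapse = " ")))
  }
  invisible(x)
}
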
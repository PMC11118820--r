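#' Write a recording as delimited text
#'
#' Tab-separated text: a comment line `# fs=<rate>`, a header row of channel
#' labels, then one column per channel.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_text <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fs=", rec$fs), con)
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$layout$labels
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multichannel recording
#'
#' Reads a delimited-text recording (header row of channel labels, one
#' column per channel, optional `# fs=` comment line). Labels are matched
#' case-insensitively against the target layout; extra channels are dropped
#' with a warning and missing required channels raise an error naming them.
#'
#' @param path Input file.
#' @param format Currently `"text"` (tab- or comma-delimited).
#' @param fs Sampling rate in Hz; overrides any rate stored in the file.
#' @param layout Target `eeg_layout` (default the 19-channel montage).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("text"), fs = NULL,
                           layout = channel_layout()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("fs\\s*=\\s*([0-9.]+)", first))[[1]]
    if (length(m) == 2 && is.null(fs)) fs <- as.numeric(m[2])
  }
  if (is.null(fs)) stop("sampling rate unknown: pass `fs` or store a ",
                        "`# fs=` header line")
  sep <- if (grepl("\t", readLines(path, n = skip + 1L)[skip + 1L])) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, skip = skip,
                          check.names = FALSE)
  have <- names(df)
  want <- layout$labels
  pos <- match(tolower(want), tolower(have))
  missing <- want[is.na(pos)]
  if (length(missing)) {
    stop("required channel(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(have, have[pos])
  if (length(extra)) {
    warning("dropping ", length(extra), " extra channel(s): ",
            paste(extra, collapse = ", "))
  }
  data <- t(as.matrix(df[, pos, drop = FALSE]))
  rownames(data) <- want
  new_recording(data, fs, layout)
}

#' Write generator ground truth as JSON
#'
#' @param gt An `eeg_ground_truth`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "eeg_ground_truth"))
  x <- unclass(gt)
  x$events <- lapply(x$events, function(ev) {
    list(start_s = ev$start_s, duration_s = ev$duration_s,
         channel_pairs = ev$channel_pairs,
         phase_lag_rad = ev$phase_lag_rad,
         coupling_strength = ev$coupling_strength)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read generator ground truth from JSON
#'
#' @param path JSON file written by [write_ground_truth()].
#' @return An `eeg_ground_truth`.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  evs <- x$events
  events <- lapply(seq_len(NROW(evs)), function(i) {
    e <- if (is.data.frame(evs)) evs[i, ] else evs[[i]]
    pairs <- e$channel_pairs
    if (is.list(pairs) && length(pairs) == 1 &&
        (is.matrix(pairs[[1]]) || is.list(pairs[[1]]))) {
      pairs <- pairs[[1]]
    }
    if (is.matrix(pairs)) {
      pairs <- lapply(seq_len(nrow(pairs)), function(k) as.character(pairs[k, ]))
    } else if (is.character(pairs)) {
      pairs <- list(pairs)
    } else if (is.list(pairs)) {
      pairs <- lapply(pairs, function(p) as.character(unlist(p)))
    }
    coupling_event(e$start_s, e$duration_s, pairs,
                   e$phase_lag_rad, e$coupling_strength)
  })
  x$events <- events
  if (!is.null(x$mixing_matrix)) x$mixing_matrix <- as.matrix(x$mixing_matrix)
  class(x) <- "eeg_ground_truth"
  x
}

#' Write a connectivity matrix as labelled CSV
#'
#' @param fc An `fc_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fc_csv <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  utils::write.csv(as.data.frame(fc$values), path, row.names = TRUE)
  invisible(path)
}

#' Read a labelled connectivity CSV back into an `fc_matrix`
#'
#' @param path CSV written by [write_fc_csv()].
#' @param metric Metric tag to attach.
#' @param layout Optional `eeg_layout`.
#' @return An `fc_matrix`.
#' @export
read_fc_csv <- function(path, metric = "wPLI", layout = NULL) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  m <- (m + t(m)) / 2    # absorb round-trip rounding
  new_fc_matrix(m, metric, layout)
}

#' Write screening scores and selection as CSV plus a JSON descriptor
#'
#' The CSV holds one row per window (index, start sample, score, selected);
#' the JSON sidecar (`<path>.json`) records the rule, threshold and core
#' pairs so a run is reproducible from its outputs.
#'
#' @param sr A `screening_result`.
#' @param ws The matching `eeg_windows`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_screening_csv <- function(sr, ws, path) {
  stopifnot(inherits(sr, "screening_result"), inherits(ws, "eeg_windows"))
  df <- data.frame(window = seq_along(sr$scores),
                   start_sample = ws$source_indices,
                   score = sr$scores,
                   selected = sr$selected)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(rule = sr$rule, threshold_used = sr$threshold_used,
         core_pairs = sr$core_pairs,
         n_windows = length(sr$scores), n_selected = sum(sr$selected)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a brain graph as an edge list
#'
#' CSV with columns source, target, weight (the underlying connectivity
#' weight of each kept edge), consumable by standard graph tools.
#'
#' @param g A `brain_graph`.
#' @param fc The `fc_matrix` it was binarized from (for edge weights);
#'   omit to write weight 1.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, fc = NULL) {
  stopifnot(inherits(g, "brain_graph"))
  idx <- which(g$adjacency & upper.tri(g$adjacency), arr.ind = TRUE)
  labels <- rownames(g$adjacency)
  w <- if (is.null(fc)) rep(1, nrow(idx)) else fc$values[idx]
  df <- data.frame(source = labels[idx[, 1]], target = labels[idx[, 2]],
                   weight = w)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a PSD estimate as CSV
#'
#' Frequency column plus one power column per channel.
#'
#' @param psd A `psd_estimate`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psd_csv <- function(psd, path) {
  stopifnot(inherits(psd, "psd_estimate"))
  df <- data.frame(freq_hz = psd$freqs, t(psd$power), check.names = FALSE)
  names(df)[-1] <- rownames(psd$power) %||%
    paste0("ch", seq_len(nrow(psd$power)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
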
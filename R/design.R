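#' Generate one randomised event sequence for a scanning run
#'
#' Builds the rapid event-related sequence used for one presentation location
#' (upper or lower visual field). The base sequence contains one image event
#' per (image, source) combination — each image shown once as sourced from
#' above fixation and once from below — plus a number of null events in which
#' nothing is displayed. Event order is a uniform random shuffle. The final
#' `n_prepend` events of the shuffled base sequence are then replicated and
#' prepended, so that the initial volumes of the run (later censored) still
#' contain balanced trials.
#'
#' @param n_images Number of distinct images (each contributes two image
#'   events: source above and source below fixation). Default 30.
#' @param n_nulls Number of null events. Default 15.
#' @param n_prepend Number of trailing events replicated at the start.
#'   Default 8.
#' @param presentation `"upper"` or `"lower"` visual field.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param inter_event_interval Spacing between successive event onsets in
#'   seconds. Default 4.
#'
#' @return A data frame of class `event_sequence` with columns `onset`
#'   (seconds from sequence start), `duration` (1 s for image events, 0 for
#'   nulls), `trial_type` (`"image"` or `"null"`), `image_id`, `source`
#'   (`"above"`/`"below"`, `NA` for nulls) and `is_prepended`. The
#'   presentation location and inter-event interval are stored as attributes.
#' @export
generate_event_sequence <- function(n_images, n_nulls, n_prepend,
                                    presentation = c("upper", "lower"),
                                    seed,
                                    inter_event_interval = 4) {
  presentation <- match.arg(presentation)
  stopifnot(n_images >= 0, n_nulls >= 0, n_prepend >= 0)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for a reproducible event sequence")
  }
  n_base <- 2L * as.integer(n_images) + as.integer(n_nulls)
  if (n_prepend > n_base) {
    stop("n_prepend (", n_prepend, ") exceeds the base sequence length (",
         n_base, ")")
  }

  base <- data.frame(
    trial_type = c(rep("image", 2L * n_images), rep("null", n_nulls)),
    image_id = c(rep(seq_len(n_images), 2L), rep(NA_integer_, n_nulls)),
    source = c(rep("above", n_images), rep("below", n_images),
               rep(NA_character_, n_nulls)),
    stringsAsFactors = FALSE
  )
  if (n_base > 0L) {
    perm <- with_seed(seed, sample.int(n_base))
    base <- base[perm, , drop = FALSE]
  }
  base$is_prepended <- logical(nrow(base))

  if (n_prepend > 0L) {
    pre <- base[seq.int(n_base - n_prepend + 1L, n_base), , drop = FALSE]
    pre$is_prepended <- TRUE
    events <- rbind(pre, base)
  } else {
    events <- base
  }
  rownames(events) <- NULL

  n_events <- nrow(events)
  events <- cbind(
    onset = if (n_events > 0L) inter_event_interval * (seq_len(n_events) - 1)
            else numeric(0),
    duration = ifelse(events$trial_type == "image", 1, 0),
    events
  )
  structure(events,
            presentation = presentation,
            inter_event_interval = inter_event_interval,
            class = c("event_sequence", "data.frame"))
}

#' Build a full run design (paired upper and lower sequences)
#'
#' A run interleaves two independently randomised event sequences, one for
#' upper and one for lower visual field presentation, on a common timeline.
#' One of the two sequences (chosen pseudo-randomly per run) is advanced by
#' 2 s: its onsets fall at 0, 4, 8, ... s while the other's fall at
#' 2, 6, 10, ... s. Since image events last 1 s and the inter-event interval
#' is 4 s, upper and lower patches are never simultaneously visible.
#'
#' @inheritParams generate_event_sequence
#' @param seed Integer run seed; sub-seeds for the two sequences and for the
#'   advanced-sequence coin flip are derived from it deterministically.
#'
#' @return A list of class `run_design` with elements `upper_seq`,
#'   `lower_seq` (each an [generate_event_sequence()] data frame, with onsets
#'   already shifted onto the run timeline), `advanced_seq` (`"upper"` or
#'   `"lower"`), `duration` (seconds), `inter_event_interval` and `seed`.
#' @export
build_run <- function(n_images = 30, n_nulls = 15, n_prepend = 8, seed,
                      inter_event_interval = 4) {
  if (missing(seed) || is.null(seed)) stop("a run seed is required")
  draws <- with_seed(seed, list(
    sub_seeds = sample.int(.Machine$integer.max, 2L),
    advanced = sample(c("upper", "lower"), 1L)
  ))

  upper <- generate_event_sequence(n_images, n_nulls, n_prepend, "upper",
                                   seed = draws$sub_seeds[1L],
                                   inter_event_interval = inter_event_interval)
  lower <- generate_event_sequence(n_images, n_nulls, n_prepend, "lower",
                                   seed = draws$sub_seeds[2L],
                                   inter_event_interval = inter_event_interval)

  offset <- inter_event_interval / 2
  if (draws$advanced == "upper") {
    lower$onset <- lower$onset + offset
  } else {
    upper$onset <- upper$onset + offset
  }

  structure(list(
    upper_seq = upper,
    lower_seq = lower,
    advanced_seq = draws$advanced,
    duration = nrow(upper) * inter_event_interval,
    inter_event_interval = inter_event_interval,
    seed = as.integer(seed)
  ), class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat("Run design:", nrow(x$upper_seq), "events per sequence,",
      x$duration, "s,", x$advanced_seq, "sequence advanced by",
      x$inter_event_interval / 2, "s\n")
  invisible(x)
}

#' Write a run design as a BIDS-style events.tsv table
#'
#' Both sequences are merged, sorted by onset and written as a tab-separated
#' table with columns `onset`, `duration`, `trial_type`, `image_id`,
#' `source`, `presentation` and `is_prepended`; missing values are written as
#' `n/a` and onsets with three decimal places, following the BIDS events.tsv
#' dialect. A JSON-style sidecar (same path with extension `.json`) records
#' the run seed, the inter-event interval and the prepend count so that
#' [read_events()] can reconstruct the run exactly.
#'
#' @param run A `run_design` from [build_run()].
#' @param path Output path for the `.tsv` file.
#' @return `path`, invisibly.
#' @export
write_events <- function(run, path) {
  stopifnot(inherits(run, "run_design"))
  tab <- rbind(as.data.frame(run$upper_seq), as.data.frame(run$lower_seq))
  tab$presentation <- rep(c("upper", "lower"),
                          c(nrow(run$upper_seq), nrow(run$lower_seq)))
  if (nrow(tab) > 0L) tab <- tab[order(tab$onset), , drop = FALSE]
  out <- data.frame(
    onset = sprintf("%.3f", tab$onset),
    duration = sprintf("%.3f", tab$duration),
    trial_type = tab$trial_type,
    image_id = ifelse(is.na(tab$image_id), "n/a", as.character(tab$image_id)),
    source = ifelse(is.na(tab$source), "n/a", tab$source),
    presentation = tab$presentation,
    is_prepended = ifelse(tab$is_prepended, "1", "0"),
    stringsAsFactors = FALSE
  )
  if (nrow(tab) == 0L) out <- out[0L, , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  writeLines(sprintf(
    '{"seed": %d, "inter_event_interval": %s, "n_prepend": %d, "advanced_seq": "%s", "duration": %s}',
    run$seed, format(run$inter_event_interval), sum(run$upper_seq$is_prepended),
    run$advanced_seq, format(run$duration)), sidecar)
  invisible(path)
}

#' Read a run design back from an events.tsv table
#'
#' @param path Path to a `.tsv` file written by [write_events()] (or
#'   hand-written in the same dialect). If the sidecar `.json` is present the
#'   run seed and timing metadata are restored from it; otherwise they are
#'   inferred from the table (seed `NA`).
#' @return A `run_design` list.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty events file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  needed <- c("onset", "duration", "trial_type", "presentation")
  missing_cols <- setdiff(needed, header)
  if (length(missing_cols) > 0L) {
    stop("line 1: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  nfield <- length(header)
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != nfield) {
      stop("line ", i, ": expected ", nfield, " fields, found ", length(f))
    }
    f
  })
  tab <- as.data.frame(do.call(rbind, c(rows, list(deparse.level = 0))),
                       stringsAsFactors = FALSE)
  if (length(rows) == 0L) {
    tab <- as.data.frame(matrix(character(0), ncol = nfield),
                         stringsAsFactors = FALSE)
  }
  names(tab) <- header
  na_in <- function(x) replace(x, x == "n/a", NA)
  onset <- suppressWarnings(as.numeric(tab$onset))
  if (any(is.na(onset) & tab$onset != "n/a")) {
    bad <- which(is.na(onset))[1L] + 1L
    stop("line ", bad, ": malformed onset value '", tab$onset[bad - 1L], "'")
  }

  meta <- list(seed = NA_integer_, inter_event_interval = NA_real_,
               advanced_seq = NA_character_, duration = NA_real_)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    txt <- paste(readLines(sidecar), collapse = " ")
    grab <- function(key) {
      m <- regmatches(txt, regexpr(paste0('"', key, '":\\s*"?[^,}"]+'), txt))
      if (length(m) == 0L) return(NA)
      sub(paste0('"', key, '":\\s*"?'), "", m)
    }
    meta$seed <- as.integer(grab("seed"))
    meta$inter_event_interval <- as.numeric(grab("inter_event_interval"))
    meta$advanced_seq <- as.character(grab("advanced_seq"))
    meta$duration <- as.numeric(grab("duration"))
  }

  mk_seq <- function(pres) {
    sel <- tab$presentation == pres
    d <- data.frame(
      onset = onset[sel],
      duration = as.numeric(tab$duration[sel]),
      trial_type = tab$trial_type[sel],
      image_id = if ("image_id" %in% names(tab)) {
        as.integer(na_in(tab$image_id[sel]))
      } else rep(NA_integer_, sum(sel)),
      source = if ("source" %in% names(tab)) {
        as.character(na_in(tab$source[sel]))
      } else rep(NA_character_, sum(sel)),
      is_prepended = if ("is_prepended" %in% names(tab)) {
        tab$is_prepended[sel] == "1"
      } else rep(FALSE, sum(sel)),
      stringsAsFactors = FALSE
    )
    d <- d[order(d$onset), , drop = FALSE]
    rownames(d) <- NULL
    iei <- meta$inter_event_interval
    if (is.na(iei)) {
      iei <- if (nrow(d) > 1L) diff(d$onset)[1L] else 4
    }
    structure(d, presentation = pres, inter_event_interval = iei,
              class = c("event_sequence", "data.frame"))
  }
  upper <- mk_seq("upper")
  lower <- mk_seq("lower")

  advanced <- meta$advanced_seq
  if (is.na(advanced)) {
    advanced <- if (nrow(upper) == 0L || nrow(lower) == 0L) {
      "upper"
    } else if (upper$onset[1L] <= lower$onset[1L]) "upper" else "lower"
  }
  iei <- attr(upper, "inter_event_interval")
  duration <- meta$duration
  if (is.na(duration)) duration <- nrow(upper) * iei

  structure(list(
    upper_seq = upper, lower_seq = lower, advanced_seq = advanced,
    duration = duration, inter_event_interval = iei, seed = meta$seed
  ), class = "run_design")
}
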
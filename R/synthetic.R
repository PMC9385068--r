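# Synthetic heart-rate-like stream generation, plus the condensation and
# replication protocol used to scale benchmark datasets, and an offline
# loader for the PAMAP2 heart-rate channel.
#
# Generated streams are built from three segment kinds that carry exactly
# the redundancy salient-point extraction exploits: constant plateaus
# (zero-derivative runs), monotone ramps with alternating direction
# (same-trend runs), and short low-amplitude oscillation bursts (turns
# inside the alpha window). Values are integer bpm clipped to the device's
# range, as wearable heart-rate sensors report.

# Per-subject value ranges of minute-resolution heart-rate benchmarks
# (bpm); one is assigned to each generated device.
hr_ranges <- list(c(78, 120), c(74, 107), c(68, 94), c(57, 121),
                  c(70, 101), c(60, 104), c(60, 99), c(66, 104))

#' Generate one synthetic heart-rate stream
#'
#' Builds a minute-resolution stream of plateaus, alternating-direction
#' monotone ramps, and short fluctuation bursts, clipped to `range` and
#' rounded to whole bpm. Deterministic for a given `(seed, device_id)`
#' pair.
#'
#' @param n_points number of observations (default 600).
#' @param interval sampling interval in minutes (default 1).
#' @param range numeric `c(lo, hi)` value range for this device.
#' @param p_plateau,p_ramp,p_burst segment-type probabilities (need not sum
#'   to one; they are renormalized).
#' @param seed master seed; combined with `device_id` so each device gets
#'   an independent, reproducible stream.
#' @param device_id label used for seeding.
#' @return a device stream (data.frame `t`, `x`).
#' @export
generate_stream <- function(n_points = 600, interval = 1,
                            range = c(60, 100),
                            p_plateau = 0.35, p_ramp = 0.45,
                            p_burst = 0.20,
                            seed = NULL, device_id = "d1") {
  if (length(range) != 2L || range[1] >= range[2])
    stop("range must be c(lo, hi) with lo < hi")
  if (n_points < 2L) stop("n_points must be >= 2")
  lo <- range[1]; hi <- range[2]
  dev_seed <- if (is.null(seed)) NULL else derive_seed(seed, id_hash(device_id))
  x <- with_seed(dev_seed, {
    cur <- stats::runif(1, lo + 0.3 * (hi - lo), hi - 0.3 * (hi - lo))
    vals <- cur
    dir <- sample(c(-1, 1), 1)
    probs <- c(p_plateau, p_ramp, p_burst)
    if (sum(probs) <= 0) stop("segment probabilities must not all be zero")
    while (length(vals) < n_points) {
      kind <- sample(3L, 1L, prob = probs)
      if (kind == 1L) {                        # plateau
        len <- sample(8:40, 1)
        vals <- c(vals, rep(cur, len))
      } else if (kind == 2L) {                 # ramp, alternating direction
        len <- sample(15:60, 1)
        span <- stats::runif(1, 0.2, 0.8) * (hi - lo)
        target <- cur + dir * span
        target <- min(max(target, lo), hi)
        dir <- -dir
        seg <- seq(cur, target, length.out = len + 1)[-1]
        vals <- c(vals, seg)
        cur <- target
      } else {                                 # fluctuation burst
        len <- sample(6:20, 1)
        amp <- stats::runif(1, 1, 3)
        seg <- cur + amp * rep_len(c(1, -1), len)
        vals <- c(vals, seg, cur)
      }
    }
    vals[seq_len(n_points)]
  })
  x <- round(pmin(pmax(x, lo), hi))
  device_stream(interval * seq_len(n_points), x)
}

#' Generate a collection of synthetic streams
#'
#' Devices cycle through the built-in per-subject heart-rate value ranges
#' (57-121 bpm overall), giving inter-device heterogeneity.
#'
#' @param n_devices number of devices (default 8).
#' @param seed master seed (each device derives its own sub-seed).
#' @param ... passed to [generate_stream()] (e.g. `n_points`, segment
#'   probabilities).
#' @return an `"ldp_streams"` collection named `dev101`, `dev102`, ...
#' @export
generate_streams <- function(n_devices = 8, seed = NULL, ...) {
  ids <- sprintf("dev%d", 100 + seq_len(n_devices))
  out <- lapply(seq_len(n_devices), function(i)
    generate_stream(range = hr_ranges[[(i - 1L) %% 8L + 1L]],
                    seed = seed, device_id = ids[i], ...))
  names(out) <- ids
  structure(out, class = "ldp_streams")
}

#' Condense a stream by block decimation
#'
#' Keeps the first record of every consecutive block of `k` records
#' (timestamps preserved), the protocol used to thin 3000-record streams
#' to 600.
#'
#' @param stream a device stream.
#' @param k block size, `>= 1`.
#' @return a device stream with `ceiling(nrow/k)` records.
#' @export
condense <- function(stream, k) {
  if (k < 1) stop("k must be >= 1")
  stream[seq(1L, nrow(stream), by = k), , drop = FALSE]
}

#' Replicate devices up to a target record count
#'
#' Copies each base stream (values unchanged, fresh device ids) until the
#' total number of records reaches `target_total`, which must be a
#' multiple of the base total. Duplicating devices leaves the
#' per-timestamp actual mean unchanged; each copy is perturbed with
#' independent noise downstream.
#'
#' @param base an `"ldp_streams"` collection.
#' @param target_total desired total record count (e.g. 120000).
#' @return an `"ldp_streams"` collection with `target_total` records.
#' @export
replicate_devices <- function(base, target_total) {
  total <- sum(vapply(base, nrow, 1L))
  if (target_total %% total != 0)
    stop("target_total (", target_total,
         ") must be a multiple of the base record count (", total, ")")
  fac <- target_total %/% total
  out <- vector("list", length(base) * fac)
  nms <- character(length(out))
  k <- 0L
  for (r in seq_len(fac)) {
    for (id in names(base)) {
      k <- k + 1L
      out[[k]] <- base[[id]]
      nms[k] <- if (r == 1L) id else paste0(id, "_r", r)
    }
  }
  names(out) <- nms
  structure(out, class = "ldp_streams")
}

#' Load PAMAP2 heart-rate streams (offline)
#'
#' Reads local PAMAP2 protocol files `subject<id>.dat` (whitespace
#' separated; column 1 timestamp in seconds, column 3 heart rate in bpm,
#' missing readings `NaN`), keeps the first valid heart-rate reading of
#' each minute, and returns up to `max_minutes` records per subject as a
#' stream ready for `condense(., 5)`. The data set is never downloaded;
#' point `dir` at an existing local copy. Subjects with fewer than two
#' valid minutes are skipped with a warning.
#'
#' @param dir directory containing `subject101.dat` ... `subject108.dat`
#'   (the `Protocol` folder of a PAMAP2 download).
#' @param subjects integer subject ids (default `101:108`).
#' @param max_minutes cap on records per subject (default 3000).
#' @return an `"ldp_streams"` collection, one stream per subject found.
#' @export
load_pamap2 <- function(dir, subjects = 101:108, max_minutes = 3000) {
  if (!dir.exists(dir))
    stop("PAMAP2 directory not found: ", dir,
         "\nDownload PAMAP2 from the UCI repository and pass its ",
         "'Protocol' directory.")
  files <- file.path(dir, sprintf("subject%d.dat", subjects))
  missing <- !file.exists(files)
  if (all(missing))
    stop("no subject<id>.dat files in ", dir)
  out <- list()
  for (i in seq_along(subjects)) {
    if (missing[i]) {
      warning("subject ", subjects[i], ": file not found, skipped")
      next
    }
    raw <- utils::read.table(files[i], header = FALSE, fill = TRUE)
    if (ncol(raw) < 3L)
      stop("subject file ", files[i], " has fewer than 3 columns; ",
           "expected PAMAP2 protocol format")
    dat <- data.frame(sec = as.numeric(raw[[1]]), hr = as.numeric(raw[[3]]))
    dat <- dat[is.finite(dat$hr), , drop = FALSE]
    if (!nrow(dat)) {
      warning("subject ", subjects[i], ": no valid heart-rate readings, ",
              "skipped")
      next
    }
    minute <- floor(dat$sec / 60)
    first <- !duplicated(minute)
    hr <- dat$hr[first]
    keep <- seq_len(min(length(hr), max_minutes))
    if (length(keep) < 2L) {
      warning("subject ", subjects[i], ": insufficient data, skipped")
      next
    }
    out[[sprintf("subj%d", subjects[i])]] <-
      device_stream(seq_along(keep), hr[keep])
  }
  if (!length(out)) stop("no usable subjects in ", dir)
  structure(out, class = "ldp_streams")
}
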
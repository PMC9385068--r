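# Private mean-curve estimation: the end-to-end pipeline fitted as an
# estimator object, plus the benchmark sweep harness.

perturb_for <- function(mechanism) {
  switch(mechanism,
    adaptive = perturb_adaptive,
    kim = perturb_kim,
    dwork = perturb_dwork,
    stop("unknown mechanism '", mechanism, "'"))
}

#' Locally private estimate of the cross-device mean curve
#'
#' Runs the full collection pipeline on a stream collection: per device,
#' identify the salient points (threshold `alpha`), perturb them with the
#' chosen mechanism under total budget `epsilon`, and reconstruct the
#' curve on the original timestamp grid; then average across devices and
#' score the estimate against the true mean curve by MRE and RMSE. The
#' whole experiment is repeated `reps` times with independent noise and
#' the metrics averaged, mirroring repeated-trial evaluation.
#'
#' The `"dwork"` mechanism perturbs every original point (no salient
#' extraction or reconstruction); `"kim"` shares the salient pipeline but
#' omits the adaptive noise weight.
#'
#' @param streams an `"ldp_streams"` collection; all devices must share
#'   one timestamp grid.
#' @param epsilon total privacy budget per device (`> 0`).
#' @param alpha salient-point interval threshold in timestamp units
#'   (default 30).
#' @param mechanism `"adaptive"` (default), `"kim"`, or `"dwork"`.
#' @param recon reconstruction method: `"linear"` (default, lowest error),
#'   `"pchip"`, or `"spline"`.
#' @param reps number of independent repetitions averaged (default 20).
#' @param seed master seed; every repetition derives its own sub-seed.
#'   `NULL` draws a seed from the session RNG (recorded in the result).
#' @param noise_factor multiplier on all injected noise; 0 gives the
#'   noise-free diagnostic path.
#' @return An object of class `"ldp_mean"`: list with the grid `t`,
#'   per-timestamp `actual` and `estimate` (averaged over repetitions),
#'   averaged `mre` and `rmse`, per-repetition `errors` data.frame,
#'   salient-point counts `p`, and the run configuration.
#' @examples
#' s <- generate_streams(4, n_points = 120, seed = 1)
#' fit <- ldp_mean(s, epsilon = 2, reps = 3, seed = 1)
#' fit
#' @export
ldp_mean <- function(streams, epsilon = 1, alpha = 30,
                     mechanism = c("adaptive", "kim", "dwork"),
                     recon = c("linear", "pchip", "spline"),
                     reps = 20, seed = NULL, noise_factor = 1) {
  mechanism <- match.arg(mechanism)
  recon <- match.arg(recon)
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (reps < 1) stop("reps must be >= 1")
  if (!inherits(streams, "ldp_streams"))
    streams <- as_streams_list(streams)
  grid <- common_grid(streams)
  n <- length(grid)
  w <- length(streams)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)

  actual <- aggregate_mean(streams)

  # Salient extraction is deterministic: compute once per distinct stream.
  p <- integer(w)
  sal <- vector("list", w)
  if (mechanism != "dwork") {
    key <- vapply(streams, function(s) paste(s$x, collapse = ","), "")
    first <- match(key, key)
    for (i in seq_len(w)) {
      if (first[i] == i)
        sal[[i]] <- identify_salient(streams[[i]], alpha)
      else
        sal[[i]] <- sal[[first[i]]]
      p[i] <- nrow(sal[[i]])
    }
  } else {
    p <- vapply(streams, nrow, 1L)
  }

  pert_fn <- perturb_for(mechanism)
  err <- data.frame(rep = seq_len(reps), mre = NA_real_, rmse = NA_real_)
  est_sum <- numeric(n)
  for (r in seq_len(reps)) {
    acc <- with_seed(derive_seed(seed, r), {
      a <- numeric(n)
      for (i in seq_len(w)) {
        if (mechanism == "dwork") {
          a <- a + pert_fn(streams[[i]], epsilon, noise_factor)$x
        } else {
          pt <- pert_fn(sal[[i]], epsilon, noise_factor)
          a <- a + recon_values(pt$t, pt$x, grid, recon)
        }
      }
      a
    })
    est_r <- data.frame(t = grid, avg = acc / w)
    err$mre[r] <- mre(actual, est_r)
    err$rmse[r] <- rmse(actual, est_r)
    est_sum <- est_sum + est_r$avg
  }

  structure(list(t = grid, actual = actual$avg, estimate = est_sum / reps,
                 mre = mean(err$mre), rmse = mean(err$rmse), errors = err,
                 w = w, n = n, p = p, epsilon = epsilon, alpha = alpha,
                 mechanism = mechanism, recon = recon, reps = reps,
                 seed = seed, noise_factor = noise_factor,
                 call = match.call()),
            class = "ldp_mean")
}

as_streams_list <- function(x) {
  if (is.data.frame(x) && all(c("device_id", "timestamp", "value") %in%
                              names(x)))
    return(as_streams(x))
  if (is.list(x) && all(vapply(x, is.data.frame, TRUE)))
    return(structure(x, class = "ldp_streams"))
  stop("cannot interpret `streams`; pass an 'ldp_streams' collection")
}

#' @export
print.ldp_mean <- function(x, digits = 4, ...) {
  cat("Locally private mean-curve estimate\n")
  cat(sprintf("  devices: %d   grid: %d pts   mechanism: %s   recon: %s\n",
              x$w, x$n, x$mechanism, x$recon))
  cat(sprintf("  epsilon: %g   alpha: %g   reps: %d   seed: %d\n",
              x$epsilon, x$alpha, x$reps, x$seed))
  cat(sprintf("  MRE:  %s\n  RMSE: %s\n",
              format(x$mre, digits = digits),
              format(x$rmse, digits = digits)))
  invisible(x)
}

#' @export
summary.ldp_mean <- function(object, ...) {
  s <- object[c("w", "n", "epsilon", "alpha", "mechanism", "recon",
                "reps", "seed", "mre", "rmse")]
  s$p_mean <- mean(object$p)
  s$compression <- 1 - mean(object$p) / object$n
  s$mre_se <- stats::sd(object$errors$mre) / sqrt(object$reps)
  s$rmse_se <- stats::sd(object$errors$rmse) / sqrt(object$reps)
  s$errors <- object$errors
  class(s) <- "summary.ldp_mean"
  s
}

#' @export
print.summary.ldp_mean <- function(x, digits = 4, ...) {
  cat("Locally private mean-curve estimate\n")
  cat(sprintf("  devices: %d   grid: %d pts   mechanism: %s   recon: %s\n",
              x$w, x$n, x$mechanism, x$recon))
  cat(sprintf("  epsilon: %g   alpha: %g   reps: %d   seed: %d\n",
              x$epsilon, x$alpha, x$reps, x$seed))
  if (x$mechanism != "dwork")
    cat(sprintf("  salient points per device: %.1f of %d (%.1f%% removed)\n",
                x$p_mean, x$n, 100 * x$compression))
  cat(sprintf("  MRE:  %s (se %s)\n  RMSE: %s (se %s)\n",
              format(x$mre, digits = digits),
              format(x$mre_se, digits = 2),
              format(x$rmse, digits = digits),
              format(x$rmse_se, digits = 2)))
  invisible(x)
}

#' @export
fitted.ldp_mean <- function(object, ...) object$estimate

#' @export
residuals.ldp_mean <- function(object, ...) object$actual - object$estimate

#' Plot actual vs privately estimated mean curve
#'
#' @param x an `"ldp_mean"` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ldp_mean <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$actual, x$estimate), type = "l",
                    lty = c(1, 2), col = c("black", "red3"),
                    xlab = "time (min)", ylab = "mean value",
                    main = sprintf("%s / %s, epsilon = %g",
                                   x$mechanism, x$recon, x$epsilon), ...)
  graphics::legend("topright", c("actual", "estimated"), lty = c(1, 2),
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Benchmark sweep over mechanisms, reconstructions, budgets and sizes
#'
#' Runs [ldp_mean()] over the cross-product of the supplied factors,
#' replicating the base collection to each target record count, and
#' returns one row per cell: `mechanism, recon, epsilon, data_size, reps,
#' mre, rmse`. Noise seeds are derived per (size, epsilon, repetition) but
#' not per mechanism or reconstruction method, so those comparisons are
#' paired (controlled-variable design).
#'
#' @param streams base `"ldp_streams"` collection.
#' @param epsilons privacy budgets to sweep (default `c(0.5, 1, 2)`).
#' @param sizes target total record counts for [replicate_devices()];
#'   `NULL` (default) uses the collection as given.
#' @param mechanisms,recons factor levels to sweep.
#' @param alpha salient threshold (default 30).
#' @param reps repetitions per cell (default 20).
#' @param seed master seed.
#' @param file optional path; when given the table is also written as CSV.
#' @return data.frame with one row per swept cell.
#' @export
run_sweep <- function(streams, epsilons = c(0.5, 1, 2), sizes = NULL,
                      mechanisms = "adaptive", recons = "linear",
                      alpha = 30, reps = 20, seed = NULL, file = NULL) {
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  base_total <- sum(vapply(streams, nrow, 1L))
  if (is.null(sizes)) sizes <- base_total
  rows <- list()
  for (si in seq_along(sizes)) {
    data_si <- if (sizes[si] == base_total) streams else
      replicate_devices(streams, sizes[si])
    for (ei in seq_along(epsilons)) {
      cell_seed <- derive_seed(seed, si, ei)
      for (mech in mechanisms) for (rc in recons) {
        fit <- ldp_mean(data_si, epsilon = epsilons[ei], alpha = alpha,
                        mechanism = mech, recon = rc, reps = reps,
                        seed = cell_seed)
        rows[[length(rows) + 1L]] <-
          data.frame(mechanism = mech, recon = rc,
                     epsilon = epsilons[ei], data_size = sizes[si],
                     reps = reps, mre = fit$mre, rmse = fit$rmse,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
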
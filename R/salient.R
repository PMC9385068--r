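# Salient-point identification.
#
# A stream point is redundant when (a) its value equals its predecessor's
# (zero derivative), (b) it continues the trend of its neighbours (same-sign
# derivatives), or (c) it is a trend turn that follows the last kept point
# within the interval threshold alpha (short fluctuation). The surviving
# points -- always including the stream's first and last observation -- are
# the salient points the device actually spends privacy budget on.

#' Remove zero-derivative points
#'
#' First censoring pass: every point whose derivative relative to its
#' predecessor in the original stream is exactly zero is dropped; the first
#' point is kept unconditionally. Survivors keep the derivative they had in
#' the original stream.
#'
#' @param stream a device stream (data.frame `t`, `x`).
#' @return data.frame with columns `t`, `x`, `d` (derivative; `NA` for the
#'   first point).
#' @export
remove_zero_derivative <- function(stream) {
  if (nrow(stream) < 2L)
    stop("stream must have at least 2 points")
  d <- stream_derivatives(stream)
  keep <- c(TRUE, d[-1L] != 0)
  data.frame(t = stream$t[keep], x = stream$x[keep], d = d[keep])
}

#' Select trend turning points
#'
#' Second censoring pass over the zero-derivative-free list: an interior
#' candidate is deleted when its derivative and the next candidate's share
#' the same sign (same trend), and also deleted at a sign change when the
#' time from the last kept point, `t_int = t_cur - t_sta`, is at most
#' `alpha`; otherwise it is kept and becomes the new starting point. The
#' first entry of the list and the last point of the parent stream are
#' always kept.
#'
#' @param list1 output of [remove_zero_derivative()].
#' @param alpha maximum-interval threshold (timestamp units); `alpha >= 0`.
#' @param last optional `c(t, x)` of the parent stream's final point, used
#'   to guarantee the endpoint survives even if censored earlier; defaults
#'   to the last row of `list1`.
#' @return data.frame with columns `t`, `x`: the salient points.
#' @export
select_turning_points <- function(list1, alpha, last = NULL) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (nrow(list1) < 1L) stop("list1 must be nonempty")
  p <- nrow(list1)
  if (is.null(last)) last <- c(list1$t[p], list1$x[p])
  keep <- logical(p)
  keep[1L] <- TRUE            # first real point seeds the traversal
  t_sta <- list1$t[1L]
  if (p >= 2L) {
    for (j in seq(2L, p)) {
      if (j == p) { keep[j] <- TRUE; break }  # final traversed point kept
      dj <- list1$d[j]; dn <- list1$d[j + 1L]
      if ((dj > 0 && dn > 0) || (dj < 0 && dn < 0)) {
        # same trend: drop
      } else if (list1$t[j] - t_sta <= alpha) {
        # turn inside the alpha window: drop
      } else {
        keep[j] <- TRUE
        t_sta <- list1$t[j]
      }
    }
  }
  out <- data.frame(t = list1$t[keep], x = list1$x[keep])
  if (out$t[nrow(out)] != last[1L])
    out <- rbind(out, data.frame(t = last[1L], x = last[2L]))
  out
}

#' Identify the salient points of a stream
#'
#' Composition of [remove_zero_derivative()] and [select_turning_points()]:
#' returns the subsequence of the stream that best preserves its curve
#' shape. Endpoints are always retained, so the salient points span the
#' full timestamp grid.
#'
#' @param stream a device stream.
#' @param alpha maximum-interval threshold (default 30 minutes).
#' @return data.frame with columns `t`, `x` -- an ordered subsequence of
#'   `stream`.
#' @examples
#' s <- device_stream(1:5, c(70, 70, 72, 74, 73))
#' identify_salient(s, alpha = 0)   # keeps (1,70), (4,74), (5,73)
#' @export
identify_salient <- function(stream, alpha = 30) {
  list1 <- remove_zero_derivative(stream)
  n <- nrow(stream)
  select_turning_points(list1, alpha,
                        last = c(stream$t[n], stream$x[n]))
}
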
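# Internal helpers: validation, seeding, geometry, intervals.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
}

check_scalar_pos <- function(x, field, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (x > 0 || (allow_zero && x >= 0))
  if (!ok) stop_field(field, if (allow_zero) "must be >= 0" else "must be > 0")
  invisible(x)
}

#' Derive a child seed from a global seed
#'
#' Each stochastic stage draws its own seed deterministically from the
#' session/config seed so that stages can be re-run in isolation without
#' perturbing one another. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param offset integer stage offset (small, stage-specific constant).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# Point-in-polygon; poly is an n x 2 matrix of vertices (not closed).
points_in_poly <- function(x, y, poly) {
  if (length(x) == 0L) return(logical(0))
  as.logical(mgcv::in.out(rbind(poly, poly[1L, , drop = FALSE]),
                          cbind(as.numeric(x), as.numeric(y))))
}

# Merge overlapping/abutting half-open intervals given as a 2-col matrix.
merge_intervals <- function(ints, gap = 0) {
  if (is.null(ints) || nrow(ints) == 0L) return(ints)
  o <- order(ints[, 1L])
  ints <- ints[o, , drop = FALSE]
  out <- ints[1L, , drop = FALSE]
  for (i in seq_len(nrow(ints))[-1L]) {
    if (ints[i, 1L] <= out[nrow(out), 2L] + gap) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], ints[i, 2L])
    } else {
      out <- rbind(out, ints[i, , drop = FALSE])
    }
  }
  out
}

# Total overlap length between [a1,a2) and a set of intervals.
interval_overlap <- function(a1, a2, ints) {
  if (is.null(ints) || nrow(ints) == 0L) return(0)
  lo <- pmax(a1, ints[, 1L]); hi <- pmin(a2, ints[, 2L])
  sum(pmax(0, hi - lo))
}

# TRUE for times falling in any [start, end) of the interval matrix.
in_any_interval <- function(t, ints) {
  if (is.null(ints) || nrow(ints) == 0L) return(rep(FALSE, length(t)))
  o <- order(ints[, 1L])
  starts <- ints[o, 1L]; ends <- ints[o, 2L]
  idx <- findInterval(t, starts)
  res <- idx > 0L
  res[res] <- t[res] < ends[idx[res]]
  res
}

cue_levels <- function() c("X1", "X2", "Y1", "Y2", "Z1", "Z2")

cue_set <- function(cue) as.integer(substr(cue, 2L, 2L))
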
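#' Construct a trajectory
#'
#' A trajectory is the time-stamped 2-D path of one object within a scene:
#' an ordered, uniformly sampled sequence of (t, x, y) positions in pixels.
#'
#' @param object_id Identifier of the object (coerced to character).
#' @param t Numeric vector of sample times in seconds, strictly increasing
#'   and uniformly spaced (tolerance 1e-6 s).
#' @param x,y Numeric vectors of positions in pixels; must be finite and the
#'   same length as `t`.
#' @param frame_rate Sampling rate in Hz. Defaults to `1 / median(diff(t))`.
#'
#' @return An object of class `fm_trajectory`: a data frame with columns
#'   `t`, `x`, `y` and attributes `object_id` and `frame_rate`.
#' @export
#' @examples
#' tr <- trajectory("f1", t = seq(0, 1, by = 0.1), x = 1:11, y = rep(0, 11))
#' nrow(tr)
trajectory <- function(object_id, t, x, y, frame_rate = NULL) {
  if (length(t) < 2L) {
    stop("invalid trajectory: needs at least 2 samples", call. = FALSE)
  }
  if (length(x) != length(t) || length(y) != length(t)) {
    stop("invalid trajectory: t, x, y must have equal length", call. = FALSE)
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop("invalid trajectory: time must be strictly increasing", call. = FALSE)
  }
  if (max(dt) - min(dt) > 1e-6) {
    stop("invalid trajectory: sampling must be uniform (1e-6 s tolerance)",
         call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("invalid trajectory: positions must be finite", call. = FALSE)
  }
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(dt)
  out <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y))
  attr(out, "object_id") <- as.character(object_id)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("fm_trajectory", "data.frame")
  out
}

#' @export
print.fm_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s: %d samples, %.2f s at %.1f Hz>\n",
              attr(x, "object_id"), nrow(x), x$t[nrow(x)] - x$t[1],
              attr(x, "frame_rate")))
  invisible(x)
}

#' Read and write trajectory CSV files
#'
#' One CSV holds all trajectories of a scene, long format with columns
#' `object_id,frame,t,x,y` (header required, '.' decimal separator).
#'
#' @param path Path to a CSV file.
#' @return `read_trajectories()` returns a named list of [trajectory()]
#'   objects, one per `object_id`, in first-appearance order.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("object_id", "frame", "t", "x", "y")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  ids <- unique(df$object_id)
  out <- lapply(ids, function(id) {
    d <- df[df$object_id == id, , drop = FALSE]
    d <- d[order(d$frame), , drop = FALSE]
    trajectory(id, d$t, d$x, d$y)
  })
  names(out) <- as.character(ids)
  out
}

#' @rdname read_trajectories
#' @param trajs List of trajectories (as returned by the simulators).
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "fm_trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    data.frame(object_id = attr(tr, "object_id"),
               frame = seq_len(nrow(tr)) - 1L,
               t = tr$t, x = tr$x, y = tr$y)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Evaluate an expression with a temporary RNG seed, restoring .Random.seed.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a per-stage child seed from a root seed; keeps results < 2^31.
# Double arithmetic: the intermediate products stay well below 2^53, so the
# modulus is exact even for seeds near the 32-bit limit.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 1103 + as.numeric(stage) * 7919) %% 2147483647)
}
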
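#' Unsorted spike data: event times with mark vectors
#'
#' A marked event sequence holds strictly increasing event times in `(0, T]`
#' seconds together with one mark vector per event (rows of `marks`), e.g. a
#' concatenated spike-waveform snippet. Duplicate times are permitted on input
#' (distinct marks, preserved in order) and are separated by an epsilon jitter
#' when `jitter_ties = TRUE` so the stored times are strictly ascending.
#'
#' @param times numeric vector of event times, seconds, in (0, duration_T]
#' @param marks n x D_k numeric matrix, one mark per event (float32 storage is
#'   promoted to double)
#' @param duration_T observation interval length, seconds
#' @param probe_id optional label
#' @param jitter_ties break exactly tied times by adding multiples of a tiny
#'   epsilon, keeping input (stable) order
#' @return object of class `marked_events`
#' @export
marked_events <- function(times, marks, duration_T, probe_id = NULL,
                          jitter_ties = TRUE) {
  times <- as.numeric(times)
  marks <- as.matrix(marks)
  storage.mode(marks) <- "double"
  if (length(times) != nrow(marks))
    stop("length(times) must equal nrow(marks)", call. = FALSE)
  if (length(times) && (any(times <= 0) | any(times > duration_T)))
    stop("event times must lie in (0, duration_T]", call. = FALSE)
  ord <- order(times) # stable sort: ties keep input order
  times <- times[ord]
  marks <- marks[ord, , drop = FALSE]
  if (length(times) > 1L && any(diff(times) == 0)) {
    if (!jitter_ties) stop("tied event times (set jitter_ties = TRUE)", call. = FALSE)
    eps <- max(duration_T, 1) * .Machine$double.eps * 8
    while (any(diff(times) == 0)) {
      k <- which(diff(times) == 0) + 1L
      times[k] <- times[k] + eps
    }
    times <- pmin(times, duration_T)
    if (any(diff(times) <= 0)) stop("could not break time ties", call. = FALSE)
  }
  structure(list(times = times, marks = marks, duration_T = as.numeric(duration_T),
                 probe_id = probe_id),
            class = "marked_events")
}

#' @export
print.marked_events <- function(x, ...) {
  cat(sprintf("<marked_events: %d events, %d-dim marks, T = %g s%s>\n",
              length(x$times), ncol(x$marks), x$duration_T,
              if (is.null(x$probe_id)) "" else paste0(", probe ", x$probe_id)))
  invisible(x)
}

#' Events as a tibble (one row per spike)
#' @param x a `marked_events`
#' @param ... unused
#' @exportS3Method generics::tidy
tidy.marked_events <- function(x, ...) {
  tibble::tibble(time = x$times,
                 mark = lapply(seq_along(x$times), function(i) x$marks[i, ]))
}

#' Covariate time series on a regular grid
#'
#' Values `y` observed at grid times `t_j = j * dt`, `j = 1..m` (the grid
#' starts at `dt`, matching the (0, T] time-origin convention). No missing
#' rows are allowed; impute upstream.
#'
#' @param dt grid spacing, seconds
#' @param values m x D_y numeric matrix
#' @export
covariate_series <- function(dt, values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar", call. = FALSE)
  if (anyNA(values)) stop("covariate values contain NA", call. = FALSE)
  structure(list(dt = as.numeric(dt), values = values), class = "covariate_series")
}

#' @export
print.covariate_series <- function(x, ...) {
  cat(sprintf("<covariate_series: %d steps x %d dims, dt = %g s>\n",
              nrow(x$values), ncol(x$values), x$dt))
  invisible(x)
}

#' Covariate at event times by nearest-neighbor interpolation
#'
#' Row i is the covariate value at the grid index minimizing `|t_i - j dt|`;
#' exact midpoints resolve to the *later* grid point. Times must lie within
#' `(0, m dt]`.
#'
#' @param cov a [covariate_series()]
#' @param times numeric vector of query times
#' @return length(times) x D_y matrix
#' @export
state_at_spikes <- function(cov, times) {
  m <- nrow(cov$values)
  if (length(times) && (any(times <= 0) | any(times > m * cov$dt + 1e-9)))
    stop("query times outside the covariate grid span (0, m*dt]", call. = FALSE)
  # nearest j of t/dt with half-up rounding = floor(t/dt + 1/2 + tie nudge)
  j <- floor(times / cov$dt + 0.5 + 1e-9)
  j <- pmin(pmax(j, 1L), m)
  cov$values[j, , drop = FALSE]
}

#' Bin events and covariates onto a common grid
#'
#' Splits `(0, R * dt_bin]` into R left-open, right-closed bins; an event at
#' time t joins bin r iff `t` lies in `((r-1) dt_bin, r dt_bin]`. The bin
#' covariate `y_r` is the covariate at the bin's right edge (decimated when
#' `dt_bin` is a multiple of the covariate grid spacing).
#'
#' @param seq a [marked_events()]
#' @param cov a [covariate_series()]
#' @param dt_bin bin width, seconds; must equal `cov$dt` or an integer
#'   multiple of it
#' @return object of class `binned_dataset` with fields `dt_bin`, `R`, `y`
#'   (R x D_y), `mark_sets` (list of R matrices, n_r x D_k), `counts`
#' @export
bin_events <- function(seq, cov, dt_bin) {
  if (!is.numeric(dt_bin) || length(dt_bin) != 1L || dt_bin <= 0)
    stop("dt_bin must be a positive scalar", call. = FALSE)
  ratio <- dt_bin / cov$dt
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1)
    stop("dt_bin must equal cov$dt or a positive integer multiple of it",
         call. = FALSE)
  ratio <- as.integer(round(ratio))
  m <- nrow(cov$values)
  R <- m %/% ratio
  if (R < 1L) stop("covariate series shorter than one bin", call. = FALSE)
  Tgrid <- R * dt_bin
  if (length(seq$times) && any(seq$times > Tgrid + 1e-9))
    stop(sprintf("event at t = %g beyond the binned span R*dt_bin = %g",
                 max(seq$times), Tgrid), call. = FALSE)
  # right-edge alignment: y_r is the covariate at grid index r * ratio
  y <- cov$values[seq_len(R) * ratio, , drop = FALSE]
  idx <- ceiling(seq$times / dt_bin - 1e-12)
  idx <- pmin(pmax(idx, 1L), R)
  mark_sets <- vector("list", R)
  counts <- integer(R)
  Dk <- ncol(seq$marks)
  for (r in seq_len(R)) mark_sets[[r]] <- matrix(0, 0L, Dk)
  if (length(idx)) {
    split_idx <- split(seq_along(idx), idx)
    for (key in names(split_idx)) {
      r <- as.integer(key)
      mark_sets[[r]] <- seq$marks[split_idx[[key]], , drop = FALSE]
      counts[r] <- length(split_idx[[key]])
    }
  }
  structure(list(dt_bin = dt_bin, R = R, y = y, mark_sets = mark_sets,
                 counts = counts),
            class = "binned_dataset")
}

#' @export
print.binned_dataset <- function(x, ...) {
  cat(sprintf("<binned_dataset: R = %d bins of %g s, %d spikes, D_y = %d>\n",
              x$R, x$dt_bin, sum(x$counts), ncol(x$y)))
  invisible(x)
}

#' Restrict a binned dataset to a contiguous range of bins
#' @param data a `binned_dataset`
#' @param bins integer vector of consecutive bin indices
#' @export
bin_subset <- function(data, bins) {
  stopifnot(all(diff(bins) == 1L), min(bins) >= 1L, max(bins) <= data$R)
  structure(list(dt_bin = data$dt_bin, R = length(bins),
                 y = data$y[bins, , drop = FALSE],
                 mark_sets = data$mark_sets[bins],
                 counts = data$counts[bins]),
            class = "binned_dataset")
}

## ---- dataset IO ----

#' Save and load clusterless datasets
#'
#' The on-disk layout mirrors a hierarchical key structure: `spikes/<probe>/times`
#' (float64, length n), `spikes/<probe>/marks` (n x D_k), `covariate/dt`,
#' `covariate/values` (m x D_y) and `meta/duration_T`, serialized as one RDS
#' file so a save/load round trip is bit exact for float64 payloads. Loading
#' validates every key and array shape and names the missing key on failure.
#'
#' @param sequences a single [marked_events()] or a named list of them (one per
#'   probe)
#' @param cov a [covariate_series()]
#' @param path file path (conventionally `.rds`)
#' @return `save_dataset` returns `path` invisibly; `load_dataset` returns
#'   `list(sequences, covariate)`
#' @export
save_dataset <- function(sequences, cov, path) {
  if (inherits(sequences, "marked_events")) sequences <- list(probe1 = sequences)
  stopifnot(length(sequences) >= 1L, inherits(cov, "covariate_series"))
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    names(sequences) <- paste0("probe", seq_along(sequences))
  Tdur <- sequences[[1]]$duration_T
  payload <- list(
    spikes = lapply(sequences, function(s) list(times = s$times, marks = s$marks)),
    covariate = list(dt = cov$dt, values = cov$values),
    meta = list(duration_T = Tdur)
  )
  saveRDS(payload, path, version = 3L)
  invisible(path)
}

require_key <- function(x, keys) {
  node <- x
  for (i in seq_along(keys)) {
    if (!is.list(node) || is.null(node[[keys[i]]]))
      stop(sprintf("dataset file is missing key /%s", paste(keys[seq_len(i)], collapse = "/")),
           call. = FALSE)
    node <- node[[keys[i]]]
  }
  node
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  payload <- readRDS(path)
  spikes <- require_key(payload, "spikes")
  dt <- require_key(payload, c("covariate", "dt"))
  values <- require_key(payload, c("covariate", "values"))
  Tdur <- require_key(payload, c("meta", "duration_T"))
  if (!length(spikes)) stop("dataset file has no probes under /spikes", call. = FALSE)
  sequences <- lapply(names(spikes), function(pr) {
    times <- require_key(payload, c("spikes", pr, "times"))
    marks <- require_key(payload, c("spikes", pr, "marks"))
    if (length(times) != nrow(as.matrix(marks)))
      stop(sprintf("shape mismatch in /spikes/%s: %d times vs %d mark rows",
                   pr, length(times), nrow(as.matrix(marks))), call. = FALSE)
    marked_events(times, marks, duration_T = Tdur, probe_id = pr,
                  jitter_ties = FALSE)
  })
  names(sequences) <- names(spikes)
  list(sequences = sequences, covariate = covariate_series(dt, values))
}
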
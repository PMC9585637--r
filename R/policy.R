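#' Scan-line schedule
#'
#' The set of raster rows the stage may scan, with per-line visit tracking
#' for the segment-linewise mode.
#'
#' @param line_rows ordered, duplicate-free row indices (1-based) eligible
#'   for scanning; default all `n_rows` rows.
#' @param n_rows grid row count, used when `line_rows` is `NULL`.
#' @param visited_once_only if `TRUE` each line can be selected at most once
#'   (physical rasters do not cheaply revisit lines); if `FALSE` a line stays
#'   eligible while it has unmeasured pixels (useful in simulation).
#' @return A `line_schedule`.
#' @export
line_schedule <- function(n_rows = NULL, line_rows = NULL, visited_once_only = TRUE) {
  if (is.null(line_rows)) {
    if (is.null(n_rows)) abort("give `n_rows` or `line_rows`")
    line_rows <- seq_len(n_rows)
  }
  line_rows <- as.integer(line_rows)
  if (anyDuplicated(line_rows) || any(line_rows < 1)) {
    abort("`line_rows` must be positive and duplicate-free")
  }
  structure(
    list(line_rows = line_rows,
         visited = setNames(rep(FALSE, length(line_rows)), line_rows),
         visited_once_only = isTRUE(visited_once_only)),
    class = "line_schedule"
  )
}

#' Pointwise initialisation: 1% random pixels
#'
#' Random 1% of pixels in the imaging region (at least one pixel), drawn via
#' [random_mask()]. ERD cannot be produced without information, so every run
#' starts from this seed set.
#'
#' @param shape integer `c(N, M)`.
#' @param seed integer seed.
#' @return tibble of `row`, `col`.
#' @export
init_pointwise <- function(shape, seed = 1L) {
  random_mask(shape, 0.01, seed = seed)
}

#' Linewise initialisation: three complete lines
#'
#' Full scan lines at 25%, 50% and 70% of the sample height: scheduled-line
#' positions `round(p * (L - 1)) + 1` for `p` in `{0.25, 0.5, 0.7}` over the
#' `L` scheduled lines, duplicates collapsed.
#'
#' @param schedule a [line_schedule()] with at least three lines.
#' @param n_cols number of pixels per line.
#' @return tibble of `row`, `col` covering the selected full rows.
#' @export
init_linewise <- function(schedule, n_cols) {
  stopifnot(inherits(schedule, "line_schedule"))
  L <- length(schedule$line_rows)
  if (L < 3) abort("linewise initialisation needs at least 3 scheduled lines")
  pos <- unique(as.integer(round(c(0.25, 0.50, 0.70) * (L - 1)) + 1))
  rows <- schedule$line_rows[pos]
  tibble(row = rep(rows, each = n_cols), col = rep(seq_len(n_cols), length(rows)))
}

#' Pointwise selection: the unmeasured ERD argmax
#'
#' Selects the single unmeasured pixel with the highest ERD; ties are broken
#' by the lowest `(row, col)` in lexicographic order for determinism.
#'
#' @param erd `N x M` ERD matrix.
#' @param state the current `measurement_state`.
#' @return one-row tibble of `row`, `col`, or `NULL` once every pixel is
#'   measured (completion).
#' @export
select_pointwise <- function(erd, state) {
  stopifnot(inherits(state, "measurement_state"))
  erd <- as.matrix(erd)
  if (!identical(dim(erd), as.integer(state$shape))) abort("ERD shape mismatch")
  un <- which(!state$measured)
  if (length(un) == 0) return(NULL)
  vals <- erd[un]
  cand <- un[vals == max(vals)]
  rc <- px_rowcol(cand, state$shape[1])
  rc[order(rc$row, rc$col)[1], ]
}

#' Otsu threshold by exhaustive between-class-variance maximisation
#'
#' Separates high- from low-priority ERD values on a scan line. The
#' threshold maximises the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over all splits between consecutive distinct
#' sorted values and is placed at the midpoint of the optimal gap (lowest
#' such split on ties), which is exact and deterministic for the short
#' vectors a scan line produces.
#'
#' @param values numeric vector of >= 2 nonnegative values.
#' @return threshold value, or `NA_real_` when all values are equal (the
#'   degenerate signal; callers then select every candidate).
#' @export
otsu_threshold <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) abort("need at least 2 values")
  if (any(!is.finite(values))) abort("values must be finite")
  v <- sort(values)
  n <- length(v)
  if (v[1] == v[n]) return(NA_real_)
  cs <- cumsum(v)
  k <- seq_len(n - 1)
  w0 <- k / n
  mu0 <- cs[k] / k
  mu1 <- (cs[n] - cs[k]) / (n - k)
  sb <- w0 * (1 - w0) * (mu0 - mu1)^2
  sb[v[k] == v[k + 1]] <- -Inf  # a split inside a tie is not a threshold
  kbest <- which.max(sb)
  (v[kbest] + v[kbest + 1]) / 2
}

#' Segment-linewise selection
#'
#' Picks the eligible scan line with the maximal sum of ERD over its
#' unmeasured pixels (ties to the lowest row), then Otsu-thresholds that
#' line's unmeasured ERD values to obtain the pixels to measure. If no pixel
#' exceeds the threshold, the single max-ERD pixel is returned; if the
#' threshold is degenerate (all values equal), all unmeasured pixels on the
#' row are returned.
#'
#' @param erd `N x M` ERD matrix.
#' @param state the current `measurement_state`.
#' @param schedule a [line_schedule()]; eligibility honours
#'   `visited_once_only` and requires >= 1 unmeasured pixel on the line.
#' @return `list(row =, pixels = tibble(row, col))`, or `NULL` when no
#'   eligible line remains (completion).
#' @export
select_linewise_segment <- function(erd, state, schedule) {
  stopifnot(inherits(state, "measurement_state"), inherits(schedule, "line_schedule"))
  erd <- as.matrix(erd)
  if (!identical(dim(erd), as.integer(state$shape))) abort("ERD shape mismatch")
  rows <- schedule$line_rows
  eligible <- rows[!(schedule$visited_once_only & schedule$visited)]
  eligible <- eligible[vapply(eligible, function(r) any(!state$measured[r, ]), logical(1))]
  if (length(eligible) == 0) return(NULL)
  sums <- vapply(eligible, function(r) {
    un <- !state$measured[r, ]
    sum(erd[r, un])
  }, numeric(1))
  row <- eligible[order(-sums, eligible)[1]]
  un_cols <- which(!state$measured[row, ])
  vals <- erd[row, un_cols]
  if (length(vals) == 1) {
    sel_cols <- un_cols
  } else {
    thr <- otsu_threshold(vals)
    if (is.na(thr)) {
      sel_cols <- un_cols               # degenerate: take the whole remainder
    } else {
      sel_cols <- un_cols[vals > thr]
      if (length(sel_cols) == 0) {
        sel_cols <- un_cols[order(-vals, un_cols)[1]]
      }
    }
  }
  list(row = row, pixels = tibble(row = rep(row, length(sel_cols)), col = sel_cols))
}

#' Mark a scheduled line as visited
#'
#' @param schedule a [line_schedule()].
#' @param row the row just scanned.
#' @return updated schedule.
#' @export
mark_visited <- function(schedule, row) {
  i <- match(row, schedule$line_rows)
  if (is.na(i)) abort("row is not on the schedule")
  schedule$visited[i] <- TRUE
  schedule
}

#' Stopping rule
#'
#' @param state the current `measurement_state`.
#' @param criteria list with at least one of `max_density` (stop once the
#'   sampling density reaches it) and `max_iterations`.
#' @param iterations number of selection iterations completed so far.
#' @return `TRUE` when any active condition is met.
#' @export
check_stop <- function(state, criteria, iterations = NULL) {
  if (is.null(criteria$max_density) && is.null(criteria$max_iterations)) {
    abort("`criteria` needs `max_density` and/or `max_iterations`")
  }
  if (is.null(iterations)) {
    iterations <- if (nrow(state$order)) max(state$order$iteration) else 0L
  }
  (!is.null(criteria$max_density) && sampling_density(state) >= criteria$max_density) ||
    (!is.null(criteria$max_iterations) && iterations >= criteria$max_iterations)
}
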
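#' Generate a block-design motor-imagery paradigm
#'
#' Builds the timing structure of a block-design run: an initial rest
#' period, then `n_blocks` task blocks whose conditions are a seeded random
#' (balanced) draw from `conditions`, each followed by a rest period. This
#' mirrors the usual real-time motor-imagery protocol of 10 s task blocks
#' separated by 20 s of rest at a TR of 2 s.
#'
#' @param tr_seconds repetition time in seconds (volume acquisition interval).
#' @param block_duration_s duration of each task block in seconds; must be a
#'   positive multiple of `tr_seconds`.
#' @param rest_duration_s duration of each rest period in seconds; must be a
#'   positive multiple of `tr_seconds`.
#' @param conditions character vector of task condition labels (e.g.
#'   `c("MIL", "MIR")`); `"rest"` is reserved.
#' @param n_blocks number of task blocks (>= 1).
#' @param seed integer seed controlling the condition order.
#' @return An object of class `paradigm`: a list with `tr_seconds`, `blocks`
#'   (data frame with `condition`, `onset`, `duration`, including rest
#'   periods), `total_duration_s` and `n_volumes`.
#' @examples
#' p <- generate_paradigm(2, 10, 20, c("MIL", "MIR"), n_blocks = 4, seed = 1)
#' p$total_duration_s  # 20 + 4 * (10 + 20) = 140
#' table(condition_labels(p))
#' @export
generate_paradigm <- function(tr_seconds, block_duration_s, rest_duration_s,
                              conditions, n_blocks, seed = 1L) {
  stopifnot_scalar_number(tr_seconds, "tr_seconds", positive = TRUE)
  stopifnot_scalar_number(block_duration_s, "block_duration_s", positive = TRUE)
  stopifnot_scalar_number(rest_duration_s, "rest_duration_s", positive = TRUE)
  if (!is.numeric(n_blocks) || length(n_blocks) != 1L || n_blocks < 1) {
    stop("`n_blocks` must be at least 1: an empty design has no task blocks",
         call. = FALSE)
  }
  n_blocks <- as.integer(n_blocks)
  if (!is_multiple_of(block_duration_s, tr_seconds)) {
    stop(sprintf("block_duration_s (%g s) is not a multiple of the TR (%g s)",
                 block_duration_s, tr_seconds), call. = FALSE)
  }
  if (!is_multiple_of(rest_duration_s, tr_seconds)) {
    stop(sprintf("rest_duration_s (%g s) is not a multiple of the TR (%g s)",
                 rest_duration_s, tr_seconds), call. = FALSE)
  }
  conditions <- as.character(conditions)
  if (length(conditions) < 1L || anyDuplicated(conditions) ||
      "rest" %in% conditions) {
    stop("`conditions` must be distinct task labels not including \"rest\"",
         call. = FALSE)
  }

  # balanced random order: every condition appears floor(n/k) or ceil(n/k)
  # times, permuted under the seed (subjects are cued a shuffled, roughly
  # balanced sequence rather than an i.i.d. draw)
  order <- with_seed(seed, {
    base <- rep(conditions, length.out = n_blocks)
    sample(base, n_blocks)
  })

  onset <- 0
  rows <- vector("list", 2L * n_blocks + 1L)
  rows[[1L]] <- data.frame(condition = "rest", onset = 0,
                           duration = rest_duration_s)
  onset <- rest_duration_s
  for (b in seq_len(n_blocks)) {
    rows[[2L * b]] <- data.frame(condition = order[b], onset = onset,
                                 duration = block_duration_s)
    onset <- onset + block_duration_s
    rows[[2L * b + 1L]] <- data.frame(condition = "rest", onset = onset,
                                      duration = rest_duration_s)
    onset <- onset + rest_duration_s
  }
  blocks <- do.call(rbind, rows)
  structure(
    list(tr_seconds = tr_seconds,
         blocks = blocks,
         total_duration_s = onset,
         n_volumes = as.integer(round(onset / tr_seconds))),
    class = "paradigm"
  )
}

#' Per-volume condition labels of a paradigm
#'
#' @param paradigm a [generate_paradigm()] object.
#' @return Character vector of length `paradigm$n_volumes`, the condition
#'   active at each volume acquisition (volume `t` covers
#'   `[(t-1)*TR, t*TR)`).
#' @export
condition_labels <- function(paradigm) {
  stopifnot(inherits(paradigm, "paradigm"))
  tr <- paradigm$tr_seconds
  labels <- rep("rest", paradigm$n_volumes)
  for (i in seq_len(nrow(paradigm$blocks))) {
    b <- paradigm$blocks[i, ]
    first <- as.integer(round(b$onset / tr)) + 1L
    last <- as.integer(round((b$onset + b$duration) / tr))
    labels[first:last] <- b$condition
  }
  labels
}

#' @export
print.paradigm <- function(x, ...) {
  task <- x$blocks[x$blocks$condition != "rest", ]
  cat(sprintf("Block paradigm: %d task blocks (%s), TR = %g s, %g s total (%d volumes)\n",
              nrow(task), paste(unique(task$condition), collapse = "/"),
              x$tr_seconds, x$total_duration_s, x$n_volumes))
  invisible(x)
}

#' Write / read a paradigm as a BIDS-style events table
#'
#' Task blocks are written as rows of a tab-separated table with columns
#' `onset`, `duration`, `trial_type` (seconds). Rest is implicit: on reading,
#' any uncovered time is labeled `"rest"`.
#'
#' @param paradigm a `paradigm` object.
#' @param path output TSV path.
#' @return `write_events` returns `path` invisibly; `read_events`
#'   reconstructs a `paradigm` (rest gaps restored) from the file.
#' @export
write_events <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "paradigm"))
  task <- paradigm$blocks[paradigm$blocks$condition != "rest", ]
  df <- data.frame(onset = task$onset, duration = task$duration,
                   trial_type = task$condition)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param tr_seconds repetition time of the run the events belong to.
#' @param total_duration_s full run duration; defaults to the end of the
#'   last event.
#' @export
read_events <- function(path, tr_seconds, total_duration_s = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df))) {
    stop("events file must have columns onset, duration, trial_type",
         call. = FALSE)
  }
  df <- df[order(df$onset), ]
  if (is.null(total_duration_s)) {
    total_duration_s <- max(df$onset + df$duration)
  }
  rows <- list()
  cursor <- 0
  for (i in seq_len(nrow(df))) {
    if (df$onset[i] > cursor) {
      rows[[length(rows) + 1L]] <- data.frame(condition = "rest",
                                              onset = cursor,
                                              duration = df$onset[i] - cursor)
    }
    rows[[length(rows) + 1L]] <- data.frame(condition = df$trial_type[i],
                                            onset = df$onset[i],
                                            duration = df$duration[i])
    cursor <- df$onset[i] + df$duration[i]
  }
  if (total_duration_s > cursor) {
    rows[[length(rows) + 1L]] <- data.frame(condition = "rest", onset = cursor,
                                            duration = total_duration_s - cursor)
  }
  blocks <- do.call(rbind, rows)
  structure(
    list(tr_seconds = tr_seconds, blocks = blocks,
         total_duration_s = total_duration_s,
         n_volumes = as.integer(round(total_duration_s / tr_seconds))),
    class = "paradigm"
  )
}
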
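#' Experiment block schedule
#'
#' The temporal skeleton of a recording session: an ordered set of rest/task
#' blocks split into a pre- and post-injection phase, anchored to an absolute
#' injection time on the recording clock. On the injection day (day 0) the
#' protocol is a baseline rest and task block followed by 3 rest and 2 task
#' blocks post-injection; follow-up days (1, 2, 6) carry post-phase blocks
#' only.
#'
#' @param subject_id Subject identifier (character scalar).
#' @param drug One of `"saline"`, `"psi_0.3"`, `"psi_1.0"` (vehicle, 0.3 and
#'   1 mg/kg psilocybin).
#' @param injection_time_s Injection time, seconds on the recording clock.
#' @param day Integer day relative to injection: 0, 1, 2 or 6.
#' @param blocks data.frame with columns `kind` ("rest"/"task"), `phase`
#'   ("pre"/"post"), `t_start`, `t_end` (seconds, half-open `[t_start, t_end)`).
#' @return A `block_schedule` object.
#' @export
#' @examples
#' sch <- standard_schedule("rat1", "psi_0.3", block_length_s = 60)
#' sch$blocks
block_schedule <- function(subject_id, drug, injection_time_s, day, blocks) {
  drug <- match.arg(drug, DRUGS)
  blocks <- as.data.frame(blocks)
  need <- c("kind", "phase", "t_start", "t_end")
  if (!all(need %in% names(blocks)))
    pfc_abort("blocks must have columns kind, phase, t_start, t_end",
              "pfc_validation_error")
  if (!all(blocks$kind %in% c("rest", "task")))
    pfc_abort("block kind must be 'rest' or 'task'", "pfc_validation_error")
  if (!all(blocks$phase %in% c("pre", "post")))
    pfc_abort("block phase must be 'pre' or 'post'", "pfc_validation_error")
  if (any(blocks$t_end <= blocks$t_start))
    pfc_abort("block durations must be positive", "pfc_validation_error")
  o <- order(blocks$t_start)
  if (!identical(o, seq_len(nrow(blocks))))
    pfc_abort("blocks must be time-ordered", "pfc_validation_error")
  if (nrow(blocks) > 1 &&
      any(blocks$t_start[-1] < blocks$t_end[-nrow(blocks)]))
    pfc_abort("blocks must be non-overlapping", "pfc_validation_error")
  if (!day %in% c(0L, 1L, 2L, 6L))
    pfc_abort("day must be one of 0, 1, 2, 6", "pfc_validation_error")
  if (day == 0) {
    post <- blocks[blocks$phase == "post", , drop = FALSE]
    if (any(post$t_start < injection_time_s))
      pfc_abort("post blocks must start at or after the injection time on day 0",
                "pfc_validation_error")
    combos <- unique(blocks[, c("kind", "phase")])
    want <- expand.grid(kind = c("rest", "task"), phase = c("pre", "post"),
                        stringsAsFactors = FALSE)
    ok <- vapply(seq_len(nrow(want)), function(i)
      any(combos$kind == want$kind[i] & combos$phase == want$phase[i]), TRUE)
    if (!all(ok))
      pfc_abort("day-0 schedule needs at least one block per (kind, phase)",
                "pfc_validation_error")
  }
  structure(list(subject_id = as.character(subject_id), drug = drug,
                 injection_time_s = as.numeric(injection_time_s),
                 day = as.integer(day), blocks = blocks),
            class = "block_schedule")
}

#' Standard session schedule
#'
#' Builds the protocol schedule for one session. Day 0: rest + task baseline,
#' injection, then rest/task/rest/task/rest post blocks. Days 1/2/6: two rest
#' and two task blocks, all post-phase.
#'
#' @inheritParams block_schedule
#' @param block_length_s Block length in seconds (900 in the full protocol).
#' @param gap_s Gap between injection and the first post block, seconds.
#' @export
standard_schedule <- function(subject_id, drug, day = 0,
                              block_length_s = 900, gap_s = 0) {
  if (day == 0) {
    kinds <- c("rest", "task", "rest", "task", "rest", "task", "rest")
    phase <- c("pre", "pre", rep("post", 5))
  } else {
    kinds <- c("rest", "task", "rest", "task")
    phase <- rep("post", 4)
  }
  n_pre <- sum(phase == "pre")
  starts <- numeric(length(kinds))
  t <- 0
  for (i in seq_along(kinds)) {
    if (phase[i] == "post" && (i == 1 || phase[i - 1] == "pre")) t <- t + gap_s
    starts[i] <- t
    t <- t + block_length_s
  }
  inj <- if (day == 0) n_pre * block_length_s else 0
  block_schedule(subject_id, drug, inj, day,
                 data.frame(kind = kinds, phase = phase, t_start = starts,
                            t_end = starts + block_length_s))
}

#' Recording span covered by a schedule
#'
#' @param schedule A `block_schedule`.
#' @return End time of the last block, seconds.
#' @export
schedule_span <- function(schedule) max(schedule$blocks$t_end)

#' Select blocks of a schedule
#'
#' @param schedule A `block_schedule`.
#' @param phase,kind Optional filters ("pre"/"post", "rest"/"task").
#' @return data.frame of matching block rows.
#' @export
schedule_blocks <- function(schedule, phase = NULL, kind = NULL) {
  b <- schedule$blocks
  if (!is.null(phase)) b <- b[b$phase == phase, , drop = FALSE]
  if (!is.null(kind)) b <- b[b$kind == kind, , drop = FALSE]
  b
}

#' Read / write a block schedule as YAML
#'
#' @param path File path.
#' @return `read_schedule` returns a validated [block_schedule()];
#'   `write_schedule` returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("subject_id", "drug", "injection_time_s", "day", "blocks")
  if (!all(need %in% names(y)))
    pfc_abort(paste("schedule file missing fields:",
                    paste(setdiff(need, names(y)), collapse = ", ")),
              "pfc_format_error")
  blocks <- do.call(rbind, lapply(y$blocks, function(b)
    data.frame(kind = b$kind, phase = b$phase,
               t_start = as.numeric(b$t_start), t_end = as.numeric(b$t_end))))
  block_schedule(y$subject_id, y$drug, y$injection_time_s, y$day, blocks)
}

#' @param schedule A `block_schedule`.
#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "block_schedule"))
  b <- schedule$blocks
  yaml::write_yaml(list(
    subject_id = schedule$subject_id, drug = schedule$drug,
    injection_time_s = schedule$injection_time_s, day = schedule$day,
    blocks = lapply(seq_len(nrow(b)), function(i)
      list(kind = b$kind[i], phase = b$phase[i],
           t_start = b$t_start[i], t_end = b$t_end[i]))), path)
  invisible(path)
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("<block_schedule> subject %s, %s, day %d, injection at %gs\n",
              x$subject_id, x$drug, x$day, x$injection_time_s))
  print(x$blocks)
  invisible(x)
}
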
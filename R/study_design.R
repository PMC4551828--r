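# Trial schedule construction for one session of the homonym relatedness
# judgment task: 42 homonyms presented twice (once per block, each meaning
# primed once), every homonym trial immediately preceded by its prime trial,
# embedded among associated fillers and two kinds of catch trials.

#' Default session design configuration
#'
#' Returns the per-session trial counts of the experiment: 42 homonyms, each
#' presented once per block across 2 blocks (84 homonym trials, each preceded
#' by a prime trial), 84 associated filler trials, 84 homonym catch trials
#' (homonym plus unrelated word), and 168 filler catch trials (two unrelated
#' words) -- 504 trials in total, 252 related and 252 unrelated word pairs.
#'
#' @param n_homonyms Number of distinct homonyms (default 42).
#' @param n_filler_assoc Number of associated filler trials (default 84).
#' @param n_homonym_catch Number of homonym catch trials (default 84).
#' @param n_filler_catch Number of filler catch trials (default 168).
#' @param n_blocks Number of blocks (default 2; each homonym appears once per
#'   block with the other meaning primed in the second block).
#' @return A list of class `design_config`.
#' @export
#' @examples
#' d <- default_design()
#' d$n_homonym_trials  # 84
default_design <- function(n_homonyms = 42L,
                           n_filler_assoc = 84L,
                           n_homonym_catch = 84L,
                           n_filler_catch = 168L,
                           n_blocks = 2L) {
  cfg <- list(
    n_homonyms = as.integer(n_homonyms),
    n_filler_assoc = as.integer(n_filler_assoc),
    n_homonym_catch = as.integer(n_homonym_catch),
    n_filler_catch = as.integer(n_filler_catch),
    n_blocks = as.integer(n_blocks)
  )
  cfg$n_homonym_trials <- cfg$n_homonyms * cfg$n_blocks
  cfg$n_prime_trials <- cfg$n_homonym_trials
  class(cfg) <- "design_config"
  validate_design(cfg)
  cfg
}

validate_design <- function(cfg) {
  counts <- c(cfg$n_homonyms, cfg$n_filler_assoc, cfg$n_homonym_catch,
              cfg$n_filler_catch)
  if (any(counts < 0) || cfg$n_blocks < 1) {
    stop_config("design counts must be non-negative and n_blocks >= 1")
  }
  if (all(counts == 0)) return(invisible(cfg))
  if (cfg$n_blocks != 2L) {
    stop_config("the priming design requires exactly 2 blocks (each meaning primed once); got %d",
                cfg$n_blocks)
  }
  if (cfg$n_homonyms %% 2L != 0L) {
    stop_config("n_homonyms must be even to balance the 2x2 priming x association cells; got %d",
                cfg$n_homonyms)
  }
  for (nm in c("n_filler_assoc", "n_homonym_catch", "n_filler_catch")) {
    if (cfg[[nm]] %% cfg$n_blocks != 0L) {
      stop_config("%s (%d) must be divisible by n_blocks (%d)",
                  nm, cfg[[nm]], cfg$n_blocks)
    }
  }
  invisible(cfg)
}

other_meaning <- function(m) ifelse(m == "A", "B", "A")

#' Build the trial schedule of one session
#'
#' Constructs a complete, ordered session: each homonym appears once per
#' block with each of its two meanings primed exactly once across blocks;
#' priming (does the associate's meaning match the primed meaning?) and
#' association strength (strong/weak) are crossed so that each factor level
#' receives half of the homonym trials (42 primed, 42 unprimed, 42 strong,
#' 42 weak under the default design). Order is uniformly random given `seed`
#' except that every homonym trial is immediately preceded by its prime
#' trial: each prime+homonym pair is shuffled as a single unit among the
#' filler and catch trials of its block.
#'
#' @param participant_id Integer participant identifier. The side of the
#'   "related" response box is counterbalanced by participant parity (odd:
#'   left, even: right).
#' @param design A `design_config`, see [default_design()].
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return A data.frame of class `session_schedule` with columns
#'   `participant`, `position`, `block`, `trial_type`, `homonym_id`,
#'   `primed_meaning`, `target_meaning`, `association`, `repetition`, and
#'   attributes `response_side_related` and `seed`.
#' @export
#' @examples
#' sched <- build_session(1, default_design(), seed = 42)
#' table(sched$trial_type)
build_session <- function(participant_id, design = default_design(), seed = 1L) {
  validate_design(design)
  side <- if (as.integer(participant_id) %% 2L == 0L) "right" else "left"

  empty <- data.frame(
    participant = integer(0), position = integer(0), block = integer(0),
    trial_type = character(0), homonym_id = character(0),
    primed_meaning = character(0), target_meaning = character(0),
    association = character(0), repetition = character(0),
    stringsAsFactors = FALSE
  )
  if (design$n_homonyms == 0 && design$n_filler_assoc == 0 &&
      design$n_homonym_catch == 0 && design$n_filler_catch == 0) {
    return(as_schedule(empty, participant_id, side, seed))
  }

  nh <- design$n_homonyms
  hom_ids <- sprintf("h%02d", seq_len(nh))
  if (anyDuplicated(hom_ids)) stop_config("duplicate homonym_id")

  trials <- with_seed(seed, {
    # Which meaning each homonym has primed in block 1 (block 2: the other).
    primed_first <- sample(c("A", "B"), nh, replace = TRUE)

    # Complementary cell pairing keeps the 2x2 cells balanced at the session
    # level: half the homonyms contribute (primed,strong)+(unprimed,weak),
    # the other half (primed,weak)+(unprimed,strong); which member of the
    # pair falls in block 1 is random per homonym.
    grp <- sample(rep(c(1L, 2L), nh / 2L))
    cell_pairs <- list(
      `1` = list(c("primed", "strong"), c("unprimed", "weak")),
      `2` = list(c("primed", "weak"), c("unprimed", "strong"))
    )
    flip <- sample(c(TRUE, FALSE), nh, replace = TRUE)

    per_block <- vector("list", design$n_blocks)
    for (b in seq_len(design$n_blocks)) {
      pm <- if (b == 1L) primed_first else other_meaning(primed_first)
      cell <- t(vapply(seq_len(nh), function(i) {
        pair <- cell_pairs[[grp[i]]]
        if (xor(b == 2L, flip[i])) pair[[1]] else pair[[2]]
      }, character(2)))
      tm <- ifelse(cell[, 1] == "primed", pm, other_meaning(pm))
      n_single <- c(filler_assoc = design$n_filler_assoc,
                    homonym_catch = design$n_homonym_catch,
                    filler_catch = design$n_filler_catch) / design$n_blocks
      # each prime+homonym pair is one shuffling unit; every other trial its own
      bd <- data.frame(
        trial_type = c(rep(c("prime", "homonym"), each = nh),
                       rep(names(n_single), n_single)),
        homonym_id = c(hom_ids, hom_ids, rep(NA_character_, sum(n_single))),
        primed_meaning = c(pm, rep(NA_character_, nh + sum(n_single))),
        target_meaning = c(rep(NA_character_, nh), tm,
                           rep(NA_character_, sum(n_single))),
        association = c(rep(NA_character_, nh), cell[, 2],
                        rep(NA_character_, sum(n_single))),
        unit = c(seq_len(nh), seq_len(nh), nh + seq_len(sum(n_single))),
        within = c(rep(1L, nh), rep(2L, nh), rep(1L, sum(n_single))),
        stringsAsFactors = FALSE)
      perm <- sample.int(nh + sum(n_single))
      bd <- bd[order(match(bd$unit, perm), bd$within), ]
      bd$unit <- bd$within <- NULL
      bd$block <- b
      per_block[[b]] <- bd
    }
    do.call(rbind, per_block)
  })

  trials$position <- seq_len(nrow(trials))
  trials$participant <- as.integer(participant_id)
  # Repetition label: block order of the two presentations of each homonym.
  trials$repetition <- NA_character_
  is_hom <- trials$trial_type == "homonym"
  trials$repetition[is_hom] <- ifelse(trials$block[is_hom] == 1L, "first", "second")
  trials <- trials[, c("participant", "position", "block", "trial_type",
                       "homonym_id", "primed_meaning", "target_meaning",
                       "association", "repetition")]
  as_schedule(trials, participant_id, side, seed)
}

as_schedule <- function(df, participant_id, side, seed) {
  rownames(df) <- NULL
  attr(df, "participant_id") <- as.integer(participant_id)
  attr(df, "response_side_related") <- side
  attr(df, "seed") <- as.integer(seed)
  class(df) <- c("session_schedule", "data.frame")
  df
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("Session schedule: participant %d, %d trials, related side = %s, seed = %d\n",
              attr(x, "participant_id"), nrow(x),
              attr(x, "response_side_related"), attr(x, "seed")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Priming and association condition of a homonym trial
#'
#' A homonym trial is *primed* when the meaning its associate belongs to
#' equals the meaning activated by the immediately preceding prime trial,
#' and *unprimed* otherwise.
#'
#' @param schedule A `session_schedule`.
#' @param position Position (1-based) of a homonym trial in the schedule.
#' @return A list with elements `priming` (`"primed"`/`"unprimed"`) and
#'   `association` (`"strong"`/`"weak"`).
#' @export
condition_of <- function(schedule, position) {
  row <- schedule[schedule$position == position, , drop = FALSE]
  if (nrow(row) != 1L) stop("no trial at position ", position, call. = FALSE)
  if (row$trial_type != "homonym") {
    stop("condition_of() is defined for homonym trials only; trial at position ",
         position, " has type '", row$trial_type, "'", call. = FALSE)
  }
  prev <- schedule[schedule$position == position - 1L, , drop = FALSE]
  if (nrow(prev) != 1L || prev$trial_type != "prime" ||
      !identical(prev$homonym_id, row$homonym_id)) {
    stop("homonym trial at position ", position,
         " is not preceded by its prime trial", call. = FALSE)
  }
  list(
    priming = if (identical(row$target_meaning, prev$primed_meaning)) "primed" else "unprimed",
    association = row$association
  )
}

#' Condition table for all homonym trials of a schedule
#'
#' Vectorized companion of [condition_of()]: returns one row per homonym
#' trial with its derived priming condition and association strength.
#'
#' @param schedule A `session_schedule`.
#' @return A data.frame with columns `position`, `homonym_id`, `block`,
#'   `repetition`, `priming`, `association`.
#' @export
homonym_conditions <- function(schedule) {
  idx <- which(schedule$trial_type == "homonym")
  if (length(idx) == 0L) {
    return(data.frame(position = integer(0), homonym_id = character(0),
                      block = integer(0), repetition = character(0),
                      priming = character(0), association = character(0),
                      stringsAsFactors = FALSE))
  }
  prev <- match(schedule$position[idx] - 1L, schedule$position)
  bad <- is.na(prev) | schedule$trial_type[prev] != "prime" |
    schedule$homonym_id[prev] != schedule$homonym_id[idx]
  if (any(bad)) {
    stop("homonym trials without adjacent prime at positions: ",
         paste(schedule$position[idx][bad], collapse = ", "), call. = FALSE)
  }
  data.frame(
    position = schedule$position[idx],
    homonym_id = schedule$homonym_id[idx],
    block = schedule$block[idx],
    repetition = schedule$repetition[idx],
    priming = ifelse(schedule$target_meaning[idx] ==
                       schedule$primed_meaning[prev], "primed", "unprimed"),
    association = schedule$association[idx],
    stringsAsFactors = FALSE
  )
}

#' Write / read a schedule as a tab-separated table
#'
#' Deterministic column order; `NA` fields are written as empty strings.
#'
#' @param schedule A `session_schedule`.
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule` a
#'   `session_schedule` (side and seed recovered from the header comment).
#' @export
write_schedule <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# participant_id=%d response_side_related=%s seed=%d",
                     attr(schedule, "participant_id"),
                     attr(schedule, "response_side_related"),
                     attr(schedule, "seed")), con)
  utils::write.table(as.data.frame(schedule), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          na.strings = "", stringsAsFactors = FALSE,
                          colClasses = c(participant = "integer",
                                         position = "integer",
                                         block = "integer",
                                         trial_type = "character",
                                         homonym_id = "character",
                                         primed_meaning = "character",
                                         target_meaning = "character",
                                         association = "character",
                                         repetition = "character"))
  as_schedule(df, as.integer(vals[["participant_id"]]),
              vals[["response_side_related"]], as.integer(vals[["seed"]]))
}
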
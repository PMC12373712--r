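#' @importFrom rlang .data
NULL

# Trajectory segment durations (s), derived from the printed segment
# velocities: the dot covers the horizontal leg at the same speed as the
# pre-crossing vertical leg. Incongruent trials keep a fixed overall
# vertical duration regardless of the horizontal speed.
HORIZONTAL_DURATION <- c(fast = 0.250, slow = 0.450)
VERTICAL_DURATION_CONGRUENT <- c(fast = 0.250 + 0.150, slow = 0.450 + 0.266)
VERTICAL_DURATION_INCONGRUENT <- 0.716

DEFAULT_TR <- 2.0

# trials per run for each direction x velocity cell present in the run
TRIALS_PER_RUN_CELL <- c(visible = 30, occluded = 50)
# incongruent trials per run-cell in the low-predictability context
INCONGRUENT_PER_RUN_CELL <- c(visible = 9, occluded = 15)

# Poisson(lambda = 4) truncated to the integer support {2,...,6}
draw_iti <- function(n, lambda = 4) {
  out <- integer(0)
  while (length(out) < n) {
    k <- stats::rpois(2 * (n - length(out)) + 8, lambda)
    out <- c(out, k[k >= 2 & k <= 6])
  }
  out[seq_len(n)]
}

#' Generate an interception-paradigm experiment design
#'
#' Builds the per-trial event table of one context/phase session: four runs,
#' two with the up-fast/down-slow direction-velocity configuration and two
#' with up-slow/down-fast. Visible-phase runs hold 30 trials of each of the
#' two cells present in the run (240 trials over 4 runs); occluded-phase
#' runs hold 50 each (400 trials). In the low-predictability (LP) context
#' 30% of trials are incongruent -- the vertical leg lasts a fixed 0.716 s
#' instead of the velocity-congruent duration -- exactly counterbalanced
#' across the four direction x velocity cells (72/240 visible, 120/400
#' occluded). The high-predictability (HP) context has no incongruent
#' trials. Inter-trial intervals are integers drawn from a Poisson(4) law
#' conditioned on \[2, 6\] s; trial order is randomized per run.
#'
#' @param context `"HP"` or `"LP"`.
#' @param phase `"visible"` or `"occluded"`.
#' @param seed Integer seed; the design is a deterministic function of it.
#' @param tr Repetition time (s) used to size runs in volumes.
#' @param n_runs Number of runs (must be even so the two configurations
#'   balance; default 4).
#' @param trials_per_run_cell Trials per direction x velocity cell per run;
#'   `NULL` (default) uses the full-session values (30 visible, 50
#'   occluded). Override for desk-scale simulations.
#' @param incongruent_per_run_cell Incongruent trials per run-cell in the
#'   LP context; `NULL` derives it (the full-session 30%, or
#'   `round(0.3 * trials_per_run_cell)` for overridden sizes).
#' @return A tibble of class `ip_design`, one row per trial, with columns
#'   `run`, `trial`, `onset`, `duration`, `horizontal_duration`,
#'   `vertical_duration`, `direction`, `velocity`, `congruency`, `phase`,
#'   `context`, `condition`, and attributes `n_runs`, `tr`,
#'   `run_length_volumes`, `run_configuration`.
#' @export
#' @examples
#' d <- generate_design("LP", "visible", seed = 1)
#' nrow(d)                      # 240
#' sum(d$congruency == "incongruent") # 72
generate_design <- function(context = c("HP", "LP"),
                            phase = c("visible", "occluded"),
                            seed, tr = DEFAULT_TR, n_runs = 4L,
                            trials_per_run_cell = NULL,
                            incongruent_per_run_cell = NULL) {
  context <- match.arg(context)
  phase <- match.arg(phase)
  stopifnot(is.numeric(seed), length(seed) == 1, n_runs %% 2 == 0)

  n_cell <- trials_per_run_cell %||% TRIALS_PER_RUN_CELL[[phase]]
  n_incon <- if (context != "LP") {
    0L
  } else if (!is.null(incongruent_per_run_cell)) {
    incongruent_per_run_cell
  } else if (is.null(trials_per_run_cell)) {
    INCONGRUENT_PER_RUN_CELL[[phase]]
  } else {
    round(0.3 * n_cell)
  }
  stopifnot(n_incon <= n_cell)

  configs <- with_substream(seed, paste0("design/config/", context, "/", phase),
    sample(rep(c("up-fast/down-slow", "up-slow/down-fast"),
               each = n_runs / 2))
  )

  runs <- purrr::map(seq_len(n_runs), function(r) {
    cells <- if (configs[r] == "up-fast/down-slow") {
      list(c("up", "fast"), c("down", "slow"))
    } else {
      list(c("up", "slow"), c("down", "fast"))
    }
    trials <- purrr::map_dfr(cells, function(cell) {
      tibble::tibble(
        direction = cell[1],
        velocity = cell[2],
        congruency = rep(c("incongruent", "congruent"),
                         c(n_incon, n_cell - n_incon))
      )
    })
    with_substream(seed, paste0("design/order/", context, "/", phase, "/run", r), {
      trials <- trials[sample(nrow(trials)), ]
      itis <- draw_iti(nrow(trials))
      trials$horizontal_duration <- unname(HORIZONTAL_DURATION[trials$velocity])
      trials$vertical_duration <- unname(ifelse(
        trials$congruency == "incongruent",
        VERTICAL_DURATION_INCONGRUENT,
        VERTICAL_DURATION_CONGRUENT[trials$velocity]
      ))
      trials$duration <- trials$horizontal_duration + trials$vertical_duration
      trials$onset <- itis[1] + c(0, cumsum(trials$duration[-nrow(trials)] +
                                              itis[-1]))
      trials$run <- r
      trials$trial <- seq_len(nrow(trials))
      trials
    })
  })

  d <- dplyr::bind_rows(runs)
  d$phase <- phase
  d$context <- context
  d$condition <- paste(d$direction, d$velocity, d$congruency, sep = "_")
  d <- dplyr::select(
    d, "run", "trial", "onset", "duration", "horizontal_duration",
    "vertical_duration", "direction", "velocity", "congruency",
    "phase", "context", "condition"
  )
  run_len <- vapply(runs, function(r) {
    as.integer(ceiling((max(r$onset + r$duration) + 20) / tr))
  }, integer(1))
  structure(
    tibble::new_tibble(d, nrow = nrow(d), class = "ip_design"),
    n_runs = as.integer(n_runs), tr = tr, run_length_volumes = run_len,
    run_configuration = configs, seed = seed
  )
}

#' Write a design as BIDS-style events tables
#'
#' One TSV per run with columns `onset`, `duration`, `trial_type`
#' (direction_velocity_congruency), `run`, `phase`, `context`.
#'
#' @param design An [generate_design()] tibble.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return Invisibly, the written file paths.
#' @export
write_events_tsv <- function(design, dir, prefix = "events") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(sort(unique(design$run)), function(r) {
    ev <- design[design$run == r, ]
    out <- tibble::tibble(
      onset = ev$onset, duration = ev$duration, trial_type = ev$condition,
      run = ev$run, phase = ev$phase, context = ev$context
    )
    path <- file.path(dir, sprintf("%s_run-%02d.tsv", prefix, r))
    readr::write_tsv(out, path)
    path
  })
  invisible(paths)
}

#' Read BIDS-style events tables back into one event tibble
#'
#' @param paths Character vector of events TSV paths.
#' @return A tibble with the columns written by [write_events_tsv()].
#' @export
read_events_tsv <- function(paths) {
  purrr::map_dfr(paths, readr::read_tsv, show_col_types = FALSE)
}
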
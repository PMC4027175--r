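#' Piecewise-constant input protocol
#'
#' Ordered list of timed additions of DNA activator A (positive input) and
#' DNA inhibitor I (negative input; I is the perfect complement of A and
#' strips it off activated templates by toehold-mediated strand
#' displacement). The running total activator `u = [A_tot]` is the input of
#' every model variant.
#'
#' @param time event times (min, nondecreasing, `>= 0`).
#' @param species `"A"` or `"I"` per event.
#' @param amount added concentration per event (nM, strictly positive).
#' @param description free-text annotation.
#' @return object of class `iffl_schedule`: a data.frame with columns
#'   `time`, `species`, `amount`.
#' @examples
#' # doubling protocol: 10 nM at time 0, total doubled at 2, 3, 4, 5 h
#' sch <- input_schedule(time = c(0, 120, 180, 240, 300),
#'                       species = "A",
#'                       amount = c(10, 10, 20, 40, 80))
#' input_u(sch, 210)  # 40 nM
#' @export
input_schedule <- function(time = numeric(), species = character(),
                           amount = numeric(), description = "") {
  n <- max(length(time), length(species), length(amount))
  if (n > 0) {
    time <- rep_len(as.numeric(time), n)
    species <- rep_len(as.character(species), n)
    amount <- rep_len(as.numeric(amount), n)
  }
  if (any(is.na(time)) || any(time < 0))
    stop("input_schedule: event times must be nonnegative numbers")
  if (is.unsorted(time))
    stop("input_schedule: event times must be nondecreasing")
  if (!all(species %in% c("A", "I")))
    stop("input_schedule: species must be 'A' or 'I'")
  if (any(is.na(amount)) || any(amount <= 0))
    stop("input_schedule: amounts must be strictly positive")
  structure(data.frame(time = time, species = species, amount = amount,
                       stringsAsFactors = FALSE),
            description = description,
            class = c("iffl_schedule", "data.frame"))
}

#' Running total activator concentration
#'
#' Evaluates the input `u(t) = [A_tot]` implied by a schedule: cumulative A
#' additions up to and including `t`, reduced stoichiometrically by each I
#' addition (instantaneous neutralization, floored at zero). The floor is
#' applied event by event, so an excess of inhibitor cannot drive the input
#' negative nor "bank" negative input against later activator additions.
#'
#' @param schedule an [input_schedule()].
#' @param t query times (min, `>= 0`); may be a vector.
#' @return total activator concentration (nM) at each `t`.
#' @export
input_u <- function(schedule, t) {
  stopifnot(inherits(schedule, "iffl_schedule"))
  if (any(is.na(t)) || any(t < 0)) stop("input_u: negative or missing time")
  if (nrow(schedule) == 0L) return(rep(0, length(t)))
  delta <- ifelse(schedule$species == "A", schedule$amount, -schedule$amount)
  run <- 0
  level <- numeric(nrow(schedule))
  for (i in seq_along(delta)) {
    run <- max(0, run + delta[i])
    level[i] <- run
  }
  idx <- findInterval(t, schedule$time)
  ifelse(idx == 0L, 0, level[pmax(idx, 1L)])
}

# distinct event times in (0, t_end]; integration restarts at each
schedule_event_times <- function(schedule, t_end) {
  if (is.null(schedule) || nrow(schedule) == 0L) return(numeric())
  sort(unique(schedule$time[schedule$time > 0 & schedule$time < t_end]))
}

#' @export
print.iffl_schedule <- function(x, ...) {
  cat("IFFL input schedule (", nrow(x), " events)\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}
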
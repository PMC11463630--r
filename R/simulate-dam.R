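#' Configuration for synthetic DAM behavioral traces
#'
#' Each fly is a two-state (wake/sleep) Markov chain at 1-minute resolution.
#' `p_doze` is the per-minute wake-to-sleep transition probability, `p_wake`
#' the sleep-to-wake probability; both vary by genotype and day. Day 1 is the
#' fed day and day 2 the starved day, matching a 24 h on food / 24 h on agar
#' design. Wake minutes emit `Poisson(lambda_wake)` beam crossings, sleep
#' minutes emit 0.
#'
#' Default transition probabilities give a fed sleep fraction near 0.6
#' (p_doze 0.06, p_wake 0.04; mean sleep bout 25 min) and a starved fraction
#' near 0.35 (p_doze 0.03, p_wake 0.055), i.e. a 30-50% within-fly sleep
#' suppression — the range wild-type flies show after a day of starvation.
#'
#' @param n_flies_per_genotype Flies per genotype.
#' @param genotypes Character vector of genotype labels.
#' @param n_days Number of days (>= 2: fed then starved).
#' @param p_doze,p_wake Matrices genotypes x days (or single numbers /
#'   per-day vectors, recycled across genotypes).
#' @param lambda_wake Mean beam crossings per wake minute (> 0).
#' @param truncate_wake_zeros If `TRUE`, wake minutes emit at least one
#'   crossing (zero-truncated Poisson); used when downstream scoring must
#'   recover the latent state exactly.
#' @param seed Integer seed.
#' @return Object of class `behavior_config`.
#' @export
behavior_config <- function(n_flies_per_genotype = 16,
                            genotypes = "control",
                            n_days = 2,
                            p_doze = c(fed = 0.06, starved = 0.03),
                            p_wake = c(fed = 0.04, starved = 0.055),
                            lambda_wake = 2,
                            truncate_wake_zeros = FALSE,
                            seed = 1L) {
  if (n_days < 2) stop("n_days must be >= 2 (a fed day and a starved day)")
  ng <- length(genotypes)
  expand <- function(p) {
    if (is.matrix(p)) {
      stopifnot(nrow(p) == ng, ncol(p) == n_days)
      m <- p
    } else if (length(p) == 1) {
      m <- matrix(p, ng, n_days)
    } else {
      stopifnot(length(p) == n_days)
      m <- matrix(rep(p, each = ng), ng, n_days)
    }
    dimnames(m) <- list(genotypes, day_labels(n_days))
    m
  }
  p_doze <- expand(p_doze); p_wake <- expand(p_wake)
  stopifnot(all(p_doze >= 0 & p_doze <= 1), all(p_wake >= 0 & p_wake <= 1),
            lambda_wake > 0, n_flies_per_genotype >= 1)
  structure(list(
    n_flies_per_genotype = as.integer(n_flies_per_genotype),
    genotypes = genotypes,
    n_days = as.integer(n_days),
    minutes_per_day = 1440L,
    p_doze = p_doze, p_wake = p_wake,
    lambda_wake = lambda_wake,
    truncate_wake_zeros = isTRUE(truncate_wake_zeros),
    seed = as.integer(seed)
  ), class = "behavior_config")
}

day_labels <- function(n_days) {
  lab <- c("fed", "starved")
  if (n_days > 2) lab <- c(lab, paste0("day", 3:n_days))
  lab
}

#' Simulate DAM monitor data from two-state Markov sleep/wake chains
#'
#' Generates per-fly minute-resolution sleep/wake states and activity counts,
#' and optionally serializes them in the DAM monitor dialect (see
#' [write_dam()]). Flies start the first minute awake.
#'
#' @param config A [behavior_config()].
#' @param file Optional path; when given, a DAM monitor file is written
#'   (requires <= 32 flies).
#' @return List: `activity` (minutes x flies counts), `states` (logical
#'   minutes x flies, `TRUE` = sleep), `flies` (data.frame `fly_id`,
#'   `genotype`, `channel`), `day` (day label per minute), `file` (path or
#'   `NULL`).
#' @export
simulate_dam <- function(config, file = NULL) {
  stopifnot(inherits(config, "behavior_config"))
  nf <- config$n_flies_per_genotype * length(config$genotypes)
  if (!is.null(file) && nf > 32) stop("a DAM monitor file holds at most 32 channels")
  mins <- config$n_days * config$minutes_per_day
  day_of_min <- rep(seq_len(config$n_days), each = config$minutes_per_day)
  flies <- data.frame(
    fly_id = sprintf("fly%02d", seq_len(nf)),
    genotype = rep(config$genotypes, each = config$n_flies_per_genotype),
    channel = seq_len(nf),
    stringsAsFactors = FALSE
  )
  out <- with_seed(config$seed, {
    states <- matrix(FALSE, mins, nf)
    activity <- matrix(0L, mins, nf)
    for (f in seq_len(nf)) {
      g <- flies$genotype[f]
      asleep <- FALSE
      u <- runif(mins)
      st <- logical(mins)
      for (t in seq_len(mins)) {
        d <- day_of_min[t]
        if (asleep) {
          if (u[t] < config$p_wake[g, d]) asleep <- FALSE
        } else {
          if (u[t] < config$p_doze[g, d]) asleep <- TRUE
        }
        st[t] <- asleep
      }
      states[, f] <- st
      nwake <- sum(!st)
      a <- rpois(nwake, config$lambda_wake)
      if (config$truncate_wake_zeros) {
        while (any(a == 0)) a[a == 0] <- rpois(sum(a == 0), config$lambda_wake)
      }
      activity[!st, f] <- a
    }
    list(states = states, activity = activity)
  })
  colnames(out$states) <- colnames(out$activity) <- flies$fly_id
  if (!is.null(file)) write_dam(out$activity, file)
  list(activity = out$activity, states = out$states, flies = flies,
       day = day_labels(config$n_days)[day_of_min],
       file = if (is.null(file)) NULL else file)
}
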
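#' Write activity counts as a DAM monitor file
#'
#' Serializes a minutes x channels matrix in the TriKinetics monitor dialect:
#' tab-delimited, one line per minute, fields = reading index, date
#' (`DD Mon YY`, C locale), time (`HH:MM:SS`), status code 1, six zero padding
#' fields (through field 10), then 32 integer channel counts (fields 11-42).
#' Channels beyond `ncol(activity)` are written as 0.
#'
#' @param activity Integer matrix, minutes x channels (<= 32 channels).
#' @param file Output path.
#' @param start POSIXct timestamp of the first minute.
#' @return `file`, invisibly.
#' @export
write_dam <- function(activity, file,
                      start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  stopifnot(is.matrix(activity), ncol(activity) <= 32, all(activity >= 0))
  n <- nrow(activity)
  full <- matrix(0L, n, 32)
  full[, seq_len(ncol(activity))] <- activity
  tt <- start + 60 * (seq_len(n) - 1)
  old_lc <- Sys.getlocale("LC_TIME")
  on.exit(Sys.setlocale("LC_TIME", old_lc), add = TRUE)
  Sys.setlocale("LC_TIME", "C")
  lines <- paste(seq_len(n),
                 format(tt, "%d %b %y", tz = "UTC"),
                 format(tt, "%H:%M:%S", tz = "UTC"),
                 1L, 0L, 0L, 0L, 0L, 0L, 0L,
                 apply(full, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, file)
  invisible(file)
}

#' Read a DAM monitor file
#'
#' Parses the dialect written by [write_dam()] (42 tab-separated fields per
#' line; fields 11-42 are the 32 channel counts). Lines with the wrong field
#' count, non-integer counts, or timestamps that do not advance by exactly one
#' minute are rejected with their line numbers.
#'
#' @param file Path to the monitor file.
#' @return List: `activity` (minutes x 32 integer matrix, columns `ch01` ...
#'   `ch32`), `time` (POSIXct per minute).
#' @export
read_dam <- function(file) {
  lines <- readLines(file)
  if (length(lines) == 0) stop("empty DAM file: ", file)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 42)
  if (length(bad)) {
    stop("malformed DAM line(s) (expected 42 fields): ",
         paste(head(bad, 5), collapse = ", "))
  }
  m <- do.call(rbind, parts)
  old_lc <- Sys.getlocale("LC_TIME")
  on.exit(Sys.setlocale("LC_TIME", old_lc), add = TRUE)
  Sys.setlocale("LC_TIME", "C")
  tt <- as.POSIXct(paste(m[, 2], m[, 3]), format = "%d %b %y %H:%M:%S",
                   tz = "UTC")
  if (any(is.na(tt))) {
    stop("unparseable timestamp at line(s): ",
         paste(head(which(is.na(tt)), 5), collapse = ", "))
  }
  if (length(tt) > 1) {
    step <- diff(as.numeric(tt))
    gap <- which(step != 60)
    if (length(gap)) {
      stop("non-contiguous timestamps (gap or reversal) after line(s): ",
           paste(head(gap, 5), collapse = ", "))
    }
  }
  counts <- suppressWarnings(matrix(as.integer(m[, 11:42]), nrow = nrow(m)))
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("non-integer or negative channel counts in: ", file)
  }
  colnames(counts) <- sprintf("ch%02d", 1:32)
  list(activity = counts, time = tt)
}

#' Score sleep from a minute-resolution activity trace
#'
#' Sleep is every minute inside a maximal run of at least 5 consecutive
#' zero-activity minutes (the standard immobility definition); all other
#' minutes are wake. Bouts are the maximal runs of each state.
#'
#' @param x Integer vector of per-minute beam crossings.
#' @param min_sleep_run Minimum immobility run scored as sleep (default 5).
#' @return List: `state` (character vector, `"SLEEP"`/`"WAKE"`), `bouts`
#'   (data.frame `state`, `start`, `duration`).
#' @export
score_sleep <- function(x, min_sleep_run = 5L) {
  stopifnot(all(x >= 0))
  r <- rle(x == 0)
  sleep_run <- r$values & r$lengths >= min_sleep_run
  state <- inverse.rle(list(values = ifelse(sleep_run, "SLEEP", "WAKE"),
                            lengths = r$lengths))
  br <- rle(state)
  ends <- cumsum(br$lengths)
  bouts <- data.frame(state = br$values,
                      start = ends - br$lengths + 1L,
                      duration = br$lengths,
                      stringsAsFactors = FALSE)
  list(state = state, bouts = bouts)
}

#' Maximum-likelihood Markov transition probabilities from a state vector
#'
#' `p_doze` = wake-to-sleep transitions over wake minutes with a successor;
#' `p_wake` = sleep-to-wake transitions over sleep minutes with a successor.
#' The last minute has no successor and is excluded from denominators.
#'
#' @param state Character (`"SLEEP"`/`"WAKE"`) or logical (`TRUE` = sleep)
#'   vector.
#' @return Named numeric: `p_doze`, `p_wake` (`NaN` when a state never occurs
#'   before the last minute).
#' @export
transition_probs <- function(state) {
  if (is.character(state)) state <- state == "SLEEP"
  n <- length(state)
  if (n < 2) return(c(p_doze = NaN, p_wake = NaN))
  from <- state[-n]; to <- state[-1]
  c(p_doze = sum(!from & to) / sum(!from),
    p_wake = sum(from & !to) / sum(from))
}

#' Per-day sleep metrics for one fly
#'
#' Splits a trace into 1440-minute days, scores sleep per day, and reports
#' the standard architecture metrics plus the Markov drive statistics:
#' total/day-phase (ZT0-12)/night-phase (ZT12-24) sleep minutes, sleep-bout
#' number and mean length (bouts attributed to their start day), waking
#' activity (beam crossings per waking minute), and `p_doze` / `p_wake`
#' (sleep drive and wake drive). Days labelled `"acclimation"` are scored
#' but dropped from the output.
#'
#' @param x Per-minute activity counts for one fly (length a multiple of
#'   1440).
#' @param days Day label per day (length `length(x) / 1440`), e.g.
#'   `c("fed", "starved")`.
#' @param min_sleep_run Immobility-run threshold (default 5 minutes).
#' @return data.frame, one row per non-acclimation day: `day`, `total_sleep`,
#'   `day_sleep`, `night_sleep`, `n_bouts`, `mean_bout_length`,
#'   `waking_activity` (`NA` on an all-sleep day), `p_doze`, `p_wake`.
#' @export
sleep_metrics <- function(x, days = c("fed", "starved"), min_sleep_run = 5L) {
  mpd <- 1440L
  if (length(x) %% mpd != 0) stop("trace length must be a multiple of 1440")
  nd <- length(x) %/% mpd
  stopifnot(length(days) == nd)
  rows <- lapply(seq_len(nd), function(d) {
    if (days[d] == "acclimation") return(NULL)
    xd <- x[((d - 1L) * mpd + 1L):(d * mpd)]
    sc <- score_sleep(xd, min_sleep_run)
    asleep <- sc$state == "SLEEP"
    sleep_bouts <- sc$bouts[sc$bouts$state == "SLEEP", , drop = FALSE]
    tp <- transition_probs(sc$state)
    wake_min <- sum(!asleep)
    data.frame(
      day = days[d],
      total_sleep = sum(asleep),
      day_sleep = sum(asleep[1:720]),
      night_sleep = sum(asleep[721:1440]),
      n_bouts = nrow(sleep_bouts),
      mean_bout_length = if (nrow(sleep_bouts)) mean(sleep_bouts$duration) else 0,
      waking_activity = if (wake_min > 0) sum(xd) / wake_min else NA_real_,
      p_doze = tp["p_doze"],
      p_wake = tp["p_wake"],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sleep metrics for a DAM cohort
#'
#' Applies [sleep_metrics()] to every fly in a channel map.
#'
#' @param activity Minutes x channels matrix (e.g. from [read_dam()] or
#'   [simulate_dam()]).
#' @param flies data.frame with `fly_id`, `genotype`, `channel`.
#' @param days Day label per 1440-minute block.
#' @param min_sleep_run Immobility threshold.
#' @return data.frame: `fly_id`, `genotype` and the per-day metrics.
#' @export
cohort_metrics <- function(activity, flies, days = c("fed", "starved"),
                           min_sleep_run = 5L) {
  rows <- lapply(seq_len(nrow(flies)), function(i) {
    m <- sleep_metrics(activity[, flies$channel[i]], days, min_sleep_run)
    cbind(fly_id = flies$fly_id[i], genotype = flies$genotype[i], m,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Starvation-induced sleep suppression
#'
#' Within-fly change in sleep between the fed and starved day: absolute
#' difference in minutes and percent change
#' `(starved - fed) / fed * 100` (undefined when fed sleep is 0; the absolute
#' change is still reported).
#'
#' @param fed,starved Numeric vectors of per-fly sleep minutes (same order),
#'   or a cohort metrics data.frame in `fed` (with `fly_id`, `day`,
#'   `total_sleep`) and `starved` omitted.
#' @return data.frame: `fly_id` (when available), `fed`, `starved`,
#'   `delta_min`, `pct_change`.
#' @export
suppression <- function(fed, starved = NULL) {
  if (is.data.frame(fed) && is.null(starved)) {
    df <- fed
    stopifnot(all(c("fly_id", "day", "total_sleep") %in% names(df)))
    wide <- merge(df[df$day == "fed", c("fly_id", "total_sleep")],
                  df[df$day == "starved", c("fly_id", "total_sleep")],
                  by = "fly_id", suffixes = c("_fed", "_starved"))
    out <- suppression(wide$total_sleep_fed, wide$total_sleep_starved)
    cbind(fly_id = wide$fly_id, out, stringsAsFactors = FALSE)
  } else {
    stopifnot(length(fed) == length(starved))
    data.frame(
      fed = fed, starved = starved,
      delta_min = starved - fed,
      pct_change = ifelse(fed > 0, (starved - fed) / fed * 100, NA_real_)
    )
  }
}

#' Dunn's post-hoc test of pairwise group differences on ranks
#'
#' Follows a Kruskal-Wallis test: pairwise z statistics on mean ranks with
#' the ties correction, and adjusted p values across comparisons.
#'
#' @param value Numeric response.
#' @param group Group factor.
#' @param method P-adjustment across pairs (default `"holm"`).
#' @return data.frame: `comparison`, `z`, `pvalue`, `padj`.
#' @export
dunn_test <- function(value, group, method = "holm") {
  group <- factor(group)
  ok <- !is.na(value) & !is.na(group)
  value <- value[ok]; group <- droplevels(group[ok])
  n <- length(value)
  r <- rank(value)
  ties <- table(value)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(group)
  combs <- utils::combn(lv, 2)
  rows <- apply(combs, 2, function(pr) {
    i <- group == pr[1]; j <- group == pr[2]
    ni <- sum(i); nj <- sum(j)
    diff <- mean(r[i]) - mean(r[j])
    sigma <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni + 1 / nj))
    z <- diff / sigma
    data.frame(comparison = paste(pr[1], pr[2], sep = " - "), z = z,
               pvalue = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$pvalue, method = method)
  rownames(out) <- NULL
  out
}

#' Group comparisons of per-fly sleep metrics
#'
#' The standard battery for DAM cohorts: one-way ANOVA with Tukey HSD across
#' genotypes; Kruskal-Wallis with Dunn's post hoc; and, when both days are
#' present per fly, a two-way repeated-measures ANOVA (genotype x day with
#' fly as the repeated subject), reporting the interaction F — the test of
#' whether starvation changes sleep differently across genotypes. Flies
#' missing a day are dropped from the repeated-measures fit with a warning.
#'
#' @param df data.frame with columns `fly_id`, `genotype`, `day` and the
#'   response.
#' @param response Name of the response column (default `"total_sleep"`).
#' @param day Restrict the one-way analyses to this day (default
#'   `"starved"`); `NULL` pools days.
#' @return List of class `sleep_group_stats`: `anova` (data.frame F, df, p),
#'   `tukey`, `kruskal` (H, df, p), `dunn`, `rm_anova` (genotype x day
#'   interaction F, df, p; `NULL` if a single day).
#' @export
group_stats <- function(df, response = "total_sleep", day = "starved") {
  stopifnot(all(c("fly_id", "genotype", "day", response) %in% names(df)))
  df$genotype <- factor(df$genotype)
  if (nlevels(df$genotype) < 2) stop("need at least two genotypes")
  one <- if (is.null(day)) df else df[df$day == day, , drop = FALSE]
  y <- one[[response]]
  fit <- aov(y ~ genotype, data = one)
  an <- summary(fit)[[1]]
  tuk <- as.data.frame(TukeyHSD(fit)$genotype)
  tuk <- cbind(comparison = rownames(tuk), tuk, stringsAsFactors = FALSE)
  rownames(tuk) <- NULL
  kw <- kruskal.test(y ~ genotype, data = one)
  dn <- dunn_test(y, one$genotype)

  rm_an <- NULL
  if (length(unique(df$day)) >= 2) {
    tab <- table(df$fly_id, df$day)
    complete <- rownames(tab)[apply(tab > 0, 1, all)]
    if (length(complete) < nrow(tab)) {
      warning(nrow(tab) - length(complete),
              " fly/flies missing a day dropped from repeated-measures ANOVA")
    }
    rd <- df[df$fly_id %in% complete, , drop = FALSE]
    rd$day <- factor(rd$day)
    rd$fly_id <- factor(rd$fly_id)
    form <- stats::as.formula(paste(response, "~ genotype * day + Error(fly_id)"))
    rfit <- aov(form, data = rd)
    within <- summary(rfit)[["Error: Within"]][[1]]
    ix <- grep("genotype:day", rownames(within))
    rm_an <- data.frame(
      effect = "genotype:day",
      F = within[ix, "F value"],
      df1 = within[ix, "Df"],
      df2 = within[nrow(within), "Df"],
      pvalue = within[ix, "Pr(>F)"]
    )
  }
  structure(list(
    anova = data.frame(F = an[1, "F value"], df1 = an[1, "Df"],
                       df2 = an[2, "Df"], pvalue = an[1, "Pr(>F)"]),
    tukey = tuk,
    kruskal = data.frame(H = unname(kw$statistic), df = unname(kw$parameter),
                         pvalue = kw$p.value),
    dunn = dn,
    rm_anova = rm_an
  ), class = "sleep_group_stats")
}

#' @export
print.sleep_group_stats <- function(x, ...) {
  cat("One-way ANOVA: F(", x$anova$df1, ",", x$anova$df2, ") =",
      signif(x$anova$F, 4), ", p =", signif(x$anova$pvalue, 3), "\n")
  cat("Kruskal-Wallis: H =", signif(x$kruskal$H, 4),
      ", p =", signif(x$kruskal$pvalue, 3), "\n")
  if (!is.null(x$rm_anova)) {
    cat("RM ANOVA genotype x day: F(", x$rm_anova$df1, ",", x$rm_anova$df2,
        ") =", signif(x$rm_anova$F, 4),
        ", p =", signif(x$rm_anova$pvalue, 3), "\n")
  }
  invisible(x)
}
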
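#' Read wide-format diary CSV
#'
#' Expects UTF-8 CSV with a header: `participant_id`, `day_type`
#' (weekday/weekend), activity columns `act_001..act_144` (one free-coded
#' activity code per 10-minute slot, sentinel `"missing"` allowed) and
#' travel columns `trv_001..trv_144` with values `none`, `travel_active`
#' or `travel_passive`.
#'
#' @param path CSV file path.
#' @return data.frame, one row per diary.
#' @export
read_diaries <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("participant_id", "day_type",
            sprintf("act_%03d", 1:144), sprintf("trv_%03d", 1:144))
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("diary file missing columns: ", paste(utils::head(miss, 5),
         collapse = ", "), call. = FALSE)
  }
  d
}

#' Read an activity taxonomy CSV
#'
#' Columns: `code` (activity code), `part` (one of [time_use_parts()]) and
#' `is_foodwork` (logical; food shopping, food preparation and management,
#' and washing dishes). Foodwork codes must map to the `work` part.
#'
#' @param path CSV file path.
#' @return data.frame with columns code, part, is_foodwork.
#' @export
read_taxonomy <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_taxonomy(t)
}

#' @rdname read_taxonomy
#' @param taxonomy data.frame to validate.
#' @export
validate_taxonomy <- function(taxonomy) {
  need <- c("code", "part", "is_foodwork")
  if (!all(need %in% names(taxonomy))) {
    stop("taxonomy needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  taxonomy$is_foodwork <- as.logical(taxonomy$is_foodwork)
  if (anyDuplicated(taxonomy$code)) {
    stop("taxonomy maps a code to more than one part", call. = FALSE)
  }
  bad <- setdiff(unique(taxonomy$part), time_use_parts())
  if (length(bad) > 0) {
    stop("unknown part label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fw <- taxonomy$is_foodwork & taxonomy$part != "work"
  if (any(fw)) {
    stop("foodwork codes must map to part 'work': ",
         paste(taxonomy$code[fw], collapse = ", "), call. = FALSE)
  }
  taxonomy
}

#' The package's built-in activity taxonomy
#'
#' A compact synthetic taxonomy covering every part, the three foodwork
#' activities, and travel codes, sufficient for simulation and testing. It
#' is not a reconstruction of any survey's code list; real analyses should
#' supply their own file via [read_taxonomy()].
#'
#' @return data.frame with columns code, part, is_foodwork.
#' @export
default_taxonomy <- function() {
  path <- system.file("extdata", "taxonomy.csv", package = "foodcoda",
                      mustWork = TRUE)
  read_taxonomy(path)
}

# internal: pull the 144 activity codes / travel flags out of a diary row
diary_slots <- function(row) {
  list(acts = as.character(unlist(row[sprintf("act_%03d", 1:144)])),
       travel = as.character(unlist(row[sprintf("trv_%03d", 1:144)])))
}

#' Quality-check one diary
#'
#' Applies the exclusion flags used for poor-quality diaries: more than
#' 90 min of missing time; fewer than 7 activity episodes (an episode
#' boundary is any change of activity code or travel flag between
#' consecutive slots); two or more of the four basic activities
#' (sleep/rest, eating/drinking, personal care, exercise/travel) absent;
#' not a full 24 h of eligible codes; or zero minutes of sleep.
#'
#' @param acts Character vector of 144 activity codes (`"missing"` allowed).
#' @param travel Character vector of 144 travel flags
#'   (none/travel_active/travel_passive).
#' @param taxonomy Activity taxonomy (see [read_taxonomy()]).
#' @return List with `missing_minutes`, `episode_count`,
#'   `basic_activities_missing`, `zero_sleep`, `full_24h`, and the verdict
#'   `include` (logical).
#' @export
validate_diary <- function(acts, travel, taxonomy = default_taxonomy()) {
  if (length(acts) != 144 || length(travel) != 144) {
    stop("a diary has exactly 144 slots; got ", length(acts), " / ",
         length(travel), call. = FALSE)
  }
  bad_trv <- which(!travel %in% c("none", "travel_active", "travel_passive"))
  if (length(bad_trv) > 0) {
    stop("malformed travel flag at slot ", bad_trv[1], call. = FALSE)
  }
  is_missing <- acts == "missing"
  known <- c(taxonomy$code, "missing")
  unknown <- which(!acts %in% known & travel == "none")
  # unknown codes on travel slots are tolerated: the flag determines them
  missing_minutes <- 10 * sum(is_missing & travel == "none")
  state <- paste(acts, travel)
  episode_count <- 1L + sum(state[-1] != state[-144])
  part_of <- taxonomy$part[match(acts, taxonomy$code)]
  have_sleep <- any(part_of %in% "sleep")
  have_eat <- any(part_of %in% "eating")
  have_pc <- any(part_of %in% "personal_care")
  have_move <- any(part_of %in% "physical_activity") ||
    any(travel != "none")
  basics_missing <- sum(!c(have_sleep, have_eat, have_pc, have_move))
  full_24h <- missing_minutes == 0 && length(unknown) == 0
  zero_sleep <- !have_sleep
  include <- missing_minutes <= 90 &&
    episode_count >= 7 &&
    basics_missing < 2 &&
    full_24h &&
    !zero_sleep
  list(missing_minutes = missing_minutes,
       episode_count = episode_count,
       basic_activities_missing = basics_missing,
       zero_sleep = zero_sleep,
       full_24h = full_24h,
       include = include)
}

#' Randomly keep one valid diary per participant
#'
#' @param diaries data.frame of diaries (wide format, possibly several rows
#'   per `participant_id`).
#' @param seed Integer seed for the uniform random choice.
#' @return data.frame with one row per participant.
#' @export
select_one_diary <- function(diaries, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- split(seq_len(nrow(diaries)), diaries$participant_id)
  keep <- vapply(idx, function(i) {
    if (length(i) == 1L) i else i[sample.int(length(i), 1L)]
  }, integer(1))
  diaries[sort(unname(keep)), , drop = FALSE]
}

#' Map a diary to the 7-part minute vector
#'
#' Each 10-minute slot contributes to exactly one part. Travel slots are
#' allocated to the activity the travel enabled: active travel (foot or
#' bicycle) goes to physical activity; passive travel inherits the part of
#' the next non-travel, non-missing slot, wrapping past the diary end.
#' Missing slots contribute nothing, so the vector sums to 1440 minus
#' missing minutes.
#'
#' @inheritParams validate_diary
#' @return Named numeric 7-vector of minutes in the canonical part order.
#' @export
map_to_parts <- function(acts, travel, taxonomy = default_taxonomy()) {
  parts <- time_use_parts()
  part_of <- taxonomy$part[match(acts, taxonomy$code)]
  is_travel <- travel != "none"
  is_missing <- !is_travel & acts == "missing"
  plain <- !is_travel & !is_missing
  unmapped <- which(plain & is.na(part_of))
  if (length(unmapped) > 0) {
    stop("unmapped activity code(s): ",
         paste(unique(acts[unmapped]), collapse = ", "), call. = FALSE)
  }
  slot_part <- rep(NA_character_, 144)
  slot_part[plain] <- part_of[plain]
  slot_part[travel == "travel_active"] <- "physical_activity"
  passive <- which(travel == "travel_passive")
  if (length(passive) > 0) {
    anchors <- which(plain)
    if (length(anchors) == 0) {
      stop("diary is all travel/missing; cannot allocate passive travel",
           call. = FALSE)
    }
    for (s in passive) {
      nxt <- anchors[anchors > s]
      a <- if (length(nxt) > 0) nxt[1] else anchors[1]  # wrap past 4 a.m.
      slot_part[s] <- slot_part[a]
    }
  }
  counts <- table(factor(slot_part, levels = parts))
  stats::setNames(10 * as.numeric(counts), parts)
}

#' Daily foodwork minutes from a diary
#'
#' Sums the 10-minute slots whose activity code is flagged as foodwork in
#' the taxonomy (food shopping, food preparation and management, washing
#' dishes) and which are not travel slots, so foodwork minutes are always
#' contained in the work part produced by [map_to_parts()].
#'
#' @inheritParams validate_diary
#' @return Minutes of foodwork (multiple of 10).
#' @export
foodwork_minutes <- function(acts, travel, taxonomy = default_taxonomy()) {
  fw_codes <- taxonomy$code[taxonomy$is_foodwork]
  10 * sum(acts %in% fw_codes & travel == "none")
}

#' Median foodwork time among engagers
#'
#' The threshold splitting 'some' from 'more' foodwork: the median of daily
#' foodwork minutes over participants with strictly positive foodwork.
#'
#' @param minutes Numeric vector of daily foodwork minutes (zeros allowed).
#' @return The engager median in minutes.
#' @export
engager_median <- function(minutes) {
  pos <- minutes[minutes > 0]
  if (length(pos) == 0) {
    stop("no participants engaged in foodwork; median undefined",
         call. = FALSE)
  }
  stats::median(pos)
}

#' Assign the three-level foodwork category
#'
#' `none` for zero minutes; `some` for positive minutes strictly below the
#' threshold; `more` for minutes at or above the threshold (the engager
#' median, 70 min/day in the motivating survey).
#'
#' @param minutes Numeric vector of daily foodwork minutes.
#' @param threshold Engager-median threshold in minutes.
#' @return Factor with levels none, some, more.
#' @export
categorize_foodwork <- function(minutes, threshold) {
  if (any(minutes < 0)) stop("negative foodwork minutes", call. = FALSE)
  out <- ifelse(minutes == 0, "none",
                ifelse(minutes < threshold, "some", "more"))
  factor(out, levels = c("none", "some", "more"))
}

#' Pearson chi-square test of independence on a counts table
#'
#' Computed from the table exactly as supplied (no continuity correction):
#' expected counts from the row/column margins, statistic
#' sum((O-E)^2/E), df = (r-1)(c-1), p from the upper chi-square tail.
#'
#' @param tab Numeric matrix of counts (r x c).
#' @return List with `statistic`, `df`, `p`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  E <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' One-way ANOVA F from per-group summary statistics
#'
#' Recovers the F statistic from group sizes, means and standard deviations
#' alone: between-group mean square over within-group mean square.
#'
#' @param n Integer vector of group sizes (each >= 2).
#' @param mean Numeric vector of group means.
#' @param sd Numeric vector of group standard deviations.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_f_summary <- function(n, mean, sd) {
  k <- length(n)
  if (k < 2 || length(mean) != k || length(sd) != k) {
    stop("need >= 2 groups with matching n, mean, sd", call. = FALSE)
  }
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  gm <- sum(n * mean) / sum(n)
  ssb <- sum(n * (mean - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  df1 <- k - 1
  df2 <- sum(n) - k
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}
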
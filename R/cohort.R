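#' Claims cohorts
#'
#' A claims cohort bundles, for every insured subject, the baseline
#' survival information (sex, age at study entry, observed follow-up time
#' since entry and a death indicator) with the longitudinal record of
#' yearly emergency-claim counts.  Counts are analysed on the
#' \eqn{y = \log(1 + \mathrm{count})} scale throughout.
#'
#' @param subjects data frame with columns \code{id}, \code{sex} (man 0 /
#'   woman 1), \code{age0} (years at entry, \eqn{\ge 65}), \code{T_obs}
#'   (observed follow-up years), \code{delta} (1 = death observed,
#'   0 = censored).
#' @param records data frame with columns \code{id}, \code{t} (years since
#'   entry), \code{count} (nonnegative integer yearly claims) and
#'   optionally \code{y} (a continuous log-scale response; defaults to
#'   \code{log1p(count)}).  May have zero rows.
#' @param meta list of provenance information (source file, or simulation
#'   config and seed).
#' @return An object of class \code{"claims_cohort"} with components
#'   \code{subjects}, \code{records} (sorted by id and time) and
#'   \code{meta}.
#' @export
claims_cohort <- function(subjects, records = NULL, meta = list()) {
  if (is.null(records))
    records <- data.frame(id = character(), t = numeric(),
                          count = numeric(), y = numeric())
  subjects <- as.data.frame(subjects)
  records <- as.data.frame(records)

  need <- c("id", "sex", "age0", "T_obs", "delta")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    jm_stop("jmclaims_missing_baseline",
            "missing baseline column(s): %s", paste(miss, collapse = ", "))
  for (v in need) {
    if (anyNA(subjects[[v]]))
      jm_stop("jmclaims_missing_baseline",
              "baseline column '%s' has missing values (first at row %d)",
              v, which(is.na(subjects[[v]]))[1])
  }
  subjects$id <- as.character(subjects$id)
  rownames(subjects) <- NULL
  if (anyDuplicated(subjects$id))
    jm_stop("jmclaims_duplicate_id", "duplicated subject id '%s'",
            subjects$id[anyDuplicated(subjects$id)])
  if (!all(subjects$delta %in% c(0, 1)))
    jm_stop("jmclaims_invalid_baseline", "delta must be 0 or 1")
  if (!all(subjects$sex %in% c(0, 1)))
    jm_stop("jmclaims_invalid_baseline", "sex must be coded man:0 / woman:1")
  if (any(subjects$T_obs < 0))
    jm_stop("jmclaims_invalid_baseline", "T_obs must be nonnegative")
  if (any(subjects$age0 < 65))
    jm_stop("jmclaims_invalid_baseline",
            "age0 below 65 (subject '%s'): the cohort is restricted to 65+",
            subjects$id[which(subjects$age0 < 65)[1]])

  if (nrow(records)) {
    if (!all(c("id", "t", "count") %in% names(records)))
      jm_stop("jmclaims_missing_baseline",
              "records need columns id, t, count")
    records$id <- as.character(records$id)
    unknown <- setdiff(records$id, subjects$id)
    if (length(unknown))
      jm_stop("jmclaims_missing_baseline",
              "record for unknown subject id '%s'", unknown[1])
    bad <- which(is.na(records$count) | records$count < 0)
    if (length(bad))
      jm_stop("jmclaims_negative_count",
              "negative or missing claim count at record row %d (id '%s', t = %s)",
              bad[1], records$id[bad[1]], format(records$t[bad[1]]))
    if (any(records$t < 0))
      jm_stop("jmclaims_invalid_record", "record times must be nonnegative")
    Tmap <- stats::setNames(subjects$T_obs, subjects$id)
    over <- which(records$t > Tmap[records$id] + 1e-9)
    if (length(over))
      jm_stop("jmclaims_time_exceeds_followup",
              "record row %d (id '%s') has t = %s beyond follow-up T_obs = %s",
              over[1], records$id[over[1]], format(records$t[over[1]]),
              format(Tmap[records$id[over[1]]]))
    dup <- duplicated(records[c("id", "t")])
    if (any(dup))
      jm_stop("jmclaims_duplicate_occasion",
              "duplicate measurement occasion at record row %d (id '%s', t = %s)",
              which(dup)[1], records$id[which(dup)[1]],
              format(records$t[which(dup)[1]]))
    if (is.null(records$y)) records$y <- log1p(records$count)
    na_y <- is.na(records$y)
    records$y[na_y] <- log1p(records$count[na_y])
    records <- records[order(match(records$id, subjects$id), records$t), ,
                       drop = FALSE]
    rownames(records) <- NULL
  } else if (is.null(records$y)) {
    records$y <- numeric()
  }

  structure(list(subjects = subjects,
                 records = records[c("id", "t", "count", "y")],
                 meta = meta),
            class = "claims_cohort")
}

#' @export
print.claims_cohort <- function(x, ...) {
  cat(sprintf("<claims cohort: %d subjects, %d deaths (%.1f%%), %d records>\n",
              nrow(x$subjects), sum(x$subjects$delta),
              100 * mean(x$subjects$delta), nrow(x$records)))
  invisible(x)
}

#' @export
as.data.frame.claims_cohort <- function(x, ...) {
  cohort_panel(x)
}

# Long-format panel: one row per (subject, occasion); subjects without
# records keep a single baseline row with NA occasion fields.
cohort_panel <- function(cohort) {
  s <- cohort$subjects
  r <- cohort$records
  has <- s$id %in% r$id
  base_only <- s[!has, , drop = FALSE]
  out <- merge(s, r, by = "id", all.x = FALSE, sort = FALSE)
  if (nrow(base_only)) {
    base_only$t <- NA_real_
    base_only$count <- NA_real_
    base_only$y <- NA_real_
    out <- rbind(out, base_only[names(out)])
  }
  out <- out[order(match(out$id, s$id), out$t, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out[c("id", "sex", "age0", "T_obs", "delta", "t", "count", "y")]
}

#' Read a claims cohort from a long-format CSV file
#'
#' Expects one row per (subject, occasion) with baseline columns repeated;
#' subjects without measurement occasions appear as a single row with empty
#' \code{t} and \code{count}.  The log-scale response \code{y} is read if
#' present and otherwise derived as \code{log1p(count)}.
#'
#' @param path CSV file path.
#' @param layout optional named character vector mapping canonical column
#'   names (\code{id}, \code{sex}, \code{age0}, \code{T_obs}, \code{delta},
#'   \code{t}, \code{count}, \code{y}) to the file's column names.
#' @return A [claims_cohort()].
#' @export
read_cohort <- function(path, layout = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(layout)) {
    for (canon in names(layout)) {
      if (!layout[[canon]] %in% names(df))
        jm_stop("jmclaims_missing_baseline",
                "layout column '%s' not found in %s", layout[[canon]], path)
      names(df)[names(df) == layout[[canon]]] <- canon
    }
  }
  need <- c("id", "sex", "age0", "T_obs", "delta")
  miss <- setdiff(need, names(df))
  if (length(miss))
    jm_stop("jmclaims_missing_baseline",
            "file %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  subjects <- unique(df[need])
  has_t <- !is.na(df$t)
  rec_cols <- intersect(c("id", "t", "count", "y"), names(df))
  records <- df[has_t, rec_cols, drop = FALSE]
  claims_cohort(subjects, records,
                meta = list(source = path))
}

#' Write a claims cohort to a long-format CSV file
#'
#' Inverse of [read_cohort()]: one row per occasion, baseline columns
#' repeated, and a single baseline-only row for subjects without records.
#' Times, ages and the continuous response are written with fixed 6-decimal
#' formatting so that a write/read cycle is the identity on cohorts whose
#' values carry at most 6 decimals (as produced by [simulate_cohort()]).
#'
#' @param cohort a [claims_cohort()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  panel <- cohort_panel(cohort)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  out <- data.frame(id = panel$id,
                    sex = panel$sex,
                    age0 = fmt(panel$age0),
                    T_obs = fmt(panel$T_obs),
                    delta = panel$delta,
                    t = fmt(panel$t),
                    count = ifelse(is.na(panel$count), "",
                                   format(panel$count, scientific = FALSE)),
                    y = fmt(panel$y))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) jm_stop("jmclaims_unwritable_path", "cannot write to '%s'", path)
  invisible(path)
}

#' Stratified cohort description
#'
#' Tabulates subject counts, death counts, row percentages and percent
#' death rates by age-at-entry stratum, overall and within each gender, in
#' the layout of a descriptive portfolio table.
#'
#' @param cohort a [claims_cohort()].
#' @param age_breaks strictly increasing break points for age at entry;
#'   default \code{c(65, 75, 85, Inf)} giving strata \eqn{[65,75)},
#'   \eqn{[75,85)}, \eqn{\ge 85}.
#' @return Data frame with one row per (group, stratum) plus the row-total
#'   stratum \code{"overall"}; columns \code{group} (\code{all},
#'   \code{men}, \code{women}), \code{stratum}, \code{subjects},
#'   \code{subjects_row_pct}, \code{deaths}, \code{deaths_row_pct} and
#'   \code{death_rate_pct} (= 100 deaths / subjects, half-up rounded to one
#'   decimal; \code{NA} for empty strata).
#' @export
cohort_summary <- function(cohort, age_breaks = c(65, 75, 85, Inf)) {
  if (is.unsorted(age_breaks, strictly = TRUE))
    jm_stop("jmclaims_invalid_breaks", "age_breaks must be strictly increasing")
  s <- cohort$subjects
  labs <- character(length(age_breaks) - 1)
  for (k in seq_along(labs)) {
    labs[k] <- if (is.finite(age_breaks[k + 1]))
      sprintf("[%g,%g)", age_breaks[k], age_breaks[k + 1])
    else sprintf(">=%g", age_breaks[k])
  }
  stratum <- cut(s$age0, breaks = age_breaks, right = FALSE, labels = labs)
  one_group <- function(idx, group) {
    n_tot <- length(idx)
    d_tot <- sum(s$delta[idx])
    n_k <- as.integer(table(stratum[idx]))
    d_k <- as.integer(tapply(s$delta[idx], stratum[idx], sum, default = 0))
    n <- c(n_k, n_tot)
    d <- c(d_k, d_tot)
    data.frame(
      group = group,
      stratum = c(labs, "overall"),
      subjects = n,
      subjects_row_pct = if (n_tot > 0) round_half_up(100 * n / n_tot)
                         else rep(NA_real_, length(n)),
      deaths = d,
      deaths_row_pct = if (d_tot > 0) round_half_up(100 * d / d_tot)
                       else rep(NA_real_, length(d)),
      death_rate_pct = ifelse(n > 0, round_half_up(100 * d / n), NA_real_))
  }
  out <- rbind(one_group(seq_len(nrow(s)), "all"),
               one_group(which(s$sex == 0), "men"),
               one_group(which(s$sex == 1), "women"))
  rownames(out) <- NULL
  out
}

# Subject extractor used by prediction: baseline row + records (optionally
# truncated to occasions at or before horizon t).
subject_data <- function(cohort, id, up_to = Inf) {
  i <- match(as.character(id), cohort$subjects$id)
  if (is.na(i))
    jm_stop("jmclaims_unknown_subject", "no subject with id '%s'", id)
  rec <- cohort$records[cohort$records$id == cohort$subjects$id[i] &
                        cohort$records$t <= up_to + 1e-12, , drop = FALSE]
  list(baseline = cohort$subjects[i, , drop = FALSE], records = rec)
}
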
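## Dietary diversity scores: count of distinct food groups (out of 12) a
## household consumed over the 72-hour recall window, plus the descriptive
## tables (per-group intake and participation, treated/control mean gaps)
## that accompany a household food survey.

.FOOD_GROUPS <- c("cereals", "roots_tubers", "legumes", "vegetables",
                  "edible_fungi", "fruits", "nuts_seeds", "livestock_meat",
                  "poultry_meat", "milk_products", "eggs", "fish_seafood")

#' Canonical food groups used for the dietary diversity score
#'
#' The 12 groups of the household dietary diversity score: cereals, roots and
#' tubers, legumes, vegetables, edible fungi, fruits, nuts and seeds,
#' livestock meat, poultry meat, milk and milk products, eggs, and fish and
#' seafood.
#'
#' @return character vector of length 12.
#' @export
food_groups <- function() .FOOD_GROUPS

check_intake_records <- function(records) {
  need <- c("household_id", "food_group", "grams_per_capita_per_day")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("intake records are missing column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(as.character(records$food_group)), .FOOD_GROUPS)
  if (length(unknown))
    stop("unknown food group label(s): ", paste(unknown, collapse = ", "))
  g <- records$grams_per_capita_per_day
  if (any(!is.finite(g)) || any(g < 0))
    stop("grams_per_capita_per_day must be finite and non-negative")
  invisible(records)
}

#' Compute household dietary diversity scores
#'
#' Counts, for each household, the number of distinct food groups with at
#' least one consumed item (positive grams) among its intake records. Each
#' group counts once regardless of how many items within it were consumed;
#' zero-gram records do not count as consumption. The score lies in 0..12.
#'
#' @param records data frame of intake records with columns `household_id`,
#'   `food_group` (one of [food_groups()]) and `grams_per_capita_per_day`;
#'   an `item_name` column is allowed and ignored.
#' @return data frame with columns `household_id` and `dds` (integer score),
#'   one row per household appearing in `records`, in order of first
#'   appearance.
#' @examples
#' recs <- data.frame(household_id = 1,
#'                    food_group = c("cereals", "cereals", "legumes"),
#'                    grams_per_capita_per_day = c(300, 120, 40))
#' compute_dds(recs)  # rice + wheat count once: score 2
#' @export
compute_dds <- function(records) {
  check_intake_records(records)
  hh <- unique(records$household_id)
  pos <- records[records$grams_per_capita_per_day > 0, , drop = FALSE]
  counts <- tapply(as.character(pos$food_group), pos$household_id,
                   function(g) length(unique(g)))
  score <- as.integer(counts[as.character(hh)])
  score[is.na(score)] <- 0L
  data.frame(household_id = hh, dds = score)
}

#' Summarise food-group participation and mean intake
#'
#' For each canonical food group, the percentage of households with at least
#' one consumed item in the group and the mean per-capita intake (g/day)
#' averaged over *all* households (non-consumers contribute zero).
#'
#' @param records intake records as in [compute_dds()].
#' @param household_count total number of surveyed households (>= 1); the
#'   denominator for both columns, which may exceed the number of households
#'   present in `records`.
#' @return data frame with columns `food_group`, `mean_intake_per_capita`
#'   and `pct_households_consuming`, one row per canonical group.
#' @export
summarize_groups <- function(records, household_count) {
  stopifnot(length(household_count) == 1, household_count >= 1)
  if (nrow(records) == 0) {
    warning("no intake records: returning all-zero group summaries")
    return(data.frame(food_group = .FOOD_GROUPS,
                      mean_intake_per_capita = 0,
                      pct_households_consuming = 0))
  }
  check_intake_records(records)
  pos <- records[records$grams_per_capita_per_day > 0, , drop = FALSE]
  out <- lapply(.FOOD_GROUPS, function(gr) {
    sub <- records[records$food_group == gr, , drop = FALSE]
    consuming <- length(unique(pos$household_id[pos$food_group == gr]))
    data.frame(food_group = gr,
               mean_intake_per_capita =
                 sum(sub$grams_per_capita_per_day) / household_count,
               pct_households_consuming = 100 * consuming / household_count)
  })
  do.call(rbind, out)
}

#' Mean differences between treated and control households
#'
#' Welch two-sample t-tests of each variable between the treated (e.g. online
#' food shoppers) and control groups, with the difference reported as
#' mean(treated) - mean(control) and stars at p < 0.10 / 0.05 / 0.01.
#'
#' @param data household-level data frame.
#' @param treatment name of the binary treatment column.
#' @param variables character vector of numeric columns to compare.
#' @return data frame with columns `variable`, `mean_treated`, `sd_treated`,
#'   `mean_control`, `sd_control`, `difference`, `p_value`, `stars`.
#' @export
group_mean_differences <- function(data, treatment = "ofs",
                                   variables = setdiff(names(data), treatment)) {
  t_col <- data[[treatment]]
  if (is.null(t_col)) stop("treatment column '", treatment, "' not found")
  if (!all(t_col %in% c(0, 1))) stop("treatment column must be binary 0/1")
  if (!any(t_col == 1)) stop("treated group is empty")
  if (!any(t_col == 0)) stop("control group is empty")
  rows <- lapply(variables, function(v) {
    x <- data[[v]][t_col == 1]
    y <- data[[v]][t_col == 0]
    d <- mean(x) - mean(y)
    p <- tryCatch(stats::t.test(x, y)$p.value,
                  error = function(e) if (isTRUE(all.equal(d, 0))) 1 else 0)
    data.frame(variable = v,
               mean_treated = mean(x), sd_treated = sd(x),
               mean_control = mean(y), sd_control = sd(y),
               difference = d, p_value = p, stars = p_stars(p))
  })
  do.call(rbind, rows)
}

#' Default food-group consumption profile
#'
#' Per-group participation rates (% of households) and mean per-capita
#' intakes (g/day, averaged over all households) used to calibrate the
#' synthetic intake generator: cereals and vegetables near-universal, eggs
#' and livestock meat common, edible fungi and nuts rare. The sum of the
#' participation probabilities implies a mean dietary diversity score of
#' about 6.6 under independent group consumption.
#'
#' @return data frame with columns `food_group`, `mean_intake_per_capita`,
#'   `pct_households_consuming`.
#' @export
default_food_group_profile <- function() {
  data.frame(
    food_group = .FOOD_GROUPS,
    mean_intake_per_capita = c(450.5, 54.0, 41.9, 365.5, 4.4, 142.6,
                               9.5, 83.7, 32.0, 8.5, 44.8, 44.3),
    pct_households_consuming = c(100.0, 57.3, 60.2, 99.8, 20.5, 56.2,
                                 21.5, 71.2, 32.2, 30.5, 73.8, 33.6)
  )
}

#' Simulate long-format food intake records
#'
#' Draws, independently per household and food group, a Bernoulli consumption
#' indicator at the profile's participation rate and, for consumers, a gamma
#' intake amount whose mean reproduces the profile's all-household mean
#' intake. Only consumed (positive-gram) records are returned.
#'
#' @param n_households number of households.
#' @param profile calibration as from [default_food_group_profile()].
#' @param cv coefficient of variation of consumer-level intake.
#' @param seed optional integer seed.
#' @return data frame of intake records (`household_id`, `item_name`,
#'   `food_group`, `grams_per_capita_per_day`) suitable for [compute_dds()].
#' @export
simulate_intake <- function(n_households, profile = default_food_group_profile(),
                            cv = 0.6, seed = NULL) {
  stopifnot(n_households >= 1, cv > 0)
  if (!is.null(seed)) set.seed(seed)
  shape <- 1 / cv^2
  out <- lapply(seq_len(nrow(profile)), function(i) {
    p <- profile$pct_households_consuming[i] / 100
    if (p <= 0) return(NULL)
    consume <- rbinom(n_households, 1, p) == 1
    if (!any(consume)) return(NULL)
    mean_consumer <- profile$mean_intake_per_capita[i] / p
    grams <- rgamma(sum(consume), shape = shape,
                    scale = mean_consumer / shape)
    data.frame(household_id = which(consume),
               item_name = paste0(profile$food_group[i], "_item"),
               food_group = profile$food_group[i],
               grams_per_capita_per_day = grams)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res <- res[order(res$household_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
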
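#' Questionnaire records for exposure derivation
#'
#' A plain data frame with one row per participant and the tobacco,
#' alcohol and HPV serology fields the exposure-derivation rules consume.
#' All fields must be non-negative.
#'
#' @param cigarettes_per_day,handrolled_per_day,cigars_per_day,smokeless_per_day
#'   Daily product counts.
#' @param years_smoked Years of smoking.
#' @param lifetime_cigarettes Lifetime cigarette count.
#' @param wine_units,spirit_units,beer_units Weekly alcohol units.
#' @param hpv16_e6_mfi HPV16 E6 median fluorescence intensity (>= 0).
#' @return A `data.frame` of class `questionnaire`.
#' @export
questionnaire <- function(cigarettes_per_day = 0, handrolled_per_day = 0,
                          cigars_per_day = 0, smokeless_per_day = 0,
                          years_smoked = 0, lifetime_cigarettes = 0,
                          wine_units = 0, spirit_units = 0, beer_units = 0,
                          hpv16_e6_mfi = 0) {
  q <- data.frame(cigarettes_per_day, handrolled_per_day, cigars_per_day,
                  smokeless_per_day, years_smoked, lifetime_cigarettes,
                  wine_units, spirit_units, beer_units, hpv16_e6_mfi)
  if (any(as.matrix(q) < 0)) stop("questionnaire fields must be >= 0")
  class(q) <- c("questionnaire", "data.frame")
  q
}

#' Derive ever/never smoking status
#'
#' A participant is an ever smoker if they smoked the equivalent of at
#' least one tobacco product a day for at least one year, or at least 100
#' cigarettes in their lifetime.  A cigar counts as four cigarettes;
#' hand-rolled and smokeless products count one-for-one.  The daily-use
#' rule is read as a joint condition (>= 1 equivalent/day AND >= 1 year
#' smoked); this predicate is the single place to swap in an alternative
#' reading.
#'
#' @param q A [questionnaire()] data frame.
#' @return Logical vector, `TRUE` for ever smokers.
#' @export
derive_smoking_status <- function(q) {
  stopifnot(is.data.frame(q))
  equivalents <- q$cigarettes_per_day + q$handrolled_per_day +
    4 * q$cigars_per_day + q$smokeless_per_day
  (equivalents >= 1 & q$years_smoked >= 1) | q$lifetime_cigarettes >= 100
}

#' Derive weekly alcohol intake in units
#'
#' Sum of wine, spirit and beer weekly units; zero defines a non-drinker.
#'
#' @param q A [questionnaire()] data frame.
#' @return Numeric vector of units/week.
#' @export
derive_alcohol_units <- function(q) {
  stopifnot(is.data.frame(q))
  q$wine_units + q$spirit_units + q$beer_units
}

#' Classify HPV16 E6 serostatus
#'
#' Seropositive if the median fluorescence intensity is at or above
#' 1000 MFI (inclusive cutoff).
#'
#' @param mfi Non-negative MFI values.
#' @param cutoff Seropositivity cutoff (default 1000 MFI).
#' @return Logical vector, `TRUE` for seropositive.
#' @export
classify_hpv_serostatus <- function(mfi, cutoff = 1000) {
  if (any(mfi < 0)) stop("MFI values must be >= 0")
  mfi >= cutoff
}
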
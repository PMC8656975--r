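#' Age groups and sexes used throughout the package
#'
#' Five age groups (under 15; 15 to 39; 40 to 64; 65 to 84; 85 and over) and
#' two sexes, the stratification of the study population.
#' @name strata
#' @export
age_groups <- c("0-14", "15-39", "40-64", "65-84", "85+")

#' @rdname strata
#' @export
sexes <- c("male", "female")

# validate a stratified table (tract_id, sex, age_group, value); returns it
# with canonical ordering, erroring on missing strata or negative counts
.check_strat_table <- function(tab, what, tract_ids = NULL) {
  need <- c("tract_id", "sex", "age_group", "value")
  if (!all(need %in% names(tab)))
    stop(what, " must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (any(tab$value < 0)) stop(what, " has negative counts", call. = FALSE)
  if (!all(tab$sex %in% sexes)) stop(what, ": unknown sex level", call. = FALSE)
  if (!all(tab$age_group %in% age_groups))
    stop(what, ": unknown age group", call. = FALSE)
  ids <- if (is.null(tract_ids)) sort(unique(tab$tract_id)) else tract_ids
  full <- expand.grid(tract_id = ids, sex = sexes, age_group = age_groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$tract_id, d$sex, d$age_group, sep = "\r")
  m <- match(key(full), key(tab))
  if (anyNA(m)) stop(what, " is missing strata (the key set must be the full ",
                     "tracts x sexes x age groups cross-product)", call. = FALSE)
  full$value <- tab$value[m]
  full
}

#' Area-wide reference admission rates
#'
#' Indirect standardization step one: the age-group-specific rates of the
#' whole study area, computed separately per sex as
#' `r_{g,s} = sum_i O_{i,g,s} / sum_i n_{i,g,s}` (cumulative risk over the
#' study period).
#'
#' @param counts observed admissions: data.frame with columns
#'   `tract_id, sex, age_group, value`.
#' @param pop population denominators in the same layout.
#' @return data.frame `sex, age_group, rate`. A stratum with events but zero
#'   population is an error; a stratum with zero population and zero events
#'   gets rate 0.
#' @export
reference_rates <- function(counts, pop) {
  pop <- .check_strat_table(pop, "pop")
  counts <- .check_strat_table(counts, "counts", sort(unique(pop$tract_id)))
  O <- stats::aggregate(value ~ sex + age_group, counts, sum)
  N <- stats::aggregate(value ~ sex + age_group, pop, sum)
  m <- match(paste(O$sex, O$age_group), paste(N$sex, N$age_group))
  if (any(O$value > 0 & N$value[m] == 0))
    stop("stratum with events but zero population", call. = FALSE)
  rate <- ifelse(N$value[m] > 0, O$value / N$value[m], 0)
  data.frame(sex = O$sex, age_group = O$age_group, rate = rate,
             stringsAsFactors = FALSE)
}

#' Expected admissions per tract by the indirect method
#'
#' `E_{i,s} = sum_g n_{i,g,s} * r_{g,s}`.
#'
#' @param pop population table (`tract_id, sex, age_group, value`).
#' @param rates reference rates (`sex, age_group, rate`), e.g. from
#'   [reference_rates()].
#' @return data.frame `tract_id, sex, E`.
#' @export
expected_counts <- function(pop, rates) {
  pop <- .check_strat_table(pop, "pop")
  m <- match(paste(pop$sex, pop$age_group), paste(rates$sex, rates$age_group))
  if (anyNA(m)) stop("rates do not cover every stratum present in pop", call. = FALSE)
  if (any(rates$rate < 0)) stop("negative rate", call. = FALSE)
  pop$E <- pop$value * rates$rate[m]
  out <- stats::aggregate(E ~ tract_id + sex, pop, sum)
  out[order(out$sex, out$tract_id), c("tract_id", "sex", "E")]
}

#' Standardized admission ratio
#'
#' `SAR_i = 100 * O_i / E_i` (percent scale). Tracts with `E_i = 0` are
#' flagged undefined (`SAR = NA`) rather than imputed, and are excluded from
#' downstream maps.
#'
#' @param observed data.frame `tract_id, sex, O` (or `value`).
#' @param expected data.frame `tract_id, sex, E`.
#' @return An object of class `standardized_result` (a data.frame
#'   `tract_id, sex, O, E, SAR, defined`).
#' @export
sar <- function(observed, expected) {
  if ("value" %in% names(observed) && !"O" %in% names(observed))
    names(observed)[names(observed) == "value"] <- "O"
  if (any(observed$O < 0) || any(expected$E < 0))
    stop("negative inputs", call. = FALSE)
  m <- match(paste(observed$tract_id, observed$sex),
             paste(expected$tract_id, expected$sex))
  if (anyNA(m)) stop("expected counts missing for some (tract, sex)", call. = FALSE)
  out <- data.frame(tract_id = observed$tract_id, sex = observed$sex,
                    O = observed$O, E = expected$E[m], stringsAsFactors = FALSE)
  out$defined <- out$E > 0
  out$SAR <- ifelse(out$defined, 100 * out$O / out$E, NA_real_)
  if (any(!out$defined))
    message(sum(!out$defined), " tract-sex cell(s) with E = 0: SAR undefined, excluded")
  out <- out[order(out$sex, out$tract_id), ]
  rownames(out) <- NULL
  structure(out, class = c("standardized_result", "data.frame"))
}

#' One-step indirect standardization
#'
#' Convenience wrapper: derives area-wide reference rates from the data
#' (unless supplied), computes expected counts, and returns the SAR table.
#' With internally derived rates, `sum_i E = sum_i O` per sex — the defining
#' conservation property of indirect standardization.
#'
#' @param counts observed admissions (`tract_id, sex, age_group, value`).
#' @param pop population table in the same layout.
#' @param rates optional external reference rates; derived internally when
#'   `NULL`.
#' @return A `standardized_result`.
#' @export
standardize <- function(counts, pop, rates = NULL) {
  pop <- .check_strat_table(pop, "pop")
  counts <- .check_strat_table(counts, "counts", sort(unique(pop$tract_id)))
  if (is.null(rates)) rates <- reference_rates(counts, pop)
  E <- expected_counts(pop, rates)
  O <- stats::aggregate(value ~ tract_id + sex, counts, sum)
  names(O)[names(O) == "value"] <- "O"
  sar(O, E)
}
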
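#' Default age-by-sex population profile
#'
#' Proportions of the total population in each of the 10 (sex, age group)
#' strata, emulating an aged urban north-Spanish population: age shares
#' 10.3 / 24.5 / 40.2 / 20.5 / 4.5 percent across the five age groups, with a
#' male fraction declining from 51.5% under 15 to 33% at 85+.
#'
#' @return data.frame `sex, age_group, prop` with `sum(prop) == 1`.
#' @export
default_age_sex_profile <- function() {
  share <- c(`0-14` = 0.103, `15-39` = 0.245, `40-64` = 0.402,
             `65-84` = 0.205, `85+` = 0.045)
  male_frac <- c(`0-14` = 0.515, `15-39` = 0.50, `40-64` = 0.49,
                 `65-84` = 0.45, `85+` = 0.33)
  data.frame(sex = rep(sexes, each = 5),
             age_group = rep(age_groups, 2),
             prop = c(share * male_frac, share * (1 - male_frac)),
             stringsAsFactors = FALSE)
}

#' Simulate a stratified tract population
#'
#' Per-tract totals are negative-binomial around `mean_pop` (dispersion
#' parameter `size`; the default `size = 4` gives a coefficient of variation
#' of about 0.5, emulating the heterogeneity of real census-tract sizes) and
#' are split into the 10 (sex, age group) strata by a multinomial draw from
#' `profile`.
#'
#' @param graph an `adjacency_graph` supplying the tract ids.
#' @param mean_pop mean tract population (default 1265).
#' @param profile data.frame `sex, age_group, prop` whose 10 proportions sum
#'   to 1 (within 1e-9).
#' @param dispersion negative-binomial size parameter; `Inf` gives Poisson
#'   totals.
#' @param seed integer seed; the draw is bit-reproducible given it.
#' @return Population table `tract_id, sex, age_group, value`.
#' @export
simulate_population <- function(graph, mean_pop = 1265,
                                profile = default_age_sex_profile(),
                                dispersion = 4, seed = 1) {
  if (mean_pop <= 0 || dispersion <= 0)
    stop("mean_pop and dispersion must be positive", call. = FALSE)
  if (nrow(profile) != 10 || abs(sum(profile$prop) - 1) > 1e-9)
    stop("profile must have 10 cells summing to 1", call. = FALSE)
  set.seed(seed)
  n <- graph$n
  totals <- if (is.infinite(dispersion)) stats::rpois(n, mean_pop)
            else stats::rnbinom(n, size = dispersion, mu = mean_pop)
  cells <- vapply(totals, function(tot)
    as.integer(stats::rmultinom(1, tot, profile$prop)), integer(10))
  data.frame(tract_id = rep(graph$tract_ids, each = 10),
             sex = rep(profile$sex, n),
             age_group = rep(profile$age_group, n),
             value = as.integer(cells),
             stringsAsFactors = FALSE)
}

#' Draw an intrinsic CAR spatial field
#'
#' Samples `u ~ ICAR(tau_u * Q)` with `Q` the graph Laplacian, by drawing
#' independent normals on the non-null eigenspace of `Q` (variances
#' `1/(tau_u * lambda_k)`) and projecting onto the sum-to-zero subspace of
#' each connected component. The result sums to zero per component to 1e-10.
#'
#' @param graph an `adjacency_graph`; tracts with zero neighbours are an
#'   error unless `allow_islands = TRUE`, in which case islands get `u = 0`
#'   (pure unstructured effect downstream).
#' @param tau_u positive precision.
#' @param seed integer seed.
#' @param allow_islands tolerate isolated tracts (see above).
#' @return named numeric vector `u` over tracts.
#' @export
simulate_icar_field <- function(graph, tau_u = 1, seed = 1, allow_islands = FALSE) {
  if (tau_u <= 0) stop("tau_u must be positive", call. = FALSE)
  d <- lengths(graph$nbr)
  if (!allow_islands && any(d == 0))
    stop("isolated tract(s): the intrinsic CAR field is undefined on islands ",
         "(use allow_islands = TRUE to give them u = 0)", call. = FALSE)
  Q <- as.matrix(build_icar_precision(graph, allow_islands = TRUE))
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > 1e-8 * max(eg$values, 1)
  set.seed(seed)
  u <- numeric(graph$n)
  if (any(pos)) {
    z <- stats::rnorm(sum(pos), sd = 1 / sqrt(tau_u * eg$values[pos]))
    u <- as.numeric(eg$vectors[, pos, drop = FALSE] %*% z)
  }
  comp <- graph_components(graph)
  u <- u - stats::ave(u, comp)       # exact sum-to-zero per component
  u[d == 0] <- 0
  names(u) <- graph$tract_ids
  u
}

#' Construct a true relative-risk surface
#'
#' The generative counterpart of the BYM model: spatially structured log-risk
#' `u ~ ICAR(tau_u)`, unstructured `v_i ~ N(0, 1/tau_v)`, global intercept
#' `alpha`, and true relative risk `theta_i = exp(alpha + u_i + v_i)`.
#'
#' @param graph an `adjacency_graph`.
#' @param alpha global log-level (0 means area-average risk 1).
#' @param tau_u,tau_v positive precisions of the structured and unstructured
#'   components.
#' @param seed integer seed.
#' @param u optional pre-drawn spatial field (to share one field across
#'   sexes); drawn internally when `NULL`.
#' @return An object of class `risk_surface`: list with `alpha`, `u`, `v`,
#'   `theta` (named by tract).
#' @export
make_risk_surface <- function(graph, alpha = 0, tau_u = 1, tau_v = 10,
                              seed = 1, u = NULL) {
  if (is.null(u)) u <- simulate_icar_field(graph, tau_u, seed = seed)
  set.seed(seed + 1L)
  v <- stats::rnorm(graph$n, sd = 1 / sqrt(tau_v))
  names(v) <- graph$tract_ids
  theta <- exp(alpha + u + v)
  structure(list(alpha = alpha, u = u, v = v, theta = theta,
                 tau_u = tau_u, tau_v = tau_v),
            class = "risk_surface")
}

#' Calibrate baseline age-specific rates to a target event total
#'
#' The study area's per-age-group admission rates are free parameters; this
#' scales a relative age shape so that the expected total
#' `sum_i sum_g n_{i,g,s} * r_{g,s}` hits `target` for the given sex.
#'
#' @param pop population table.
#' @param sex which sex's strata to calibrate.
#' @param target expected total number of events for that sex.
#' @param shape named relative rate by age group (any positive scale); the
#'   default rises steeply with age as ischemic heart disease admissions do.
#' @param theta optional named per-tract relative-risk vector; when given,
#'   the scale is chosen so the expected total under that risk surface (not
#'   under flat risk) equals `target`.
#' @return data.frame `sex, age_group, rate` for the one sex.
#' @export
calibrate_rates <- function(pop, sex, target,
                            shape = c(`0-14` = 0.001, `15-39` = 0.05,
                                      `40-64` = 1, `65-84` = 3.5, `85+` = 5),
                            theta = NULL) {
  stopifnot(sex %in% sexes, target >= 0, all(shape >= 0))
  p <- pop[pop$sex == sex, ]
  w <- if (is.null(theta)) rep(1, nrow(p)) else as.numeric(theta[p$tract_id])
  if (anyNA(w)) stop("theta not defined on every tract", call. = FALSE)
  ntot <- tapply(p$value * w, p$age_group, sum)[age_groups]
  denom <- sum(ntot * shape[age_groups])
  if (denom == 0) stop("zero population in all strata", call. = FALSE)
  data.frame(sex = sex, age_group = age_groups,
             rate = as.numeric(target / denom * shape[age_groups]),
             stringsAsFactors = FALSE)
}

#' Simulate admission counts
#'
#' `O_{i,g,s} ~ Poisson(n_{i,g,s} * r_{g,s} * theta_i)` independently across
#' strata — the generative counterpart of the spatial Poisson likelihood.
#'
#' @param pop population table.
#' @param rates reference rates (`sex, age_group, rate`), covering every
#'   stratum in `pop`.
#' @param surface a `risk_surface` (or a named theta vector) defined on every
#'   tract of `pop`.
#' @param seed integer seed.
#' @return Count table `tract_id, sex, age_group, value`.
#' @export
simulate_admissions <- function(pop, rates, surface, seed = 1) {
  if (any(rates$rate < 0)) stop("rates must be non-negative", call. = FALSE)
  theta <- if (inherits(surface, "risk_surface")) surface$theta else surface
  m <- match(paste(pop$sex, pop$age_group), paste(rates$sex, rates$age_group))
  if (anyNA(m)) stop("rates do not cover every stratum in pop", call. = FALSE)
  th <- theta[pop$tract_id]
  if (anyNA(th)) stop("surface not defined on every tract of pop", call. = FALSE)
  mu <- pop$value * rates$rate[m] * as.numeric(th)
  set.seed(seed)
  out <- pop
  out$value <- stats::rpois(nrow(pop), mu)
  out
}

#' Expand a count table into event-level records
#'
#' One row per admission (tract id, sex, age group), with a fraction of
#' additional records left spatially unassigned (`tract_id = NA`) to emulate
#' geocoding failures.
#'
#' @param counts count table.
#' @param p_unassigned fraction of all records that fail spatial assignment
#'   (default `33/3251`, about 1.01%).
#' @param seed integer seed.
#' @return data.frame `tract_id, sex, age_group` with `NA` tract ids for the
#'   unassigned records.
#' @export
simulate_events <- function(counts, p_unassigned = 33 / 3251, seed = 1) {
  stopifnot(p_unassigned >= 0, p_unassigned < 1)
  keep <- counts[counts$value > 0, ]
  ev <- data.frame(
    tract_id = rep(keep$tract_id, keep$value),
    sex = rep(keep$sex, keep$value),
    age_group = rep(keep$age_group, keep$value),
    stringsAsFactors = FALSE)
  set.seed(seed)
  n_extra <- stats::rpois(1, nrow(ev) * p_unassigned / (1 - p_unassigned))
  if (n_extra > 0) {
    pick <- sample.int(max(nrow(ev), 1), n_extra, replace = TRUE)
    extra <- ev[pick, , drop = FALSE]
    extra$tract_id <- NA_character_
    ev <- rbind(ev, extra)
  }
  rownames(ev) <- NULL
  ev
}

#' Simulate a full Asturias-like synthetic study
#'
#' One call generates everything downstream stages need: a 558-tract queen
#' lattice (18 x 31), negative-binomial tract populations around 1265
#' inhabitants, a shared ICAR spatial risk field with sex-specific
#' unstructured noise, baseline age rates calibrated so the expected 3-year
#' event totals are 3218 split 64.42% / 35.58% male / female, admission
#' counts, and an event-level record table with ~1.01% unassigned records.
#'
#' @param seed integer master seed; sub-stage seeds are fixed offsets of it.
#' @param n_rows,n_cols lattice dimensions (defaults 18 x 31 = 558 tracts).
#' @param mean_pop mean tract population.
#' @param total_events expected total admissions over the study period.
#' @param male_frac fraction of events occurring in men.
#' @param tau_u,tau_v risk-surface precisions (shared spatial / per-sex
#'   unstructured).
#' @param alpha global log-risk level.
#' @param null_risk if `TRUE`, force `theta == 1` everywhere (flat-risk null
#'   scenario).
#' @return list with `graph`, `pop`, `counts` (both sexes), `events`,
#'   `rates`, `surface` (per sex), and the parameters used.
#' @export
simulate_study <- function(seed = 1, n_rows = 18, n_cols = 31,
                           mean_pop = 1265, total_events = 3218,
                           male_frac = 0.6442, tau_u = 1, tau_v = 10,
                           alpha = 0, null_risk = FALSE) {
  graph <- make_lattice(n_rows, n_cols, "queen")
  pop <- simulate_population(graph, mean_pop, seed = seed + 11L)
  if (null_risk) {
    one <- stats::setNames(rep(1, graph$n), graph$tract_ids)
    surf_m <- surf_f <- structure(list(alpha = 0,
                                       u = one * 0, v = one * 0, theta = one,
                                       tau_u = Inf, tau_v = Inf),
                                  class = "risk_surface")
  } else {
    u <- simulate_icar_field(graph, tau_u, seed = seed + 21L)
    surf_m <- make_risk_surface(graph, alpha, tau_u, tau_v,
                                seed = seed + 31L, u = u)
    surf_f <- make_risk_surface(graph, alpha, tau_u, tau_v,
                                seed = seed + 41L, u = u)
  }
  rates <- rbind(
    calibrate_rates(pop, "male", total_events * male_frac,
                    theta = surf_m$theta),
    calibrate_rates(pop, "female", total_events * (1 - male_frac),
                    theta = surf_f$theta))
  pop_m <- pop[pop$sex == "male", ]; pop_f <- pop[pop$sex == "female", ]
  cnt_m <- simulate_admissions(pop_m, rates, surf_m, seed = seed + 51L)
  cnt_f <- simulate_admissions(pop_f, rates, surf_f, seed = seed + 61L)
  counts <- rbind(cnt_m, cnt_f)
  events <- simulate_events(counts, seed = seed + 71L)
  list(graph = graph, pop = pop, counts = counts, events = events,
       rates = rates, surface = list(male = surf_m, female = surf_f),
       params = list(seed = seed, n_rows = n_rows, n_cols = n_cols,
                     mean_pop = mean_pop, total_events = total_events,
                     male_frac = male_frac, tau_u = tau_u, tau_v = tau_v,
                     alpha = alpha, null_risk = null_risk))
}
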
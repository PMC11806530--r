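# Synthetic input-output panels with a known constant-returns frontier.
#
# The generator mirrors the shape of the provincial pediatric-medication
# panel (31 provinces x 7 years, 9 inputs, 8 outputs) while keeping the
# production technology analytically known, so the DEA stage can be tested
# against closed-form oracles.

default_input_names <- c(
  "health_expenditure", "tertiary_pediatric_hospitals", "pediatric_beds",
  "senior_pediatricians", "qualified_pediatric_pharmacists",
  "medication_health_training", "pediatrician_patient_load",
  "technical_consultation", "health_records_management")

default_output_names <- c(
  "pediatric_discharges", "outpatient_emergency_visits",
  "pediatric_drug_use_scale", "class_ab_incidence", "class_ab_mortality",
  "family_health_services", "effective_child_support",
  "community_medication_guidance")

#' Configuration of the synthetic panel generator
#'
#' The frontier is Cobb-Douglas with constant returns,
#' \eqn{Y^*_{jt} = A_t \prod_i x_{ij}^{\beta_i}} with
#' \eqn{\sum_i \beta_i = 1}; the frontier level advances by
#' \eqn{A_{t+1} = A_t (1 + g_t)}.  Inputs are drawn once per DMU on the log
#' scale and held fixed over periods, isolating frontier shift and
#' inefficiency as the only sources of change.  Potential output is split
#' across the output indicators by fixed positive proportions and contracted
#' by \eqn{e^{-u_{jt}}} with half-normal inefficiency draws
#' \eqn{u_{jt} = \sigma_u |Z|}; optional multiplicative log-normal noise of
#' scale \code{sigma_v} can be added on top.
#'
#' @param n_dmus number of DMUs (default 31).
#' @param n_periods number of periods (default 7, labelled 2015-2021).
#' @param period_labels period identifiers.
#' @param input_names,output_names indicator names (defaults mirror a
#'   9-input / 8-output provincial panel).
#' @param beta Cobb-Douglas input exponents; normalised to sum 1.
#' @param tech_shift per-pair frontier growth \eqn{g_t}; scalar or vector of
#'   length \code{n_periods - 1} (default 0.02).
#' @param sigma_u half-normal inefficiency scale (default 0.1).
#' @param sigma_v multiplicative output noise scale (default 0).
#' @param input_meanlog,input_sdlog log-scale location/spread of the input
#'   draws; recycled over inputs.
#' @param output_shares positive proportions splitting potential output
#'   across the output indicators; normalised to sum 1.
#' @param frontier_level initial frontier level \eqn{A_1}.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return an object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_dmus = 31L, n_periods = 7L,
                             period_labels = NULL,
                             input_names = default_input_names,
                             output_names = default_output_names,
                             beta = NULL,
                             tech_shift = 0.02,
                             sigma_u = 0.1,
                             sigma_v = 0,
                             input_meanlog = log(500),
                             input_sdlog = 0.6,
                             output_shares = NULL,
                             frontier_level = 1,
                             seed = 1L) {
  m <- length(input_names); s <- length(output_names)
  if (n_dmus < 1 || n_periods < 2 || m < 1 || s < 1)
    stop("need n_dmus >= 1, n_periods >= 2 and at least one input and output",
         call. = FALSE)
  if (is.null(period_labels)) {
    period_labels <- if (n_periods == 7L) as.character(2015:2021)
                     else as.character(seq_len(n_periods))
  }
  stopifnot(length(period_labels) == n_periods)
  if (is.null(beta)) beta <- rep(1 / m, m)
  if (length(beta) != m || any(beta < 0) || sum(beta) <= 0)
    stop("'beta' must be nonnegative with a positive sum, one per input",
         call. = FALSE)
  beta <- beta / sum(beta)
  if (length(tech_shift) == 1L) tech_shift <- rep(tech_shift, n_periods - 1L)
  if (length(tech_shift) != n_periods - 1L)
    stop("'tech_shift' must be scalar or length n_periods - 1", call. = FALSE)
  if (any(tech_shift <= -1))
    stop("'tech_shift' must be greater than -1", call. = FALSE)
  if (sigma_u < 0 || sigma_v < 0 || frontier_level <= 0 ||
      any(input_sdlog < 0))
    stop("scales must be nonnegative and frontier_level positive",
         call. = FALSE)
  if (is.null(output_shares)) output_shares <- (s:1) / sum(s:1)
  if (length(output_shares) != s || any(output_shares <= 0))
    stop("'output_shares' must be positive, one per output", call. = FALSE)
  output_shares <- output_shares / sum(output_shares)
  structure(list(n_dmus = as.integer(n_dmus), n_periods = as.integer(n_periods),
                 period_labels = as.character(period_labels),
                 input_names = input_names, output_names = output_names,
                 beta = beta, tech_shift = tech_shift,
                 sigma_u = sigma_u, sigma_v = sigma_v,
                 input_meanlog = rep_len(input_meanlog, m),
                 input_sdlog = rep_len(input_sdlog, m),
                 output_shares = output_shares,
                 frontier_level = frontier_level,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic panel with known frontier structure
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return a list with components \code{panel}
#'   (a \code{\link{panel_dataset}}) and \code{truth} (class
#'   \code{"synthetic_truth"}: the realised inefficiency draws \code{u},
#'   frontier levels \code{A}, potential outputs and the config).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_dmus; Tn <- config$n_periods
  m <- length(config$input_names); s <- length(config$output_names)

  out <- with_seed(config$seed, {
    xbase <- matrix(stats::rlnorm(n * m,
                                  meanlog = rep(config$input_meanlog, each = n),
                                  sdlog = rep(config$input_sdlog, each = n)),
                    n, m)
    u <- if (config$sigma_u > 0)
      matrix(abs(stats::rnorm(n * Tn, sd = config$sigma_u)), n, Tn)
    else matrix(0, n, Tn)
    v <- if (config$sigma_v > 0)
      array(stats::rnorm(n * Tn * s, sd = config$sigma_v), c(n, Tn, s))
    else array(0, c(n, Tn, s))
    list(xbase = xbase, u = u, v = v)
  })

  A <- cumprod(c(config$frontier_level, 1 + config$tech_shift))
  frontier <- drop(exp(log(out$xbase) %*% config$beta))  # prod x_i^beta_i

  x <- array(out$xbase, c(n, m, Tn))
  x <- aperm(x, c(1, 3, 2))                               # dmu, period, input
  y <- array(NA_real_, c(n, Tn, s))
  for (t in seq_len(Tn)) {
    ystar <- A[t] * frontier * exp(-out$u[, t])
    y[, t, ] <- outer(ystar, config$output_shares) * exp(out$v[, t, ])
  }
  panel <- panel_dataset(x, y, dmu_ids = sprintf("dmu%02d", seq_len(n)),
                         period_ids = config$period_labels,
                         input_names = config$input_names,
                         output_names = config$output_names)
  truth <- structure(list(u = out$u, A = A, frontier = frontier,
                          config = config),
                     class = "synthetic_truth")
  list(panel = panel, truth = truth)
}

#' Oracle Malmquist index for a zero-noise synthetic panel
#'
#' For a noise-free panel (no inefficiency, no output noise) with fixed
#' inputs and a uniform frontier shift \eqn{g_t}, the four component
#' efficiencies of the input-oriented index can be written down directly:
#' the two within-period scores coincide, and the cross-period scores equal
#' the within-period score divided (respectively multiplied) by
#' \eqn{1 + g_t}.  The index therefore equals \eqn{1 / (1 + g_t)} for every
#' DMU, independent of the DEA computation.  This closed form is the
#' recovery target for the engine.
#'
#' @param truth the \code{truth} component returned by
#'   \code{\link{simulate_panel}}.
#' @param period_pair pair index (1-based) or a label such as
#'   \code{"2015=>2016"}.
#' @return the oracle index, a positive scalar.
#' @export
expected_index <- function(truth, period_pair) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  if (cfg$sigma_u > 0 || cfg$sigma_v > 0)
    stop("oracle undefined for noisy configurations (sigma_u or sigma_v > 0)",
         call. = FALSE)
  labels <- paste0(cfg$period_labels[-cfg$n_periods], "=>",
                   cfg$period_labels[-1])
  i <- if (is.numeric(period_pair)) as.integer(period_pair)
       else match(period_pair, labels)
  if (is.na(i) || i < 1 || i > length(labels))
    stop("no such period pair", call. = FALSE)
  1 / (1 + cfg$tech_shift[i])
}
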
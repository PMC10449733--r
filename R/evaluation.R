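#' Relative prediction error
#'
#' Signed percentage deviation of a prediction from an observation:
#' `(predicted - observed) / observed * 100`. Vectorized.
#'
#' @param predicted,observed numeric vectors; `observed` must be positive.
#' @return RPE in percent.
#' @export
#' @examples
#' rpe(2.95, 3.32)   # about -11.1
rpe <- function(predicted, observed) {
  if (any(observed <= 0)) stop("observed values must be positive", call. = FALSE)
  (predicted - observed) / observed * 100
}

# half-away-from-zero rounding, the convention of the reported tables
# (base round() is half-to-even)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reported (integer-percent) relative prediction error
#'
#' [rpe()] rounded half-away-from-zero to the nearest integer percent, the
#' formatting used in reporting tables. Raw values should be kept for any
#' further computation.
#'
#' @inheritParams rpe
#' @return Integer-valued RPE in percent.
#' @export
rpe_reported <- function(predicted, observed) {
  round_half_away(rpe(predicted, observed))
}

#' Compare individual against population predictions
#'
#' For each patient/region pair, the prediction with the strictly smaller
#' absolute RPE wins; exact ties are flagged and counted for neither side.
#' The verdicts depend only on RPE magnitudes and are therefore invariant
#' to the units of the underlying AUCs.
#'
#' @param pairs data.frame with columns `id`, `region`, `rpe_individual`,
#'   `rpe_population` (percent).
#' @return List with `comparison` (the input plus a `winner` column:
#'   `"individual"`, `"population"` or `"tie"`) and `summary` (per region:
#'   counts of individual wins, population wins, ties).
#' @export
compare_individual_vs_population <- function(pairs) {
  need <- c("id", "region", "rpe_individual", "rpe_population")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyNA(pairs$rpe_individual) || anyNA(pairs$rpe_population)) {
    stop("unpaired patient: RPE missing for one approach", call. = FALSE)
  }
  ai <- abs(pairs$rpe_individual)
  ap <- abs(pairs$rpe_population)
  pairs$winner <- ifelse(ai < ap, "individual",
                         ifelse(ap < ai, "population", "tie"))
  summ <- do.call(rbind, lapply(split(pairs, pairs$region), function(d) {
    data.frame(region = d$region[1],
               individual = sum(d$winner == "individual"),
               population = sum(d$winner == "population"),
               tie = sum(d$winner == "tie"))
  }))
  rownames(summ) <- NULL
  list(comparison = pairs, summary = summ)
}

#' Tabular goodness-of-fit summary
#'
#' Observed-versus-predicted regression slope and intercept, correlation,
#' and the mean and SD of the normalized residuals
#' `(observed - predicted) / predicted`, per agent and region. Under the
#' proportional error model the normalized residual SD estimates the
#' residual CV (the square root of sigma2). A tabular stand-in for visual
#' goodness-of-fit inspection.
#'
#' @param obs observation table (non-excluded rows are used).
#' @param pred numeric vector of model predictions aligned with the rows of
#'   `obs`.
#' @return data.frame with one row per agent/region: `agent`, `region`,
#'   `n`, `slope`, `intercept`, `correlation`, `resid_mean`, `resid_sd`.
#' @export
gof_summary <- function(obs, pred) {
  stopifnot(length(pred) == nrow(obs))
  use <- obs$EXCL == 0 & !is.na(obs$DV) & pred > 0
  if (!any(use)) stop("no usable paired records", call. = FALSE)
  d <- data.frame(agent = obs$AGENT[use], region = obs$CMT[use],
                  y = obs$DV[use], f = pred[use])
  out <- do.call(rbind, lapply(split(d, list(d$agent, d$region), drop = TRUE),
                               function(g) {
    res <- (g$y - g$f) / g$f
    if (nrow(g) >= 2 && sd(g$f) > 0) {
      co <- coef(lm(y ~ f, data = g))
      r <- suppressWarnings(cor(g$y, g$f))
    } else {
      co <- c(NA_real_, NA_real_)
      r <- NA_real_
    }
    data.frame(agent = g$agent[1], region = g$region[1], n = nrow(g),
               slope = co[[2]], intercept = co[[1]], correlation = r,
               resid_mean = mean(res), resid_sd = if (nrow(g) >= 2) sd(res) else 0)
  }))
  rownames(out) <- NULL
  out
}

#' Normality check of estimated random effects
#'
#' Shapiro-Wilk test per eta dimension; under a correctly specified model
#' the posterior modes across patients should look approximately normal.
#'
#' @param etas matrix of etas (patients in rows, eta keys in columns).
#' @return data.frame with `key`, `W`, `p_value`.
#' @export
eta_normality <- function(etas) {
  do.call(rbind, lapply(colnames(etas), function(k) {
    s <- shapiro.test(etas[, k])
    data.frame(key = k, W = unname(s$statistic), p_value = s$p.value)
  }))
}

#' Bundled worked-example prediction table
#'
#' Observed and predicted tumor and kidney exposures for a nine-patient
#' clinical theranostic cohort, as reported: AUC from time zero to the last
#' measurement (mg h/L) and absorbed dose (Gy), with the reported
#' integer-percent RPEs. Useful as a desk check of the RPE arithmetic and
#' as input to the comparison utilities.
#'
#' @return data.frame with columns `id`, `region`, `quantity`
#'   (`"auc"`/`"dose"`), `observed`, `predicted`, `rpe_printed`.
#' @export
example_predictions <- function() {
  path <- system.file("extdata", "reference_predictions.tsv",
                      package = "theranopk", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
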
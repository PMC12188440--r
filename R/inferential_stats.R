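#' Fit a Gaussian linear mixed model
#'
#' Thin, contract-stable wrapper around `glmmTMB`: Gaussian response,
#' random intercepts, REML estimation, Wald z p-values for the fixed
#' effects. Rows with missing values in any used variable are dropped and
#' counted. Non-convergence is flagged on the result, never silently
#' worked around.
#'
#' @param formula model formula in `lme4` syntax, e.g.
#'   `y ~ dominance * period + (1 | id)`.
#' @param data data frame.
#' @param reml use REML (default) rather than ML.
#' @return an `lmm_fit`: list with `coefficients` (term, estimate, se, z, p),
#'   `varcomp` (group, variance; residual included), `converged`, `n_obs`,
#'   `n_dropped`, `formula` and the underlying `fit`.
#' @export
fit_lmm <- function(formula, data, reml = TRUE) {
  vars <- all.vars(formula)
  vars <- intersect(vars, names(data))
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  ## grouping factors must be categorical
  bars <- lme4_barnames(formula)
  for (b in bars) {
    if (b %in% names(data)) data[[b]] <- factor(data[[b]])
  }
  ## scale-aware starting values for the random-effect SDs: the default
  ## unit-scale start can collapse to the zero-variance boundary when the
  ## response is measured in tens of metres
  resp <- data[[all.vars(formula)[1]]]
  resp_sd <- stats::sd(resp)
  start <- if (is.finite(resp_sd) && resp_sd > 0 && length(bars) > 0) {
    list(theta = rep(log(resp_sd / 2), length(bars)))
  } else NULL
  fit_once <- function(start) {
    suppressWarnings(
      glmmTMB::glmmTMB(formula, data = data, REML = reml,
                       family = stats::gaussian(), start = start)
    )
  }
  degenerate <- function(msg) {
    structure(list(
      formula = formula,
      coefficients = tibble::tibble(term = character(0),
                                    estimate = numeric(0), se = numeric(0),
                                    z = numeric(0), p = numeric(0)),
      varcomp = tibble::tibble(group = character(0), variance = numeric(0)),
      converged = FALSE, n_obs = nrow(data), n_dropped = n_dropped,
      error = msg, fit = NULL
    ), class = "lmm_fit")
  }
  if (!is.finite(resp_sd) || resp_sd == 0) {
    return(degenerate("response is constant or empty"))
  }
  fit <- tryCatch(fit_once(start), error = identity)
  if (inherits(fit, "error") || !isTRUE(fit$sdr$pdHess)) {
    refit <- tryCatch(fit_once(NULL), error = identity)
    if (!inherits(refit, "error") && isTRUE(refit$sdr$pdHess)) {
      fit <- refit
    } else if (inherits(fit, "error")) {
      fit <- refit
    }
  }
  if (inherits(fit, "error")) return(degenerate(conditionMessage(fit)))
  sm <- summary(fit)
  co <- sm$coefficients$cond
  coefficients <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    se = unname(co[, "Std. Error"]),
    z = unname(co[, "z value"]),
    p = unname(co[, "Pr(>|z|)"])
  )
  vc <- glmmTMB::VarCorr(fit)$cond
  varcomp <- tibble::tibble(
    group = c(names(vc), "residual"),
    variance = unname(c(vapply(vc, function(m) m[1, 1], numeric(1)),
                        attr(vc, "sc")^2))
  )
  converged <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  structure(list(formula = formula, coefficients = coefficients,
                 varcomp = varcomp, converged = converged,
                 n_obs = nrow(data), n_dropped = n_dropped, fit = fit),
            class = "lmm_fit")
}

## grouping-factor names in (1 | g) terms
lme4_barnames <- function(formula) {
  rhs <- formula[[length(formula)]]
  found <- character(0)
  walk <- function(e) {
    if (is.call(e)) {
      if (identical(e[[1]], as.name("|"))) {
        found <<- c(found, all.vars(e[[3]]))
      } else {
        for (k in seq(2, length(e))) walk(e[[k]])
      }
    }
  }
  walk(rhs)
  unique(found)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model:", deparse(x$formula), "\n")
  cat(sprintf("n = %d (%d rows dropped), %s\n", x$n_obs, x$n_dropped,
              if (x$converged) "converged" else "DID NOT CONVERGE"))
  print(as.data.frame(x$coefficients), digits = 3)
  cat("Variance components:\n")
  print(as.data.frame(x$varcomp), digits = 3)
  invisible(x)
}

#' Intraclass correlation coefficient (repeatability)
#'
#' Share of response variance attributable to among-group differences:
#' `var(factor) / (var(factor) + var(residual))` from the variance
#' components of a random-intercept fit. With individual identity as the
#' factor this is the repeatability of the response across events.
#'
#' @param fit an [fit_lmm()] result.
#' @param factor grouping-factor name (default "id").
#' @return ratio in `[0, 1]`.
#' @export
icc <- function(fit, factor = "id") {
  vc <- fit$varcomp
  if (!factor %in% vc$group) {
    stop("no random factor '", factor, "' in the fit; available: ",
         paste(setdiff(vc$group, "residual"), collapse = ", "), call. = FALSE)
  }
  v_id <- vc$variance[vc$group == factor]
  v_res <- vc$variance[vc$group == "residual"]
  v_id / (v_id + v_res)
}

#' The progression-order mixed-model battery
#'
#' Fits the five models used to discriminate the risk, competition,
#' decision-making and social-spandrel explanations of progression order:
#' \enumerate{
#'   \item spatial position ~ dominance x period + sex x period + (1 | id),
#'     with the repeatability (ICC) of position appended;
#'   \item spatial interiority ~ same terms (on the raw |position| scale,
#'     where *small* values are central — signs are reported on this scale);
#'   \item progression pairwise distance ~ rest-of-day pairwise distance
#'     + (1 | pair) + (1 | date);
#'   \item within-event SD of position ~ dominance + (1 | date) +
#'     (1 | event_id) + (1 | id);
#'   \item nearest-neighbour consistency ~ dominance + sex + (1 | id) +
#'     (1 | date) + (1 | event_id).
#' }
#' Responses are aggregated to the progression level beforehand (models 1,
#' 2, 4, 5) or to (pair, date) (model 3), which removes the second-scale
#' autocorrelation of the raw series. If a model's `period` factor has a
#' single level the interaction terms are dropped for that model. A failing
#' model is flagged and the others are still reported.
#'
#' @param aggregates [aggregate_event_positions()] output with `period`.
#' @param pair_table [pairwise_distance_by_date()] output.
#' @param variability [positional_variability()] output.
#' @param consistency [consistency_model_data()] output (with dates).
#' @param attrs attribute table (id, sex, dominance).
#' @param events events table (for dates of models 4).
#' @return a `model_battery`: named list of `lmm_fit`s (`position`,
#'   `interiority`, `association`, `variability`, `consistency`), plus
#'   `icc_position` and an `errors` list of failed models.
#' @export
model_battery <- function(aggregates, pair_table, variability, consistency,
                          attrs, events = NULL) {
  errors <- list()
  fits <- list()
  try_fit <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
      NULL
    } else res
  }

  pos <- dplyr::left_join(aggregates, attrs, by = "id")
  two_periods <- length(unique(pos$period)) >= 2
  f1 <- if (two_periods) {
    mean_position ~ dominance * period + sex * period + (1 | id)
  } else mean_position ~ dominance + sex + (1 | id)
  f2 <- if (two_periods) {
    mean_interiority ~ dominance * period + sex * period + (1 | id)
  } else mean_interiority ~ dominance + sex + (1 | id)
  fits$position <- try_fit("position", fit_lmm(f1, pos))
  fits$interiority <- try_fit("interiority", fit_lmm(f2, pos))
  fits$association <- try_fit("association", fit_lmm(
    progression_dist ~ rest_dist + (1 | pair) + (1 | date), pair_table))

  vr <- dplyr::left_join(variability, attrs, by = "id")
  if (!is.null(events)) {
    vr <- dplyr::left_join(vr, events[, c("event_id", "date")], by = "event_id")
  }
  vr$id <- vr$id
  fits$variability <- try_fit("variability", fit_lmm(
    sd_position ~ dominance + (1 | date) + (1 | event_id) + (1 | id), vr))

  fits$consistency <- try_fit("consistency", fit_lmm(
    consistency ~ dominance + sex + (1 | id) + (1 | date) + (1 | event_id),
    consistency))

  icc_position <- if (!is.null(fits$position)) {
    tryCatch(icc(fits$position, "id"), error = function(e) NA_real_)
  } else NA_real_

  structure(list(fits = fits, icc_position = icc_position, errors = errors),
            class = "model_battery")
}

#' @export
print.model_battery <- function(x, ...) {
  for (nm in names(x$fits)) {
    if (is.null(x$fits[[nm]])) {
      cat(sprintf("-- %s: FAILED (%s)\n", nm, x$errors[[nm]]))
    } else {
      cat("--", nm, "--\n")
      print(x$fits[[nm]])
    }
    cat("\n")
  }
  cat(sprintf("Repeatability of spatial position (ICC): %.3f\n",
              x$icc_position))
  invisible(x)
}

#' One-row-per-term summary of a model battery
#' @param battery a [model_battery()] result.
#' @return tibble: model, term, estimate, se, p, converged.
#' @export
battery_summary <- function(battery) {
  dplyr::bind_rows(lapply(names(battery$fits), function(nm) {
    f <- battery$fits[[nm]]
    if (is.null(f)) return(NULL)
    out <- f$coefficients
    out$model <- nm
    out$converged <- f$converged
    out[, c("model", "term", "estimate", "se", "z", "p", "converged")]
  }))
}
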
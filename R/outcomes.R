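#' Build a 2x2 outcome contingency table
#'
#' Cell layout: `a` = exposed events, `b` = exposed non-events, `c` =
#' unexposed events, `d` = unexposed non-events.
#'
#' @param events_exposed,n_exposed Events and total in the exposed group
#'   (e.g. rsERT-guided transfers).
#' @param events_unexposed,n_unexposed Events and total in the comparison
#'   group (e.g. standard FET).
#' @return An object of class `two_by_two` (named integer vector `a`, `b`,
#'   `c`, `d`).
#' @examples
#' make_table(63, 115, 105, 272)   # clinical pregnancy, pET vs standard FET
#' @export
make_table <- function(events_exposed, n_exposed,
                       events_unexposed, n_unexposed) {
  v <- c(events_exposed, n_exposed, events_unexposed, n_unexposed)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  if (events_exposed > n_exposed || events_unexposed > n_unexposed) {
    stop("events cannot exceed group totals", call. = FALSE)
  }
  structure(c(a = as.integer(events_exposed),
              b = as.integer(n_exposed - events_exposed),
              c = as.integer(events_unexposed),
              d = as.integer(n_unexposed - events_unexposed)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(unclass(x), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

# Haldane-Anscombe: add 0.5 to every cell when any cell is zero
haldane <- function(t) {
  t <- as.numeric(unclass(t))
  if (all(t == 0)) stop("all-zero table", call. = FALSE)
  if (any(t == 0)) {
    attr(t, "haldane") <- TRUE
    t <- t + 0.5
    attr(t, "haldane") <- TRUE
  }
  t
}

#' Odds ratio of a 2x2 table
#'
#' `OR = (a d) / (b c)`. If any cell is zero, 0.5 is added to all cells
#' first (Haldane--Anscombe) and the result carries attribute
#' `haldane = TRUE`.
#'
#' @param t A [make_table()] result.
#' @return Odds ratio (positive scalar).
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  v <- haldane(t)
  out <- (v[1] * v[4]) / (v[2] * v[3])
  names(out) <- NULL
  if (isTRUE(attr(v, "haldane"))) attr(out, "haldane") <- TRUE
  out
}

#' Woolf confidence interval for the odds ratio
#'
#' Wald-type interval on the log odds ratio:
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param t A [make_table()] result.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
woolf_ci <- function(t, level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)", call. = FALSE)
  }
  v <- haldane(t)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- log((v[1] * v[4]) / (v[2] * v[3]))
  hw <- z * sqrt(sum(1 / v))
  out <- exp(c(low = lo - hw, high = lo + hw))
  names(out) <- c("low", "high")
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' Closed-form statistic `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1
#' degree of freedom; the Yates continuity correction subtracts `N/2` from
#' `|ad - bc|` when requested (off by default).
#'
#' @param t A [make_table()] result.
#' @param continuity_correction Apply the Yates correction (default
#'   `FALSE`).
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_test <- function(t, continuity_correction = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  v <- as.numeric(unclass(t))
  a <- v[1]; b <- v[2]; c <- v[3]; d <- v[4]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin; test undefined", call. = FALSE)
  num <- abs(a * d - b * c)
  if (continuity_correction) num <- max(num - n / 2, 0)
  stat <- n * num^2 / prod(margins)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Crude effect estimate for a 2x2 table
#'
#' Bundles [odds_ratio()], [woolf_ci()] and [chi_square_test()].
#'
#' @param t A [make_table()] result.
#' @param level Confidence level.
#' @param continuity_correction Passed to [chi_square_test()].
#' @return An object of class `effect_estimate`: list with `odds_ratio`,
#'   `ci_low`, `ci_high`, `chi_square_statistic`, `p_value`.
#' @export
effect_estimate <- function(t, level = 0.95, continuity_correction = FALSE) {
  or <- odds_ratio(t)
  ci <- woolf_ci(t, level)
  cs <- chi_square_test(t, continuity_correction)
  structure(list(odds_ratio = as.numeric(or),
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 chi_square_statistic = cs$statistic,
                 p_value = cs$p_value,
                 haldane = isTRUE(attr(or, "haldane"))),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), chi-square %.2f, P = %.3f\n",
              x$odds_ratio, x$ci_low, x$ci_high,
              x$chi_square_statistic, x$p_value))
  invisible(x)
}

# round half-up to `digits` decimals (matches clinical-table presentation,
# unlike round()'s round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Event-rate formatting as printed in clinical outcome tables
#'
#' @param events,n Event count(s) and denominator(s).
#' @return Data frame with `events`, `n`, `percent` (half-up to 1 decimal
#'   place) and `formatted` (e.g. `"63/115 (54.8%)"`).
#' @export
outcome_rates <- function(events, n) {
  if (any(n <= 0)) stop("denominators must be positive", call. = FALSE)
  if (any(events > n) || any(events < 0)) {
    stop("events must lie in [0, n]", call. = FALSE)
  }
  pct <- round_half_up(100 * events / n, 1)
  data.frame(events = events, n = n, percent = pct,
             formatted = sprintf("%d/%d (%.1f%%)", events, n, pct),
             stringsAsFactors = FALSE)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit of a binary outcome on group membership
#' plus optional covariates, via Newton--Raphson on the log-likelihood
#' (IRLS). Convergence when the largest coefficient change is below 1e-8,
#' up to 100 iterations. The adjusted odds ratio is `exp` of the group
#' coefficient, with a Wald confidence interval from the inverse observed
#' information. Complete or quasi-complete separation is detected and
#' raised as an error rather than reported as a huge unstable estimate.
#'
#' @param records Data frame with a `group` column (two levels; the
#'   non-reference level is the "exposed" group, see `exposed`), the
#'   outcome flag column, and any covariate columns.
#' @param outcome Name of the logical/0-1 outcome column (e.g.
#'   `"clinical"`).
#' @param covariates Character vector of covariate column names (possibly
#'   empty, giving the crude OR).
#' @param exposed Level of `group` treated as exposed; default the last
#'   level alphabetically unless `group` is a factor.
#' @param level Confidence level for the Wald interval.
#' @return An object of class `logistic_fit`: list with `coefficients`
#'   (table with estimates, SEs, z, p), `odds_ratio`, `ci_low`, `ci_high`
#'   (for the group effect), `converged`, `iterations`.
#' @export
fit_logistic <- function(records, outcome, covariates = character(),
                         exposed = NULL, level = 0.95) {
  stopifnot(is.data.frame(records), outcome %in% names(records))
  if (!"group" %in% names(records)) stop("records need a 'group' column",
                                         call. = FALSE)
  g <- factor(records$group)
  if (nlevels(g) != 2L) stop("'group' must have exactly two levels",
                             call. = FALSE)
  if (!is.null(exposed)) g <- stats::relevel(g, ref = setdiff(levels(g), exposed))
  if (min(table(g)) < 2L) stop("need at least 2 records per group",
                               call. = FALSE)
  y <- as.numeric(records[[outcome]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  X <- cbind("(Intercept)" = 1, group = as.numeric(g) - 1)
  for (cv in covariates) X <- cbind(X, stats::setNames(
    as.numeric(records[[cv]]), NULL))
  colnames(X) <- c("(Intercept)", "group", covariates)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient",
                                 call. = FALSE)

  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(100L)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-10) && max(abs(beta)) > 15) break  # heading to separation
    info <- crossprod(X, X * w)
    score <- crossprod(X, y - mu)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) { converged <- TRUE; break }
  }
  if (!converged || max(abs(beta)) > 30) {
    stop("logistic fit did not converge (data may be separated)",
         call. = FALSE)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  vcov <- solve(crossprod(X, X * (mu * (1 - mu))))
  se <- sqrt(diag(vcov))
  z <- beta / se
  coef_tab <- data.frame(term = colnames(X), estimate = beta, se = se,
                         z = z, p_value = 2 * stats::pnorm(-abs(z)),
                         stringsAsFactors = FALSE)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  i <- match("group", coef_tab$term)
  structure(list(coefficients = coef_tab,
                 odds_ratio = unname(exp(beta[i])),
                 ci_low = unname(exp(beta[i] - zq * se[i])),
                 ci_high = unname(exp(beta[i] + zq * se[i])),
                 exposed_level = levels(g)[2],
                 converged = converged, iterations = it),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Adjusted OR (group = %s): %.2f (95%% CI %.2f-%.2f)\n",
              x$exposed_level, x$odds_ratio, x$ci_low, x$ci_high))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Render a clinical-outcomes comparison table
#'
#' Builds the standard three-row outcome comparison (positive hCG,
#' biochemical pregnancy, clinical pregnancy) between an exposed and a
#' comparison group from nested outcome counts. Biochemical pregnancies
#' are conditioned on positive hCG (their denominator is the hCG-positive
#' count), as conventional in transfer-outcome tables.
#'
#' @param exposed Named list/vector with `n`, `hcg`, `biochemical`,
#'   `clinical` counts for the exposed group.
#' @param unexposed Same for the comparison group.
#' @return Data frame, one row per outcome, with formatted rates, OR,
#'   Woolf CI, chi-square statistic and p-value.
#' @examples
#' outcome_table(list(n = 115, hcg = 73, biochemical = 10, clinical = 63),
#'               list(n = 272, hcg = 140, biochemical = 35, clinical = 105))
#' @export
outcome_table <- function(exposed, unexposed) {
  need <- c("n", "hcg", "biochemical", "clinical")
  stopifnot(all(need %in% names(exposed)), all(need %in% names(unexposed)))
  rows <- list(
    list(name = "Positive hCG",
         e = exposed$hcg, ne = exposed$n,
         u = unexposed$hcg, nu = unexposed$n),
    list(name = "Biochemical pregnancy",
         e = exposed$biochemical, ne = exposed$hcg,
         u = unexposed$biochemical, nu = unexposed$hcg),
    list(name = "Clinical pregnancy",
         e = exposed$clinical, ne = exposed$n,
         u = unexposed$clinical, nu = unexposed$n))
  do.call(rbind, lapply(rows, function(r) {
    t <- make_table(r$e, r$ne, r$u, r$nu)
    est <- effect_estimate(t)
    data.frame(outcome = r$name,
               exposed = outcome_rates(r$e, r$ne)$formatted,
               unexposed = outcome_rates(r$u, r$nu)$formatted,
               odds_ratio = est$odds_ratio,
               ci_low = est$ci_low, ci_high = est$ci_high,
               chi_square = est$chi_square_statistic,
               p_value = est$p_value,
               stringsAsFactors = FALSE)
  }))
}
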
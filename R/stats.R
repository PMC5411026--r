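#' Type-I (sequential) ANOVA with eta-squared effect sizes
#'
#' Computes the sequential sum-of-squares decomposition of a fitted linear
#' model — each term's SS is the drop in residual SS when it is added after
#' all earlier terms, so the order of terms matters — together with the
#' eta-squared effect size of every term, `SS_term / SS_total`. The
#' decomposition is delegated to [stats::anova()] on the [stats::lm()] fit;
#' eta-squared and the total row are added here.
#'
#' @param fit An `lm` fit, or a formula (with `data`) to fit.
#' @param data Data frame, required when `fit` is a formula.
#' @param term_order Optional character vector giving the term order; the
#'   model is refitted with the terms rearranged. Must contain every term
#'   of the model.
#' @return A data frame with one row per term plus a `Residuals` row:
#'   `term`, `df`, `sum_sq`, `eta_sq`, `f_value`, `p_value`; the total SS
#'   is stored in the `total_ss` attribute.
#' @export
#' @examples
#' tab <- data.frame(x = rnorm(50), g = gl(2, 25))
#' tab$y <- tab$x + rnorm(50)
#' sequential_anova(y ~ x + g, data = tab)
sequential_anova <- function(fit, data = NULL, term_order = NULL) {
  if (inherits(fit, "formula")) {
    stopifnot(!is.null(data))
    fit <- stats::lm(fit, data = data)
  }
  stopifnot(inherits(fit, "lm"))
  terms_now <- attr(stats::terms(fit), "term.labels")
  if (!is.null(term_order)) {
    missing_terms <- setdiff(terms_now, term_order)
    if (length(missing_terms))
      stop("term_order omits model terms: ",
           paste(missing_terms, collapse = ", "))
    extra <- setdiff(term_order, terms_now)
    if (length(extra))
      stop("term_order contains unknown terms: ", paste(extra, collapse = ", "))
    f <- stats::reformulate(term_order,
                            response = all.vars(stats::formula(fit))[1])
    fit <- stats::update(fit, f)
  }
  a <- stats::anova(fit)
  ss <- a[["Sum Sq"]]
  total_ss <- sum(ss)
  out <- data.frame(term = rownames(a), df = a$Df, sum_sq = ss,
                    eta_sq = ss / total_ss, f_value = a[["F value"]],
                    p_value = a[["Pr(>F)"]], row.names = NULL)
  out$eta_sq[out$term == "Residuals"] <- NA_real_
  attr(out, "total_ss") <- total_ss
  attr(out, "fit") <- fit
  out
}

z_std <- function(x) (x - mean(x)) / stats::sd(x)

#' Linear model for the edge-cluster count
#'
#' Fits `n_c_edge ~ n_c0 + r_c0 + d_c0 + dose` by ordinary least squares
#' after z-standardising all four predictors (the inducer dose — or the
#' switching rate in simulated tables — enters numerically on its dose
#' scale), and returns the standardised coefficients together with the
#' sequential ANOVA in that term order.
#'
#' @param table A data frame with columns `n_c_edge`, `n_c0`, `r_c0_um`,
#'   `d_c0_um` and `dose` (inducer concentration or switching rate).
#' @return A list: `coefficients` (standardised), `anova` (from
#'   [sequential_anova()]), `fit`.
#' @export
fit_nc_edge_model <- function(table) {
  need <- c("n_c_edge", "n_c0", "r_c0_um", "d_c0_um", "dose")
  stopifnot(all(need %in% names(table)))
  if (nrow(table) < 20) stop("need at least 20 rows")
  d <- data.frame(n_c_edge = table$n_c_edge,
                  n_c0 = z_std(table$n_c0),
                  r_c0 = z_std(table$r_c0_um),
                  d_c0 = z_std(table$d_c0_um),
                  dose = z_std(table$dose))
  fit <- stats::lm(n_c_edge ~ n_c0 + r_c0 + d_c0 + dose, data = d)
  if (fit$rank < 5) stop("rank-deficient design")
  list(coefficients = stats::coef(fit), anova = sequential_anova(fit),
       fit = fit)
}

#' Experimental outcome model: final fraction on initial-condition metrics
#'
#' Fits the full main-effects plus pairwise-interaction model of the final
#' C fraction on the inducer dose (categorical), the edge-cluster count and
#' the three spatial initial metrics (continuous), with sequential term
#' order dose, n_c_edge, n_c0, d_c0, r_c0, then the interactions grouped by
#' their first factor in that same order.
#'
#' @param table Data frame with columns `f_c`, `dose`, `n_c_edge`, `n_c0`,
#'   `d_c0_um`, `r_c0_um`.
#' @return A list: `anova`, `fit`.
#' @export
fit_fc_model_experimental <- function(table) {
  need <- c("f_c", "dose", "n_c_edge", "n_c0", "d_c0_um", "r_c0_um")
  stopifnot(all(need %in% names(table)))
  d <- data.frame(f_c = table$f_c, dose = factor(table$dose),
                  n_c_edge = as.numeric(table$n_c_edge),
                  n_c0 = as.numeric(table$n_c0),
                  d_c0 = as.numeric(table$d_c0_um),
                  r_c0 = as.numeric(table$r_c0_um))
  if (any(table(d$dose) == 0)) stop("empty dose level")
  fit <- stats::lm(
    f_c ~ dose + n_c_edge + n_c0 + d_c0 + r_c0 +
      dose:n_c_edge + dose:n_c0 + dose:d_c0 + dose:r_c0 +
      n_c_edge:n_c0 + n_c_edge:d_c0 + n_c_edge:r_c0 +
      n_c0:d_c0 + n_c0:r_c0 + d_c0:r_c0,
    data = d)
  list(anova = sequential_anova(fit), fit = fit)
}

#' Simulation outcome model: final fraction on switching rate, edge
#' clusters and initial condition
#'
#' Fits the three-factor model of the final C fraction on the switching
#' rate, the edge-cluster count and the initial-condition label — all
#' categorical — with pairwise interactions, in the sequential order
#' s_c, n_c_edge, ic, then s_c:n_c_edge, s_c:ic, n_c_edge:ic.
#'
#' @param table Data frame with columns `f_c`, `s_c`, `n_c_edge`, `ic`.
#' @return A list: `anova`, `fit`.
#' @export
fit_fc_model_simulation <- function(table) {
  need <- c("f_c", "s_c", "n_c_edge", "ic")
  stopifnot(all(need %in% names(table)))
  d <- data.frame(f_c = table$f_c, s_c = factor(table$s_c),
                  n_c_edge = factor(table$n_c_edge), ic = factor(table$ic))
  for (v in c("s_c", "n_c_edge", "ic"))
    if (any(table(d[[v]]) == 0)) stop("empty level in ", v)
  fit <- stats::lm(f_c ~ s_c + n_c_edge + ic +
                     s_c:n_c_edge + s_c:ic + n_c_edge:ic, data = d)
  list(anova = sequential_anova(fit), fit = fit)
}

#' Outcome distribution over the four competition classes
#'
#' @param outcomes Character vector of outcome classes (as returned by
#'   [classify_outcome()]).
#' @return A data frame with `outcome`, `count`, `proportion` for all four
#'   classes (zero counts included).
#' @export
#' @examples
#' outcome_distribution(c("c_domination", "coexistence", "c_domination"))
outcome_distribution <- function(outcomes) {
  stopifnot(length(outcomes) > 0)
  classes <- c("c_domination", "s_domination", "coexistence", "extinction")
  bad <- setdiff(unique(outcomes), classes)
  if (length(bad)) stop("unknown outcome classes: ", paste(bad, collapse = ", "))
  counts <- table(factor(outcomes, levels = classes))
  data.frame(outcome = classes, count = as.integer(counts),
             proportion = as.numeric(counts) / length(outcomes))
}

#' Time-averaged across-replicate variance of the C fraction
#'
#' At every recorded time point, computes the across-replicate variance of
#' the C-lineage fraction of the colonized area (population convention,
#' divide by n) and returns the average over time. Decreasing values with
#' increasing inoculation density indicate more reproducible dynamics.
#'
#' @param trajectories A list of `competition_trajectory` objects on a
#'   common recording grid, or a replicates x times numeric matrix of C
#'   fractions.
#' @return A single number.
#' @export
fc_variance_over_time <- function(trajectories) {
  if (is.matrix(trajectories)) {
    mat <- trajectories
  } else {
    stopifnot(length(trajectories) >= 2)
    grids <- lapply(trajectories, function(tr) tr$areas$time_h)
    if (!all(vapply(grids[-1], function(g) isTRUE(all.equal(g, grids[[1]])),
                    logical(1))))
      stop("trajectories are not on a common time grid")
    mat <- t(vapply(trajectories, function(tr) {
      a <- tr$areas
      tot <- a$n_c + a$n_con + a$n_x + a$n_xstop
      ifelse(tot > 0, (a$n_c + a$n_con) / tot, 0)
    }, numeric(length(grids[[1]]))))
  }
  if (nrow(mat) < 2) stop("need at least 2 replicates")
  pop_var <- function(x) mean((x - mean(x))^2)
  mean(apply(mat, 2, pop_var))
}
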
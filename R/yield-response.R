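## Polynomial fixed-effects yield response model.
##
## Yield is regressed on orthogonal polynomial expansions of the continuous
## covariates plus binary covariates and year / agro-ecological-zone fixed
## effects. Polynomial orders are chosen per covariate by forward nested
## F-tests. The orthogonalisation data of every polynomial basis is frozen
## in the fitted object so that predictions (and JSON round-trips) rebuild
## the training design exactly.

#' Yield model specification
#'
#' Names the response, the continuous covariates entering as orthogonal
#' polynomials, the binary covariates, the fixed-effect factors, the
#' maximum polynomial order and the significance level of the nested-ANOVA
#' order search.
#'
#' @param continuous Continuous covariate names.
#' @param binary Binary (0/1) covariate names.
#' @param fixed Fixed-effect column names (default year and zone).
#' @param max_order Maximum polynomial order per covariate (>= 1).
#' @param alpha Significance level for order selection, in (0, 1]; the
#'   order is increased while the nested F-test has p < alpha.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(continuous = c("PH", "Fert", "CEC", "SOC", "SND",
                                      "PDSI", "Elevation", "Ext.Area",
                                      "Imp.Seed", "Irg.Area", "Damage",
                                      "DistPP"),
                       binary = c("PSNP", "AGP"),
                       fixed = c("year", "agro_eco_zone"),
                       max_order = 4, alpha = 0.05) {
  check_number(max_order, "max_order", lower = 1)
  check_number(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  if (!length(continuous)) stop("'continuous' must be non-empty",
                                call. = FALSE)
  structure(list(continuous = continuous, binary = binary, fixed = fixed,
                 max_order = as.integer(max_order), alpha = alpha),
            class = "model_spec")
}

safe_name <- function(v) gsub("[^A-Za-z0-9]", "_", v)

## expand one covariate into its orthogonal polynomial columns; 'coefs'
## freezes the centering/orthogonalisation so new data reuse the training
## basis
poly_cols <- function(x, degree, coefs = NULL, name) {
  p <- if (is.null(coefs)) stats::poly(x, degree = degree) else
    stats::poly(x, degree = degree, coefs = coefs)
  m <- unclass(p)[, seq_len(degree), drop = FALSE]
  colnames(m) <- paste0(safe_name(name), "_", seq_len(degree))
  list(cols = m, coefs = attr(p, "coefs"))
}

## build the model frame (expanded columns + factors) and, unless frozen,
## the basis
build_frame <- function(panel, spec, orders, basis = NULL, fe = NULL) {
  out <- list()
  new_basis <- list()
  for (v in spec$continuous) {
    k <- orders[[v]]
    pc <- poly_cols(panel[[v]], k, coefs = basis[[v]]$coefs, name = v)
    out[[v]] <- pc$cols
    new_basis[[v]] <- list(degree = k, coefs = pc$coefs)
  }
  dd <- as.data.frame(do.call(cbind, out))
  for (v in spec$binary) dd[[safe_name(v)]] <- panel[[v]]
  if (length(spec$fixed) >= 1) {
    lev <- fe$year_levels %||% sort(unique(panel[[spec$fixed[1]]]))
    dd$year_f <- factor(panel[[spec$fixed[1]]], levels = lev)
  }
  if (length(spec$fixed) >= 2) {
    lev <- fe$zone_levels %||% sort(unique(panel[[spec$fixed[2]]]))
    dd$zone_f <- factor(panel[[spec$fixed[2]]], levels = lev)
  }
  list(frame = dd, basis = new_basis)
}

## design matrix in the exact column order of the lm fit
design_matrix <- function(object, newdata) {
  bf <- build_frame(newdata, object$spec, object$orders,
                    basis = object$basis, fe = object$fe)
  dd <- bf$frame
  if (anyNA(dd)) {
    stop("newdata produced missing values in the design ",
         "(unknown fixed-effect level?)", call. = FALSE)
  }
  num_cols <- setdiff(names(dd), c("year_f", "zone_f"))
  X <- cbind(`(Intercept)` = 1, as.matrix(dd[num_cols]))
  if (!is.null(dd$year_f)) {
    lev <- levels(dd$year_f)
    for (l in lev[-1]) {
      X <- cbind(X, as.numeric(dd$year_f == l))
      colnames(X)[ncol(X)] <- paste0("year_f", l)
    }
  }
  if (!is.null(dd$zone_f)) {
    lev <- levels(dd$zone_f)
    for (l in lev[-1]) {
      X <- cbind(X, as.numeric(dd$zone_f == l))
      colnames(X)[ncol(X)] <- paste0("zone_f", l)
    }
  }
  X
}

check_fe_cells <- function(panel, spec) {
  if (length(spec$fixed) < 2) return(invisible())
  cells <- table(panel[[spec$fixed[1]]], panel[[spec$fixed[2]]])
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop(sprintf("empty fixed-effect cell(s): %s",
                 paste(rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]],
                       sep = "/", collapse = ", ")), call. = FALSE)
  }
}

#' Select polynomial orders by nested ANOVA
#'
#' For each continuous covariate independently (all other covariates held
#' at first order), the order is grown forward: order k+1 is accepted if
#' and only if the nested F-test of the model with order k+1 for that
#' covariate against the model with order k rejects at `alpha`; the search
#' stops at the first non-rejection or at `max_order`.
#'
#' @param panel Sub-kebele panel (already restricted to one crop).
#' @param spec A [model_spec()].
#' @param covariates Covariates to search over (default all continuous
#'   ones; others are fixed at order 1).
#' @return Named integer vector of selected orders, one per continuous
#'   covariate.
#' @export
select_orders <- function(panel, spec = model_spec(),
                          covariates = spec$continuous) {
  check_columns(panel, c("Yield", spec$continuous, spec$binary,
                         spec$fixed))
  orders <- setNames(rep(1L, length(spec$continuous)), spec$continuous)
  fit_with <- function(orders) {
    bf <- build_frame(panel, spec, as.list(orders))
    dd <- bf$frame
    dd$Yield <- panel$Yield
    lm(Yield ~ ., data = dd)
  }
  for (v in covariates) {
    k <- 1L
    trial <- orders
    m_k <- fit_with(trial)
    while (k < spec$max_order) {
      trial[v] <- k + 1L
      m_k1 <- fit_with(trial)
      p <- anova(m_k, m_k1)[2, "Pr(>F)"]
      if (is.na(p) || p >= spec$alpha) break
      k <- k + 1L
      m_k <- m_k1
    }
    orders[v] <- k
  }
  orders
}

#' Fit the polynomial fixed-effects yield response model
#'
#' Ordinary least squares of yield on orthogonal polynomial expansions of
#' the continuous covariates, the binary covariates, and year and
#' agro-ecological-zone fixed effects. Polynomial orders are selected by
#' [select_orders()] unless supplied. The fitted object freezes the
#' polynomial bases, covariate means and training ranges, so predictions
#' are reproducible from the object alone (see [write_model_json()]).
#'
#' @param panel Sub-kebele panel data.frame.
#' @param crop Optional crop to subset on (`panel$crop`); crops are
#'   modelled separately.
#' @param spec A [model_spec()].
#' @param orders Named vector of polynomial orders; `NULL` (default)
#'   selects them by nested ANOVA.
#' @param fe_ref Reference fixed-effect cell `c(year, zone)` used by
#'   marginal curves; default the most populous cell.
#' @return An object of class `yield_response` with methods `print`,
#'   `summary`, `coef`, `vcov`, `predict`, `fitted`, `residuals`,
#'   `simulate` and `plot`.
#' @examples
#' cfg <- synth_config(n_subkebeles = 60, seed = 42)
#' panel <- generate_panel(cfg)
#' fit <- yield_response(panel, crop = "wheat",
#'                       orders = c(PH = 2, Fert = 2))
#' fit
#' @export
yield_response <- function(panel, crop = NULL, spec = model_spec(),
                           orders = NULL, fe_ref = NULL) {
  cl <- match.call()
  if (!is.null(crop)) {
    check_columns(panel, "crop")
    panel <- panel[panel$crop == crop, , drop = FALSE]
    if (!nrow(panel)) stop(sprintf("no rows for crop '%s'", crop),
                           call. = FALSE)
  }
  check_columns(panel, c("Yield", spec$continuous, spec$binary,
                         spec$fixed))
  keep <- complete.cases(panel[c("Yield", spec$continuous, spec$binary,
                                 spec$fixed)])
  panel <- panel[keep, , drop = FALSE]
  check_fe_cells(panel, spec)

  if (is.null(orders)) {
    orders <- select_orders(panel, spec)
  } else {
    full <- setNames(rep(1L, length(spec$continuous)), spec$continuous)
    full[names(orders)] <- as.integer(orders)
    orders <- full
  }
  n_par <- 1 + sum(orders) + length(spec$binary) +
    length(unique(panel[[spec$fixed[1]]])) - 1 +
    length(unique(panel[[spec$fixed[2]]])) - 1
  if (nrow(panel) < n_par + 10) {
    stop(sprintf("panel too small: %d rows for %d parameters",
                 nrow(panel), n_par), call. = FALSE)
  }

  bf <- build_frame(panel, spec, as.list(orders))
  dd <- bf$frame
  dd$Yield <- panel$Yield
  rhs <- setdiff(names(dd), "Yield")
  ## single-level factors (e.g. one zone) carry no dummies
  rhs <- rhs[vapply(rhs, function(v)
    !is.factor(dd[[v]]) || nlevels(dd[[v]]) > 1, logical(1))]
  form <- as.formula(paste("Yield ~", paste(rhs, collapse = " + ")))
  fit <- lm(form, data = dd)

  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }

  fe <- list(year_levels = levels(dd$year_f),
             zone_levels = levels(dd$zone_f))
  if (is.null(fe_ref)) {
    cells <- table(panel[[spec$fixed[1]]], panel[[spec$fixed[2]]])
    top <- which(cells == max(cells), arr.ind = TRUE)[1, ]
    fe_ref <- c(rownames(cells)[top[1]], colnames(cells)[top[2]])
  }
  fe$ref_year <- fe_ref[1]
  fe$ref_zone <- fe_ref[2]
  ## sample shares of the dummy levels, for "average hectare" baselines
  fe$year_shares <- as.vector(table(factor(panel[[spec$fixed[1]]],
                                           levels = fe$year_levels))) /
    nrow(panel)
  names(fe$year_shares) <- fe$year_levels
  fe$zone_shares <- as.vector(table(factor(panel[[spec$fixed[2]]],
                                           levels = fe$zone_levels))) /
    nrow(panel)
  names(fe$zone_shares) <- fe$zone_levels

  covars <- c(spec$continuous, spec$binary)
  means <- vapply(covars, function(v) mean(panel[[v]]), numeric(1))
  ranges <- vapply(spec$continuous,
                   function(v) range(panel[[v]]), numeric(2))
  smry <- summary(fit)

  obj <- structure(list(
    coefficients = coef(fit),
    vcov = vcov(fit),
    sigma = smry$sigma,
    df_residual = fit$df.residual,
    r_squared = smry$r.squared,
    adj_r_squared = smry$adj.r.squared,
    orders = orders,
    basis = bf$basis,
    spec = spec,
    crop = crop,
    means = means,
    ranges = ranges,
    fert_cap = unname(quantile(panel$Fert, 0.99)),
    fe = fe,
    n = nrow(panel),
    fitted_values = unname(fitted(fit)),
    residuals_values = unname(residuals(fit)),
    call = cl
  ), class = "yield_response")

  ## the stored basis must reproduce the lm design exactly
  X <- design_matrix(obj, panel)
  stopifnot(identical(colnames(X), names(obj$coefficients)))
  obj
}

## complete a newdata frame: training means, reference fixed-effect cell,
## then user overrides
newdata_rows <- function(object, n = 1, overrides = list()) {
  nd <- as.data.frame(as.list(object$means))
  names(nd) <- names(object$means)
  nd <- nd[rep(1, n), , drop = FALSE]
  fx <- object$spec$fixed
  nd[[fx[1]]] <- object$fe$ref_year
  nd[[fx[2]]] <- object$fe$ref_zone
  for (v in names(overrides)) nd[[v]] <- overrides[[v]]
  rownames(nd) <- NULL
  nd
}

#' @export
predict.yield_response <- function(object, newdata = NULL,
                                   se.fit = FALSE,
                                   interval = c("none", "confidence"),
                                   level = 0.95, ...) {
  interval <- match.arg(interval)
  if (is.null(newdata)) {
    if (is.null(object$fitted_values)) {
      stop("no newdata and no stored fitted values", call. = FALSE)
    }
    return(object$fitted_values)
  }
  ## absent covariates sit at their training means, fixed effects at the
  ## reference cell
  nd <- newdata_rows(object, n = nrow(as.data.frame(newdata)))
  newdata <- as.data.frame(newdata)
  for (v in names(newdata)) nd[[v]] <- newdata[[v]]
  X <- design_matrix(object, nd)
  fit <- drop(X %*% object$coefficients)
  if (!se.fit && interval == "none") return(fit)
  se <- sqrt(pmax(rowSums((X %*% object$vcov) * X), 0))
  if (interval == "confidence") {
    tq <- qt(1 - (1 - level) / 2, object$df_residual)
    out <- cbind(fit = fit, lwr = fit - tq * se, upr = fit + tq * se)
    if (se.fit) return(list(fit = out, se.fit = se))
    return(out)
  }
  list(fit = fit, se.fit = se)
}

#' @export
coef.yield_response <- function(object, ...) object$coefficients

#' @export
vcov.yield_response <- function(object, ...) object$vcov

#' @export
fitted.yield_response <- function(object, ...) object$fitted_values

#' @export
residuals.yield_response <- function(object, ...) object$residuals_values

#' @export
simulate.yield_response <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(object$fitted_values)) {
    stop("simulate needs the training fitted values ",
         "(not preserved through JSON round-trips)", call. = FALSE)
  }
  n <- length(object$fitted_values)
  out <- as.data.frame(replicate(
    nsim, pmax(object$fitted_values + rnorm(n, 0, object$sigma), 0)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.yield_response <- function(x, ...) {
  cat("Polynomial fixed-effects yield response model\n")
  if (!is.null(x$crop)) cat(sprintf("  crop: %s\n", x$crop))
  cat(sprintf("  n = %d, adj. R-squared = %.3f, residual sd = %.3f mt/ha\n",
              x$n, x$adj_r_squared, x$sigma))
  cat("  polynomial orders:\n")
  ord <- x$orders
  cat(sprintf("    %s\n",
              paste(sprintf("%s:%d", names(ord), ord), collapse = "  ")))
  cat(sprintf("  fixed effects: %s (reference %s/%s)\n",
              paste(x$spec$fixed, collapse = " + "),
              x$fe$ref_year, x$fe$ref_zone))
  invisible(x)
}

#' @export
summary.yield_response <- function(object, ...) {
  est <- object$coefficients
  se <- sqrt(diag(object$vcov))
  tval <- est / se
  pval <- 2 * pt(-abs(tval), object$df_residual)
  stars <- ifelse(pval < 0.01, "***",
                  ifelse(pval < 0.05, "**", ifelse(pval < 0.1, "*", "")))
  tab <- data.frame(Estimate = est, `Std. Error` = se, `t value` = tval,
                    `Pr(>|t|)` = pval, ` ` = stars,
                    check.names = FALSE)
  structure(list(table = tab, model = object),
            class = "summary.yield_response")
}

#' @export
print.summary.yield_response <- function(x, ...) {
  print(x$model)
  cat("\nCoefficients:\n")
  tab <- x$table
  tab$Estimate <- signif(tab$Estimate, 5)
  tab$`Std. Error` <- signif(tab$`Std. Error`, 4)
  tab$`t value` <- round(tab$`t value`, 2)
  tab$`Pr(>|t|)` <- signif(tab$`Pr(>|t|)`, 3)
  print(tab)
  cat("Signif.: '***' p<0.01, '**' p<0.05, '*' p<0.1\n")
  invisible(x)
}

#' @export
plot.yield_response <- function(x, vary = "PH", ...) {
  plot(marginal_curve(x, vary), ...)
}
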
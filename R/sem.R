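# Observed-variable path analysis: recursive models fitted by maximum
# likelihood (per-equation least squares, which is the ML solution for
# recursive systems with uncorrelated disturbances), with likelihood-ratio
# chi-square against the saturated model, RMSEA, standardized coefficients
# and per-endogenous r-squared.

#' Define a recursive path model
#'
#' @param edges Two-column data.frame (`from`, `to`) of directed paths.
#' @param exogenous Optional character vector naming exogenous variables;
#'   defaults to all variables that never appear as `to`. Exogenous
#'   variables are allowed to covary freely.
#' @return A `path_model`: list with `edges`, `variables` (topologically
#'   ordered), `exogenous`, `endogenous`.
#' @export
path_model <- function(edges, exogenous = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  abort_if(!all(c("from", "to") %in% names(edges)),
           "path_model: edges need columns from, to")
  vars <- unique(c(edges$from, edges$to))
  # Kahn topological sort; cycle check
  order <- character(0)
  pending <- vars
  while (length(pending) > 0) {
    active <- edges[edges$from %in% pending & edges$to %in% pending, , drop = FALSE]
    has_parent <- pending %in% active$to
    abort_if(all(has_parent), "path_model: model is cyclic")
    roots <- pending[!has_parent]
    order <- c(order, roots)
    pending <- setdiff(pending, roots)
  }
  endo <- unique(edges$to)
  exo_default <- setdiff(vars, endo)
  if (is.null(exogenous)) {
    exogenous <- exo_default
  } else {
    abort_if(!all(exo_default %in% exogenous) ||
               any(exogenous %in% endo),
             "path_model: exogenous set inconsistent with edges")
  }
  structure(list(edges = edges, variables = order,
                 exogenous = exogenous, endogenous = order[order %in% endo]),
            class = "path_model")
}

#' The default nutrient-input path model
#'
#' N and P input indicators (0/1, freely covarying) act on soil pH and the
#' soil N:P ratio, which in turn act on the three gene-category total
#' abundances: `cat_regulation` (P-starvation response regulation),
#' `cat_solubilization` (inorganic-P solubilization / organic-P
#' mineralization) and `cat_transport` (P uptake and transport).
#'
#' @return A `path_model`.
#' @export
nutrient_path_model <- function() {
  edges <- rbind(
    expand.grid(from = c("N_input", "P_input"), to = c("pH", "NP_ratio"),
                stringsAsFactors = FALSE),
    expand.grid(from = c("pH", "NP_ratio"),
                to = c("cat_regulation", "cat_solubilization", "cat_transport"),
                stringsAsFactors = FALSE))
  path_model(edges)
}

#' Fit a recursive path model by maximum likelihood
#'
#' Estimates each endogenous variable's equation by least squares on
#' standardized data (the ML solution for recursive models with
#' uncorrelated disturbances), assembles the model-implied covariance, and
#' reports the likelihood-ratio chi-square `(n - 1) * F_ML` against the
#' saturated model with `df = p(p+1)/2 - #free parameters`, the RMSEA,
#' standardized path coefficients with t-test p-values, and r-squared per
#' endogenous variable.
#'
#' @param data data.frame or matrix, samples x variables, no missing values.
#' @param model A `path_model`.
#' @return A `path_fit`: list with `coefficients` (from, to, estimate, se,
#'   p, significant), `chi_square`, `df`, `chi_p`, `rmsea`, `r2`, `n`.
#' @export
fit_path_model <- function(data, model) {
  stopifnot(inherits(model, "path_model"))
  data <- as.data.frame(data)
  vars <- model$variables
  missing <- setdiff(vars, names(data))
  abort_if(length(missing) > 0, "fit_path_model: data lacks variable(s) ",
           paste(missing, collapse = ", "))
  data <- data[, vars, drop = FALSE]
  abort_if(anyNA(data), "fit_path_model: missing values not allowed")
  n <- nrow(data)
  p <- length(vars)
  abort_if(n <= p, "fit_path_model: need n > number of variables")
  sds <- vapply(data, stats::sd, 0)
  abort_if(any(sds == 0), "fit_path_model: constant variable(s) ",
           paste(vars[sds == 0], collapse = ", "))
  z <- as.data.frame(scale(data))
  s_obs <- stats::cov(z) * (n - 1) / n      # ML (biased) covariance
  abort_if(abs(det(s_obs)) < 1e-12, "fit_path_model: singular covariance")

  bmat <- matrix(0, p, p, dimnames = list(vars, vars))  # B[to, from]
  psi <- matrix(0, p, p, dimnames = list(vars, vars))
  exo <- model$exogenous
  psi[exo, exo] <- s_obs[exo, exo, drop = FALSE]
  coefs <- NULL
  r2 <- stats::setNames(numeric(length(model$endogenous)), model$endogenous)
  for (v in model$endogenous) {
    parents <- model$edges$from[model$edges$to == v]
    fml <- stats::reformulate(parents, response = v)
    fit <- stats::lm(fml, data = z)
    sm <- summary(fit)$coefficients
    est <- stats::coef(fit)[parents]
    bmat[v, parents] <- est
    resid_var <- sum(stats::resid(fit)^2) / n
    psi[v, v] <- resid_var
    r2[v] <- summary(fit)$r.squared
    coefs <- rbind(coefs, data.frame(
      from = parents, to = v,
      estimate = unname(est),
      se = unname(sm[parents, "Std. Error"]),
      p = unname(sm[parents, "Pr(>|t|)"]),
      stringsAsFactors = FALSE))
  }
  imat <- diag(p)
  inv <- solve(imat - bmat)
  sigma <- inv %*% psi %*% t(inv)
  f_ml <- as.numeric(determinant(sigma, logarithm = TRUE)$modulus -
                       determinant(s_obs, logarithm = TRUE)$modulus +
                       sum(diag(s_obs %*% solve(sigma))) - p)
  f_ml <- max(f_ml, 0)
  chi_square <- (n - 1) * f_ml
  k_ex <- length(exo)
  n_free <- nrow(model$edges) + k_ex * (k_ex + 1) / 2 + length(model$endogenous)
  df <- p * (p + 1) / 2 - n_free
  chi_p <- if (df > 0) stats::pchisq(chi_square, df, lower.tail = FALSE) else NA_real_
  coefs$significant <- coefs$p < 0.05
  structure(list(coefficients = coefs,
                 chi_square = chi_square, df = df, chi_p = chi_p,
                 rmsea = if (df > 0) rmsea(chi_square, df, n) else NA_real_,
                 r2 = r2, n = n,
                 implied_cov = sigma, observed_cov = s_obs),
            class = "path_fit")
}

#' Root mean square error of approximation
#'
#' `sqrt(max(0, chi_square - df) / (df * (n - 1)))`; values below 0.05
#' conventionally indicate close fit.
#'
#' @param chi_square Model chi-square.
#' @param df Model degrees of freedom (>= 1).
#' @param n Sample size (>= 2).
#' @return RMSEA value.
#' @export
rmsea <- function(chi_square, df, n) {
  abort_if(df < 1, "rmsea: undefined for df = 0")
  abort_if(n < 2, "rmsea: need n >= 2")
  sqrt(max(0, chi_square - df) / (df * (n - 1)))
}

#' @export
print.path_fit <- function(x, ...) {
  cat("path model fit: chi-square =", format(x$chi_square, digits = 4),
      "(df =", x$df, ", p =", format(x$chi_p, digits = 3),
      "), RMSEA =", format(x$rmsea, digits = 3), ", n =", x$n, "\n")
  print(x$coefficients, digits = 3)
  cat("r2:", paste(names(x$r2), format(x$r2, digits = 2), sep = " = ",
                   collapse = ", "), "\n")
  invisible(x)
}
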
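#' Linear mixed model for the 2x2 crossover outcome
#'
#' Fits the crossover model
#' `y = b0 + b_seq + b_drug + b_period + u_subject + e`,
#' with `u ~ N(0, sigma_u^2)` (random intercept for each participant,
#' nested in sequence) and `e ~ N(0, sigma^2)`, to one observation per
#' subject x drug. The outcome is the percent change in aqueous-column
#' width from the same-drug baseline at the chosen timepoint (raw width is
#' available via `outcome = "width"`). Estimation is restricted maximum
#' likelihood, profiled to a 1-D optimization over the variance ratio
#' `lambda = sigma_u^2 / sigma^2`; the drug-effect p-value is a two-sided
#' Wald test against the normal reference (no small-sample df correction,
#' a documented limitation).
#'
#' @param table long-format measurement table with columns `subject_id`,
#'   `sequence`, `period`, `drug`, `timepoint`, `width_px` (e.g. from
#'   [render_crossover_study()]).
#' @param outcome `"percent_change_width"` (default) or `"width"`.
#' @param timepoint which post-instillation timepoint to analyze.
#' @return an object of class `crossover_lmm` with components
#'   `coefficients`, `se`, `vcov`, `sigma_u2`, `sigma_e2`, `lambda`,
#'   `p_drug`, `converged`, `reml_criterion`, `data` (the analysis rows),
#'   `fitted`, `residuals`.
#' @examples
#' study <- render_crossover_study(seed = 7)
#' fit <- fit_crossover_lmm(study$table)
#' summary(fit)
#' @export
fit_crossover_lmm <- function(table,
                              outcome = c("percent_change_width", "width"),
                              timepoint = "2h") {
  outcome <- match.arg(outcome)
  req <- c("subject_id", "sequence", "period", "drug", "timepoint", "width_px")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols) > 0)
    stop_aquacol(paste("measurement table is missing column(s):",
                       paste(missing_cols, collapse = ", ")),
                 "aquacol_schema_error")
  if (length(unique(table$sequence)) < 2)
    stop_aquacol("both crossover sequences must be represented",
                 "aquacol_design_error")

  dat <- build_outcome_rows(table, outcome, timepoint)
  n_per_seq <- tapply(dat$subject_id, dat$sequence,
                      function(s) length(unique(s)))
  if (any(is.na(n_per_seq)) || any(n_per_seq < 2))
    stop_aquacol("need at least 2 subjects per sequence",
                 "aquacol_design_error")

  y <- dat$y
  X <- cbind(`(Intercept)` = 1,
             sequence = as.numeric(dat$sequence ==
                                     "latanoprost-ripasudil"),
             drug = as.numeric(dat$drug == "ripasudil"),
             period = as.numeric(dat$period == 2))
  subj <- factor(dat$subject_id)
  Z <- stats::model.matrix(~ subj - 1)
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p)
    stop_aquacol("singular fixed-effects design", "aquacol_design_error")

  # REML criterion profiled over lambda = sigma_u^2 / sigma_e^2
  ZZt <- tcrossprod(Z)
  reml_pieces <- function(lambda) {
    H <- diag(n) + lambda * ZZt
    ch <- chol(H)
    Hi_X <- backsolve(ch, forwardsolve(t(ch), X))
    Hi_y <- backsolve(ch, forwardsolve(t(ch), y))
    XtHiX <- crossprod(X, Hi_X)
    beta <- solve(XtHiX, crossprod(X, Hi_y))
    r <- y - X %*% beta
    Hi_r <- backsolve(ch, forwardsolve(t(ch), r))
    q <- drop(crossprod(r, Hi_r))
    list(beta = drop(beta), q = q, logdetH = 2 * sum(log(diag(ch))),
         XtHiX = XtHiX)
  }
  neg_reml <- function(loglambda) {
    pc <- reml_pieces(exp(loglambda))
    s2 <- max(pc$q / (n - p), 1e-300)
    0.5 * ((n - p) * log(s2) + pc$logdetH +
             determinant(pc$XtHiX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(neg_reml, interval = c(-12, 12), tol = 1e-9)
  at_zero <- neg_reml(-50)  # effectively lambda = 0
  if (at_zero <= opt$objective) {
    lambda <- 0
    crit <- at_zero
  } else {
    lambda <- exp(opt$minimum)
    crit <- opt$objective
  }
  converged <- is.finite(crit) && (lambda == 0 || opt$minimum < 12 - 1e-3)

  pc <- reml_pieces(lambda)
  sigma_e2 <- pc$q / (n - p)
  sigma_u2 <- lambda * sigma_e2
  vc <- sigma_e2 * solve(pc$XtHiX)
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(vc), 0))
  beta <- stats::setNames(pc$beta, colnames(X))
  z_drug <- if (se[["drug"]] > 0) beta[["drug"]] / se[["drug"]] else
    sign(beta[["drug"]]) * Inf
  p_drug <- if (is.infinite(z_drug)) 0 else 2 * stats::pnorm(-abs(z_drug))
  if (beta[["drug"]] == 0 && se[["drug"]] == 0) p_drug <- 1

  fitted <- drop(X %*% beta)
  structure(list(coefficients = beta, se = se, vcov = vc,
                 sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, lambda = lambda,
                 p_drug = p_drug, converged = converged,
                 reml_criterion = -as.numeric(crit),
                 outcome = outcome, timepoint = timepoint,
                 data = dat, X = X, fitted = fitted,
                 residuals = y - fitted, n = n,
                 call = match.call()),
            class = "crossover_lmm")
}

# one analysis row per subject x drug: outcome at `timepoint`, with the
# same-drug baseline resolved per subject
build_outcome_rows <- function(table, outcome, timepoint) {
  base <- table[table$timepoint == "baseline", ]
  post <- table[table$timepoint == timepoint, ]
  if (nrow(post) == 0)
    stop_aquacol(sprintf("no rows at timepoint '%s'", timepoint),
                 "aquacol_schema_error")
  key <- function(d) paste(d$subject_id, d$drug, sep = "\r")
  bw <- stats::setNames(base$width_px, key(base))
  bmatch <- bw[key(post)]
  if (outcome == "percent_change_width") {
    if (any(is.na(bmatch)))
      stop_aquacol("missing same-drug baseline for some subjects",
                   "aquacol_schema_error")
    y <- percent_change(bmatch, post$width_px)
  } else {
    y <- post$width_px
  }
  data.frame(subject_id = post$subject_id, sequence = post$sequence,
             period = post$period, drug = post$drug, y = unname(y))
}

#' @export
print.crossover_lmm <- function(x, ...) {
  cat(sprintf("Crossover linear mixed model (REML), outcome = %s at %s\n",
              x$outcome, x$timepoint))
  cat("Fixed effects:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("sigma_u^2 = %.4g, sigma^2 = %.4g; drug effect p = %.4g%s\n",
              x$sigma_u2, x$sigma_e2, x$p_drug,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.crossover_lmm <- function(object, ...) {
  z <- object$coefficients / ifelse(object$se > 0, object$se, NA)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, sigma_u2 = object$sigma_u2,
              sigma_e2 = object$sigma_e2, p_drug = object$p_drug,
              converged = object$converged, n = object$n,
              outcome = object$outcome, timepoint = object$timepoint)
  class(out) <- "summary.crossover_lmm"
  out
}

#' @export
print.summary.crossover_lmm <- function(x, ...) {
  cat(sprintf("Crossover LMM (REML), outcome = %s at %s, n = %d\n",
              x$outcome, x$timepoint, x$n))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("Random intercept variance %.4g, residual variance %.4g\n",
              x$sigma_u2, x$sigma_e2))
  cat(sprintf("Drug effect (Wald) p = %.4g; converged: %s\n",
              x$p_drug, x$converged))
  invisible(x)
}

#' @export
coef.crossover_lmm <- function(object, ...) object$coefficients

#' @export
vcov.crossover_lmm <- function(object, ...) object$vcov

#' @export
residuals.crossover_lmm <- function(object, ...) object$residuals

#' @export
fitted.crossover_lmm <- function(object, ...) object$fitted

#' Fixed-effect predictions from a crossover LMM
#' @param object a [fit_crossover_lmm()] fit.
#' @param newdata optional data frame with `sequence`, `drug`, `period`;
#'   defaults to the analysis rows.
#' @param ... unused.
#' @return numeric vector of marginal (fixed-effect) predictions.
#' @export
predict.crossover_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- cbind(1, as.numeric(newdata$sequence == "latanoprost-ripasudil"),
             as.numeric(newdata$drug == "ripasudil"),
             as.numeric(newdata$period == 2))
  drop(X %*% object$coefficients)
}

#' Simulate outcomes from a fitted crossover LMM
#' @param object a [fit_crossover_lmm()] fit.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data frame with `nsim` columns, rows matching the analysis
#'   rows.
#' @export
simulate.crossover_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    subj <- factor(object$data$subject_id)
    u <- stats::rnorm(nlevels(subj), 0, sqrt(object$sigma_u2))
    object$fitted + u[as.integer(subj)] +
      stats::rnorm(object$n, 0, sqrt(object$sigma_e2))
  }
  run <- function() as.data.frame(replicate(nsim, draw()))
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.crossover_lmm <- function(x, ...) {
  graphics::plot(x$fitted, x$residuals,
                 xlab = "Fitted percent change", ylab = "Residual",
                 main = "Crossover LMM residuals", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
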
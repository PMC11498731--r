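## Integrated step-selection function: tentative gamma/von-Mises movement
## kernel, matched random steps, strata assembly over the covariate stack,
## conditional logistic regression by Newton-Raphson, AIC model comparison
## and relative selection strength.

#' Fit the tentative movement kernel
#'
#' ML gamma fit to the positive used step lengths and ML von Mises fit to
#' the defined turning angles.
#'
#' @param steps `step_series` of used steps.
#' @return list of class `movement_kernel`: shape, rate (gamma), mu, kappa
#'   (von Mises).
#' @export
fit_kernel <- function(steps) {
  s <- steps$step[is.finite(steps$step) & steps$step > 0]
  if (!length(s)) stop("all step lengths are zero; cannot fit a gamma kernel")
  a <- steps$angle[is.finite(steps$angle)]
  if (length(a) < 30) stop("need >= 30 steps with defined turning angles")
  g <- fit_gamma_mle(s)
  v <- fit_vonmises(a)
  structure(list(shape = g$shape, rate = g$rate, mu = v$mu,
                 kappa = v$kappa), class = "movement_kernel")
}

#' @export
print.movement_kernel <- function(x, ...) {
  cat(sprintf(
    "movement kernel: gamma(shape %.3f, rate %.3g; mean %.1f m), von Mises(mu %.2f, kappa %.3f)\n",
    x$shape, x$rate, x$shape / x$rate, x$mu, x$kappa))
  invisible(x)
}

#' Generate random candidate steps
#'
#' Draws `n` step lengths from the kernel's gamma and turns from its von
#' Mises, applies each turn to the previous step's bearing and projects
#' from the start point.
#'
#' @param x0,y0 step start coordinates (m).
#' @param prev_bearing bearing (rad) of the previous step.
#' @param kernel a `movement_kernel`.
#' @param n number of candidates (default 15).
#' @return data.frame: x, y, step, turn.
#' @export
generate_random_steps <- function(x0, y0, prev_bearing, kernel, n = 15) {
  if (!is.finite(prev_bearing)) stop("previous bearing is undefined")
  len <- rgamma(n, shape = kernel$shape, rate = kernel$rate)
  turn <- rvonmises(n, mu = kernel$mu, kappa = kernel$kappa)
  dir <- prev_bearing + turn
  data.frame(x = x0 + len * cos(dir), y = y0 + len * sin(dir),
             step = len, turn = turn)
}

ISSF_MOVEMENT_TERMS <- c("step", "log_step", "cos_turn",
                         "step_day", "step_night", "log_step_day",
                         "log_step_night", "cos_turn_day", "cos_turn_night")

#' Candidate model specifications
#'
#' Three nested specifications: `habitat` (covariates only),
#' `habitat_movement` (plus shared movement-adjustment terms), and
#' `habitat_diel` (diel-specific forest and movement terms; the structure of
#' the full selection model with day/night forest classes, cos-turn,
#' diel-specific step and log-step adjustments and a night turn term).
#'
#' @return named list of character term vectors.
#' @export
issf_model_specs <- function() {
  list(
    habitat = c("ndvi", "dist_village", "forest", "open_forest"),
    habitat_movement = c("ndvi", "dist_village", "forest", "open_forest",
                         "step", "log_step", "cos_turn"),
    habitat_diel = c("ndvi", "dist_village",
                     "forest_day", "forest_night",
                     "open_forest_day", "open_forest_night",
                     "cos_turn",
                     "log_step_day", "log_step_night",
                     "step_day", "step_night", "cos_turn_night")
  )
}

#' Build conditional-logistic strata from used steps
#'
#' For every used step with a defined turning angle, generates `n_random`
#' candidate steps from the tentative kernel (per-stratum substream of the
#' master seed, so strata are reproducible independent of order), samples
#' the covariate stack at all endpoints, drops out-of-extent candidates
#' (the used row is never dropped; a stratum survives while >= 2 candidates
#' remain), and attaches movement-adjustment and diel-interaction columns.
#'
#' @param steps `step_series` with `diel` labels (see [assign_diel()]).
#' @param stack a `landscape_stack`.
#' @param kernel a `movement_kernel`.
#' @param n_random candidates per used step (default 15).
#' @param seed master seed for candidate generation.
#' @param standardize "dataset" (z-score ndvi/dist_village/dist_water over
#'   all rows), "none", or a constants data.frame (covariate, mean, sd) to
#'   standardize against.
#' @param wrap passed to [sample_covariates()] (periodic landscapes).
#' @return data.frame of class `issf_strata`; attributes `standardization`,
#'   `n_dropped_strata`, `n_dropped_candidates`, `n_skipped_bearing`.
#' @export
build_strata <- function(steps, stack, kernel, n_random = 15, seed = 1,
                         standardize = "dataset", wrap = FALSE) {
  if (!"diel" %in% names(steps)) stop("steps need a 'diel' column")
  usable <- which(is.finite(steps$angle) & is.finite(steps$step))
  skipped <- nrow(steps) - length(usable)
  rows <- vector("list", length(usable))
  for (i in seq_along(usable)) {
    t <- usable[i]
    prev_bearing <- wrap_angle(steps$bearing[t] - steps$angle[t])
    set.seed(as.integer((seed * 48271 + i * 9973) %% 2147483647))
    cand <- generate_random_steps(steps$x0[t], steps$y0[t], prev_bearing,
                                  kernel, n = n_random)
    rows[[i]] <- data.frame(
      stratum = i, used = c(1L, rep(0L, n_random)),
      x = c(steps$x1[t], cand$x), y = c(steps$y1[t], cand$y),
      step = c(steps$step[t], cand$step),
      turn = c(steps$angle[t], cand$turn),
      diel = steps$diel[t], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  cov <- sample_covariates(stack, df$x, df$y, wrap = wrap)
  df <- cbind(df, cov)
  # out-of-extent handling: drop candidates, never the used row
  bad_used <- df$used == 1L & df$out_of_extent
  drop_strata <- unique(df$stratum[bad_used])
  df <- df[!df$stratum %in% drop_strata, , drop = FALSE]
  n_cand_dropped <- sum(df$used == 0L & df$out_of_extent)
  df <- df[!(df$used == 0L & df$out_of_extent), , drop = FALSE]
  nk <- table(df$stratum)
  keep <- names(nk)[nk >= 3]  # used + at least 2 candidates
  thin <- sum(!df$stratum %in% as.integer(keep) & df$used == 1L)
  df <- df[df$stratum %in% as.integer(keep), , drop = FALSE]
  if (!nrow(df)) stop("no stratum survived covariate sampling")
  day <- as.numeric(df$diel == "day")
  df$log_step <- log(df$step)
  df$cos_turn <- cos(df$turn)
  for (v in c("forest", "open_forest")) {
    df[[paste0(v, "_day")]] <- df[[v]] * day
    df[[paste0(v, "_night")]] <- df[[v]] * (1 - day)
  }
  for (v in c("step", "log_step", "cos_turn")) {
    df[[paste0(v, "_day")]] <- df[[v]] * day
    df[[paste0(v, "_night")]] <- df[[v]] * (1 - day)
  }
  const <- NULL
  contcols <- c("ndvi", "dist_village", "dist_water")
  if (is.data.frame(standardize)) {
    for (i in seq_len(nrow(standardize))) {
      cv <- standardize$covariate[i]
      df[[cv]] <- (df[[cv]] - standardize$mean[i]) / standardize$sd[i]
    }
    const <- standardize
  } else if (identical(standardize, "dataset")) {
    df <- standardize_covariates(df, contcols)
    const <- attr(df, "standardization")
  } else if (!identical(standardize, "none")) {
    stop("'standardize' must be \"dataset\", \"none\" or a constants data.frame")
  }
  structure(df, class = c("issf_strata", "data.frame"),
            standardization = const,
            n_dropped_strata = length(drop_strata) + thin,
            n_dropped_candidates = n_cand_dropped,
            n_skipped_bearing = skipped)
}

#' Conditional log-likelihood at fixed coefficients
#'
#' Evaluates sum_i \[ beta' x_used(i) - log sum_j exp(beta' x_j(i)) \]
#' without fitting; `beta = 0` gives -sum_i log(m_i) with m_i candidates
#' per stratum.
#'
#' @param strata data.frame with `stratum`, `used` and the model columns.
#' @param terms model term names.
#' @param beta coefficient vector (recycled scalar allowed).
#' @return log-likelihood (scalar).
#' @export
clogit_loglik <- function(strata, terms, beta) {
  X <- as.matrix(strata[, terms, drop = FALSE])
  beta <- rep_len(beta, ncol(X))
  y <- strata$used == 1L
  sid <- as.integer(factor(strata$stratum))
  eta <- as.numeric(X %*% beta)
  mxs <- as.numeric(tapply(eta, sid, max))
  lse <- log(as.numeric(rowsum(exp(eta - mxs[sid]), sid))) + mxs
  sum(eta[y]) - sum(lse)
}

#' Conditional logistic regression for matched strata
#'
#' Maximizes the conditional log-likelihood
#' sum_i \[ beta' x_used(i) - log sum_j exp(beta' x_j(i)) \]
#' by Newton-Raphson with step halving. Standard errors come from the
#' observed information; p-values are two-sided Wald.
#'
#' @param strata an `issf_strata` (or any data.frame with `stratum`, `used`
#'   and the model columns).
#' @param terms character vector of column names entering the linear
#'   predictor.
#' @param label model label for reporting.
#' @return object of class `ssf_fit`: coefficients table, loglik, AIC, vcov.
#' @export
fit_clogit <- function(strata, terms, label = "model") {
  miss <- setdiff(terms, names(strata))
  if (length(miss)) stop("model term(s) not in strata: ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(strata[, terms, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite values in design columns")
  y <- strata$used == 1L
  sid <- as.integer(factor(strata$stratum))
  ns <- max(sid)
  if (sum(y) != ns) stop("each stratum needs exactly one used row")
  p <- ncol(X)
  beta <- rep(0, p)
  loglik <- function(b) {
    eta <- as.numeric(X %*% b)
    mxs <- as.numeric(tapply(eta, sid, max))
    lse <- log(as.numeric(rowsum(exp(eta - mxs[sid]), sid))) + mxs
    sum(eta[y]) - sum(lse)
  }
  ll <- loglik(beta)
  for (it in 1:50) {
    eta <- as.numeric(X %*% beta)
    mx <- tapply(eta, sid, max)[sid]
    w <- exp(eta - mx)
    denom <- rowsum(w, sid)[sid]
    pr <- as.numeric(w / denom)
    E <- rowsum(pr * X, sid)           # per-stratum expected covariates
    grad <- colSums(X[y, , drop = FALSE]) - colSums(E)
    Hess <- -(t(X) %*% (pr * X) - t(E) %*% E)
    step <- tryCatch(solve(-Hess, grad), error = function(e) {
      stop("singular information matrix (possible complete separation); ",
           "max |beta| = ", sprintf("%.2f", max(abs(beta))))
    })
    sz <- 1
    repeat {
      bnew <- beta + sz * step
      llnew <- loglik(bnew)
      if (is.finite(llnew) && llnew >= ll - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-8) { bnew <- beta; llnew <- ll; break }
    }
    conv <- abs(llnew - ll) < 1e-12 && max(abs(grad)) < 1e-6
    beta <- bnew; ll <- llnew
    if (max(abs(beta)) > 30) {
      stop("coefficients diverging (complete separation?): ",
           terms[which.max(abs(beta))], " -> ",
           sprintf("%.1f", beta[which.max(abs(beta))]))
    }
    if (conv) break
  }
  eta <- as.numeric(X %*% beta)
  mx <- tapply(eta, sid, max)[sid]
  w <- exp(eta - mx)
  pr <- as.numeric(w / rowsum(w, sid)[sid])
  E <- rowsum(pr * X, sid)
  Hess <- -(t(X) %*% (pr * X) - t(E) %*% E)
  vcov <- tryCatch(solve(-Hess), error = function(e) {
    stop("singular information matrix at the optimum")
  })
  se <- sqrt(pmax(diag(vcov), 0))
  zval <- beta / se
  tab <- data.frame(factor = terms, coefficient = beta, se = se,
                    p_value = 2 * pnorm(-abs(zval)), row.names = NULL)
  structure(list(label = label, coefficients = setNames(beta, terms),
                 table = tab, vcov = vcov, loglik = ll,
                 aic = 2 * p - 2 * ll, n_strata = ns,
                 standardization = attr(strata, "standardization")),
            class = "ssf_fit")
}

#' @export
print.ssf_fit <- function(x, ...) {
  cat(sprintf("iSSF conditional logit '%s': %d strata, logLik %.2f, AIC %.2f\n",
              x$label, x$n_strata, x$loglik, x$aic))
  print(x$table, digits = 4)
  invisible(x)
}

#' Compare candidate models by AIC
#'
#' @param strata an `issf_strata`.
#' @param specs named list of term vectors (default [issf_model_specs()]).
#' @return list: `table` (model, k, loglik, AIC, dAIC; AIC-ordered) and
#'   `fits` (the `ssf_fit` objects).
#' @export
compare_models <- function(strata, specs = issf_model_specs()) {
  fits <- lapply(names(specs), function(nm) {
    fit_clogit(strata, specs[[nm]], label = nm)
  })
  names(fits) <- names(specs)
  tab <- data.frame(
    model = names(specs),
    k = vapply(fits, function(f) length(f$coefficients), 0),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = vapply(fits, `[[`, 0, "aic"), row.names = NULL)
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  list(table = tab, fits = fits)
}

#' Relative selection strength between two habitat compositions
#'
#' RSS = exp(beta' (x1 - x2)) with a Wald 95% CI on the log scale. `x1` and
#' `x2` are named vectors on the model's (standardized) covariate scale;
#' terms left unnamed are taken equal in both compositions.
#' Movement-adjustment terms cannot enter the contrast.
#'
#' @param fit an `ssf_fit`.
#' @param x1,x2 named numeric vectors of habitat covariate values.
#' @return list: rss, lower, upper, log_rss, se_log.
#' @export
rss <- function(fit, x1, x2) {
  nm <- union(names(x1), names(x2))
  if (!length(nm)) stop("empty contrast")
  bad <- intersect(nm, ISSF_MOVEMENT_TERMS)
  if (length(bad)) stop("movement-adjustment term(s) in RSS contrast: ",
                        paste(bad, collapse = ", "))
  absent <- setdiff(nm, names(fit$coefficients))
  if (length(absent)) stop("contrast term(s) absent from the fit: ",
                           paste(absent, collapse = ", "))
  d <- setNames(rep(0, length(fit$coefficients)), names(fit$coefficients))
  for (v in nm) {
    d[v] <- (if (v %in% names(x1)) x1[[v]] else 0) -
      (if (v %in% names(x2)) x2[[v]] else 0)
  }
  lr <- sum(fit$coefficients * d)
  vr <- max(as.numeric(t(d) %*% fit$vcov %*% d), 0)
  se <- sqrt(vr)
  list(rss = exp(lr), lower = exp(lr - qnorm(0.975) * se),
       upper = exp(lr + qnorm(0.975) * se), log_rss = lr, se_log = se)
}
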
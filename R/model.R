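#' Specify a GAMMAR exposure model
#'
#' Defines one of the three exposure models: a generalized additive mixed
#' model with moving-average residual structure.  The linear predictor is
#' fixed effects + day and participant random intercepts + a time-of-day
#' smooth + a 2D spatial smooth; the residuals follow an MA(`ma_order`)
#' process (restarting at trip boundaries) driven by Student-t or Gaussian
#' innovations.  Residential streets are always the reference road class;
#' the noise model excludes humidity and wind.
#'
#' @param response `"noise"` (dB(A), column `laeq_1min`), `"no2"`
#'   (µg/m³, column `no2_ugm3`) or `"inhalation"` (µg, column
#'   `inhaled_ug`).
#' @param fixed Character vector of fixed-effect columns; defaults to the
#'   standard set for the response (intersections, speed, grade, five
#'   road-class shares, plus humidity and wind except for noise).
#' @param spline_time Basis size for the time-of-day smooth; 0 disables it.
#' @param spline_space Basis size for the 2D thin-plate spatial smooth;
#'   0 disables it.
#' @param random Include day and participant random intercepts.
#' @param ma_order Order of the moving-average residual term (0 disables).
#' @param likelihood `"student"` (default, heavy-tailed, via iteratively
#'   reweighted least squares) or `"gaussian"`.
#' @param student_df Degrees of freedom for the Student likelihood.
#' @return A `gammar_spec` object.
#' @examples
#' gammar_spec("no2")
#' gammar_spec("noise", spline_space = 20)
#' @export
gammar_spec <- function(response = c("no2", "noise", "inhalation"),
                        fixed = NULL,
                        spline_time = 10, spline_space = 30,
                        random = TRUE, ma_order = 3,
                        likelihood = c("student", "gaussian"),
                        student_df = 4) {
  response <- match.arg(response)
  likelihood <- match.arg(likelihood)
  base_fixed <- c("intersections", "speed_kmh", "slope_pct",
                  "share_trunk_motorway", "share_primary", "share_secondary",
                  "share_tertiary", "share_unclassified_service")
  if (is.null(fixed)) {
    fixed <- if (response == "noise") base_fixed
             else c("humidity_pct", "wind_kmh", base_fixed)
  }
  if (response == "noise" && any(c("humidity_pct", "wind_kmh") %in% fixed)) {
    abort("The noise model excludes humidity and wind.")
  }
  structure(
    list(
      response = response,
      response_col = c(noise = "laeq_1min", no2 = "no2_ugm3",
                       inhalation = "inhaled_ug")[[response]],
      fixed = fixed,
      spline_time = spline_time,
      spline_space = spline_space,
      random = random,
      ma_order = ma_order,
      likelihood = likelihood,
      student_df = student_df
    ),
    class = "gammar_spec"
  )
}

#' Build the design bundle for a GAMMAR fit
#'
#' Validates the covariates, orders observations in time within trips (the
#' MA structure needs the original ordering), assembles the fixed-effect
#' matrix with residential streets as the omitted reference, evaluates
#' centred penalized spline bases for time of day and space
#' ([mgcv::smoothCon()] with the identifiability constraint absorbed), and
#' builds the random-intercept indicator blocks.
#'
#' @param segments Segment tibble.
#' @param spec A [gammar_spec()].
#' @return A list with elements `y`, `X` (fixed effects, no intercept),
#'   `data` (ordered model frame), `basis_time`, `basis_space` (centred
#'   bases), `smooth_time`, `smooth_space` (the smooth constructors),
#'   `Z_day`, `Z_participant`, `spec`.
#' @export
build_design <- function(segments, spec) {
  needed <- c(spec$response_col, spec$fixed, "x", "y", "clock_min")
  if (spec$random) needed <- c(needed, "day", "participant")
  missing <- setdiff(needed, names(segments))
  if (length(missing)) {
    abort(paste0("Missing covariates: ", paste(missing, collapse = ", ")))
  }
  df <- as_tibble_plain(segments)
  if (!"trip_id" %in% names(df)) df$trip_id <- "trip_001"
  ord <- if ("timestamp_minute" %in% names(df)) {
    order(df$trip_id, df$timestamp_minute)
  } else {
    order(df$trip_id, seq_len(nrow(df)))
  }
  df <- df[ord, ]

  X <- as.matrix(df[, spec$fixed, drop = FALSE])
  mf <- tibble(
    .response = df[[spec$response_col]],
    clock_min = df$clock_min,
    x = df$x, y = df$y,
    trip_id = df$trip_id
  )
  Z_day <- Z_participant <- NULL
  if (spec$random) {
    mf$day <- factor(df$day)
    mf$participant <- factor(df$participant)
    Z_day <- level_indicators(mf$day)
    Z_participant <- level_indicators(mf$participant)
  }
  mf <- dplyr::bind_cols(mf, tibble::as_tibble(X))

  smooth_time <- smooth_space <- NULL
  if (spec$spline_time >= 3) {
    smooth_time <- mgcv::smoothCon(
      mgcv::s(clock_min, k = spec$spline_time, bs = "tp"),
      data = mf, absorb.cons = TRUE)[[1]]
  }
  if (spec$spline_space >= 3) {
    smooth_space <- mgcv::smoothCon(
      mgcv::s(x, y, k = spec$spline_space, bs = "tp"),
      data = mf, absorb.cons = TRUE)[[1]]
  }
  list(y = mf$.response, X = X, data = mf,
       basis_time = smooth_time$X, basis_space = smooth_space$X,
       smooth_time = smooth_time, smooth_space = smooth_space,
       Z_day = Z_day, Z_participant = Z_participant,
       spec = spec)
}

level_indicators <- function(f) {
  lv <- levels(f)
  Z <- matrix(0, length(f), length(lv), dimnames = list(NULL, lv))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

#' Fit a GAMMAR exposure model
#'
#' Iterated whitened penalized least squares.  Given current MA
#' coefficients, the response, the fixed-effect columns, the spline bases
#' and the random-intercept indicators are all passed through the
#' innovations (whitening) filter per trip, and the whole linear predictor
#' is estimated **jointly** by penalized least squares with REML smoothing
#' parameters ([mgcv::gam()] with `paraPen`; the random intercepts are
#' ridge-penalized blocks, i.e. ordinary random effects).  The MA
#' coefficients are then re-estimated on the per-trip ordered residuals by
#' conditional least squares, and the two steps iterate to a 1e-4
#' relative-change tolerance (at most 20 iterations; typically 4–8).  The
#' Student likelihood is handled by iteratively reweighted least squares
#' on the whitened innovations with fixed degrees of freedom.  Intervals
#' for the fixed effects come from the joint fit's Bayesian posterior
#' covariance, which includes the uncertainty of the smooth terms.
#'
#' @param segments Segment tibble (or a [build_design()] bundle).
#' @param spec A [gammar_spec()].
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Maximum outer iterations.
#' @return A `gammar_fit` object; see [tidy.gammar_fit()],
#'   [glance.gammar_fit()], [predict_exposure()], [bayes_r2()],
#'   [residual_diagnostics()].
#' @examples
#' \donttest{
#' segs <- simulate_study(default_scenario(), n_trips = 6,
#'                        minutes_per_trip = 30, seed = 1)
#' fit <- fit_gammar(segs, gammar_spec("no2", spline_space = 15))
#' tidy(fit)
#' }
#' @export
fit_gammar <- function(segments, spec = gammar_spec(), tol = 1e-4,
                       max_iter = 20) {
  d <- if (is.list(segments) && !is.data.frame(segments) &&
           all(c("y", "X", "data") %in% names(segments))) {
    segments
  } else {
    build_design(segments, spec)
  }
  spec <- d$spec
  mf <- d$data
  y <- d$y
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, d$X)
  p <- ncol(X)
  trip <- mf$trip_id

  const_cols <- if (ncol(d$X) > 0) {
    apply(d$X, 2, function(v) var(v) == 0)
  } else logical(0)
  if (any(const_cols)) {
    abort(paste0("Constant fixed-effect columns: ",
                 paste(colnames(d$X)[const_cols], collapse = ", "),
                 ". Drop them from the spec."))
  }
  if (n < 10 * (p + spec$ma_order)) {
    abort("Need at least 10 observations per coefficient.")
  }

  # penalized blocks: spline bases and random-intercept indicators
  blocks <- list()
  if (!is.null(d$smooth_time)) {
    blocks$Zt <- list(Z = d$smooth_time$X, S = d$smooth_time$S[[1]])
  }
  if (!is.null(d$smooth_space)) {
    blocks$Zs <- list(Z = d$smooth_space$X, S = d$smooth_space$S[[1]])
  }
  if (!is.null(d$Z_day)) {
    blocks$Zd <- list(Z = d$Z_day, S = diag(ncol(d$Z_day)))
    blocks$Zp <- list(Z = d$Z_participant, S = diag(ncol(d$Z_participant)))
  }

  form <- stats::as.formula(paste(
    ".yw ~", paste(c("Xw", names(blocks)), collapse = " + "), "- 1"))
  pen <- lapply(blocks, function(b) list(b$S))

  theta <- if (spec$ma_order > 0) rep(0, spec$ma_order) else numeric(0)
  w <- rep(1, n)
  beta <- rep(0, p)
  g <- NULL
  css <- NULL
  coefs_blocks <- NULL
  iter <- 0
  converged <- FALSE

  repeat {
    iter <- iter + 1
    old <- c(beta, theta)

    dat <- list(.yw = as.numeric(ma_whiten(y, trip, theta)),
                Xw = ma_whiten(X, trip, theta))
    for (nm in names(blocks)) {
      dat[[nm]] <- ma_whiten(blocks[[nm]]$Z, trip, theta)
    }
    if (length(blocks) > 0) {
      g <- mgcv::gam(form, data = dat, paraPen = pen, method = "REML",
                     weights = w)
      cf <- coef(g)
    } else {
      # no penalized terms: plain (weighted) least squares
      f <- lm.wfit(dat$Xw, dat$.yw, w)
      if (anyNA(f$coefficients)) abort("Singular fixed-effect design.")
      cf <- f$coefficients
    }
    beta <- unname(cf[seq_len(p)])
    coefs_blocks <- list()
    off <- p
    for (nm in names(blocks)) {
      k <- ncol(blocks[[nm]]$Z)
      coefs_blocks[[nm]] <- unname(cf[off + seq_len(k)])
      off <- off + k
    }

    # residuals on the original (unwhitened) scale, per-trip ordered
    eta <- as.vector(X %*% beta)
    for (nm in names(blocks)) {
      eta <- eta + as.vector(blocks[[nm]]$Z %*% coefs_blocks[[nm]])
    }
    r <- y - eta

    if (spec$ma_order > 0) {
      css <- css_ma(r, trip, spec$ma_order, init = theta)
      theta <- css$theta
    }

    s_irls <- NA_real_
    if (spec$likelihood == "student") {
      e <- as.numeric(ma_whiten(r, trip, theta))
      # ML-type scale: EM fixed point sigma^2 = mean(w e^2)
      s_irls <- median(abs(e)) / 0.6745
      if (s_irls > 0) for (j in 1:10) {
        wj <- (spec$student_df + 1) /
          (spec$student_df + (e / s_irls)^2)
        s_new <- sqrt(mean(wj * e^2))
        if (abs(s_new - s_irls) < 1e-8 * s_irls) break
        s_irls <- s_new
      }
      if (s_irls > 0) {
        w <- (spec$student_df + 1) / (spec$student_df + (e / s_irls)^2)
      }
    }

    delta <- max(abs(c(beta, theta) - old) / (1 + abs(old)))
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  # M-estimation sandwich covariance of the penalized whitened fit:
  # A = C' diag(psi') C + S_lambda, B = C' diag(psi^2) C, V = A^-1 B A^-1,
  # with psi(e) = w(e) e.  Valid for the Student IRLS estimator and
  # reducing to the heteroscedasticity-robust form under the Gaussian
  # likelihood; also robust to the mild censoring of concentrations at 0.
  dat_fin <- list(.yw = as.numeric(ma_whiten(y, trip, theta)),
                  Xw = ma_whiten(X, trip, theta))
  for (nm in names(blocks)) {
    dat_fin[[nm]] <- ma_whiten(blocks[[nm]]$Z, trip, theta)
  }
  C <- do.call(cbind, c(list(dat_fin$Xw), unname(dat_fin[names(blocks)])))
  all_coefs <- c(beta, unlist(unname(coefs_blocks)))
  e_fin <- dat_fin$.yw - as.vector(C %*% all_coefs)
  if (spec$likelihood == "student" && is.finite(s_irls) && s_irls > 0) {
    nu <- spec$student_df
    u2 <- (e_fin / s_irls)^2
    psi <- (nu + 1) * e_fin / (nu + u2)
    dpsi <- (nu + 1) * (nu - u2) / (nu + u2)^2
  } else {
    psi <- e_fin
    dpsi <- rep(1, n)
  }
  S_lambda <- matrix(0, ncol(C), ncol(C))
  off <- p
  sp <- if (!is.null(g)) g$sp else numeric(0)
  sp_i <- 1
  for (nm in names(blocks)) {
    k <- ncol(blocks[[nm]]$Z)
    S_lambda[off + seq_len(k), off + seq_len(k)] <-
      sp[sp_i] * blocks[[nm]]$S
    off <- off + k
    sp_i <- sp_i + 1
  }
  A <- crossprod(C * dpsi, C) + S_lambda
  B <- crossprod(C * psi)
  Vp <- tryCatch({
    Ainv <- solve(A)
    Ainv %*% B %*% Ainv
  }, error = function(err) {
    if (!is.null(g)) g$Vp
    else solve(crossprod(C) + diag(1e-8, ncol(C))) * var(e_fin)
  })
  se <- sqrt(pmax(diag(Vp)[seq_len(p)], 0))
  coefs <- tibble(
    term = colnames(X),
    estimate = beta,
    std.error = se,
    conf.low = beta - 1.96 * se,
    conf.high = beta + 1.96 * se
  )

  ma_tbl <- NULL
  if (spec$ma_order > 0) {
    mase <- sqrt(pmax(diag(css$vcov), 0))
    ma_tbl <- tibble(
      term = paste0("ma", seq_len(spec$ma_order)),
      estimate = css$theta,
      std.error = mase,
      conf.low = css$theta - 1.96 * mase,
      conf.high = css$theta + 1.96 * mase
    )
  }

  re_tbl <- NULL
  if (!is.null(d$Z_day)) {
    idx <- p + (if (!is.null(blocks$Zt)) ncol(blocks$Zt$Z) else 0) +
      (if (!is.null(blocks$Zs)) ncol(blocks$Zs$Z) else 0)
    vp_diag <- diag(Vp)
    re_rows <- function(group, Z, b, offset) {
      se_re <- sqrt(pmax(vp_diag[offset + seq_len(ncol(Z))], 0))
      tibble(group = group, level = colnames(Z), estimate = b,
             std.error = se_re,
             conf.low = b - 1.96 * se_re, conf.high = b + 1.96 * se_re)
    }
    re_tbl <- bind_rows(
      re_rows("day", d$Z_day, coefs_blocks$Zd, idx),
      re_rows("participant", d$Z_participant, coefs_blocks$Zp,
              idx + ncol(d$Z_day))
    )
  }

  fitted_fix <- as.vector(X %*% beta)
  fitted_smooth <- rep(0, n)
  for (nm in intersect(c("Zt", "Zs"), names(blocks))) {
    fitted_smooth <- fitted_smooth +
      as.vector(blocks[[nm]]$Z %*% coefs_blocks[[nm]])
  }
  fitted_re <- rep(0, n)
  for (nm in intersect(c("Zd", "Zp"), names(blocks))) {
    fitted_re <- fitted_re + as.vector(blocks[[nm]]$Z %*% coefs_blocks[[nm]])
  }
  fitted_cond <- fitted_fix + fitted_smooth + fitted_re
  resid_cond <- y - fitted_cond
  innov <- as.numeric(ma_whiten(resid_cond, trip, theta))

  racf <- sapply(1:3, function(k) {
    tryCatch(acf_index(tibble(v = innov, trip_id = trip), v, k = k),
             error = function(e) NA_real_)
  })

  structure(
    list(
      spec = spec,
      coefficients = coefs,
      ma = ma_tbl,
      random = re_tbl,
      smooth_time = d$smooth_time,
      smooth_space = d$smooth_space,
      coefs_blocks = coefs_blocks,
      theta = theta,
      sigma = sqrt(mean(innov^2)),
      n = n,
      iterations = iter,
      converged = converged && (is.null(css) || css$converged),
      var_fixed_smooth = var(fitted_fix + fitted_smooth),
      var_re = var(fitted_re),
      var_resid = var(resid_cond),
      resid_acf = racf,
      residuals = resid_cond,
      innovations = innov,
      trip = trip,
      fitted = fitted_cond,
      data_ranges = list(x = range(mf$x), y = range(mf$y),
                         clock_min = range(mf$clock_min)),
      covariate_means = colMeans(d$X),
      re_levels = if (spec$random) list(day = levels(mf$day),
                                        participant = levels(mf$participant))
    ),
    class = "gammar_fit"
  )
}

#' Predict exposure at new covariate settings
#'
#' Linear-predictor prediction: intercept + fixed effects + time and space
#' smooths evaluated at the supplied clock time and coordinates, with
#' random intercepts excluded by default (the convention for scenario
#' predictions, which avoids overestimation).  Points outside the fitted
#' spatial support are flagged and a warning raised.
#'
#' @param fit A `gammar_fit`.
#' @param newdata Tibble with the model's fixed-effect columns plus
#'   `clock_min`, `x`, `y` (and `day`/`participant` when
#'   `include_random = TRUE`).
#' @param include_random Add the day/participant random intercepts.
#' @return `newdata` with `.pred` and `.extrapolated` columns appended.
#' @export
predict_exposure <- function(fit, newdata, include_random = FALSE) {
  if (!fit$converged) abort("Model did not converge; refusing to predict.")
  spec <- fit$spec
  newdata <- as_tibble_plain(newdata)
  missing <- setdiff(c(spec$fixed, "clock_min", "x", "y"), names(newdata))
  if (length(missing)) {
    abort(paste0("`newdata` lacks columns: ", paste(missing, collapse = ", ")))
  }
  X <- cbind(1, as.matrix(newdata[, spec$fixed, drop = FALSE]))
  eta <- as.vector(X %*% fit$coefficients$estimate)

  nd <- as.data.frame(newdata[, c("clock_min", "x", "y")])
  if (!is.null(fit$smooth_time)) {
    Zt <- mgcv::PredictMat(fit$smooth_time, nd)
    eta <- eta + as.vector(Zt %*% fit$coefs_blocks$Zt)
  }
  if (!is.null(fit$smooth_space)) {
    Zs <- mgcv::PredictMat(fit$smooth_space, nd)
    eta <- eta + as.vector(Zs %*% fit$coefs_blocks$Zs)
  }
  if (include_random && !is.null(fit$random)) {
    if (!all(c("day", "participant") %in% names(newdata))) {
      abort("`include_random = TRUE` needs `day` and `participant` columns.")
    }
    re <- fit$random
    day_eff <- re$estimate[re$group == "day"][
      match(newdata$day, re$level[re$group == "day"])]
    part_eff <- re$estimate[re$group == "participant"][
      match(newdata$participant, re$level[re$group == "participant"])]
    if (anyNA(day_eff) || anyNA(part_eff)) {
      abort("Unknown day or participant level in `newdata`.")
    }
    eta <- eta + day_eff + part_eff
  }

  rx <- fit$data_ranges
  extrap <- newdata$x < rx$x[1] | newdata$x > rx$x[2] |
    newdata$y < rx$y[1] | newdata$y > rx$y[2]
  if (is.null(fit$smooth_space)) extrap <- rep(FALSE, nrow(newdata))
  if (any(extrap)) {
    warn(paste0(sum(extrap), " prediction point(s) outside the fitted ",
                "spatial support; extrapolated values flagged."))
  }
  newdata %>% mutate(.pred = eta, .extrapolated = extrap)
}

#' Explained-variance summaries for a GAMMAR fit
#'
#' Empirical variance-partition R²: the marginal version uses the fixed and
#' smooth terms only, the conditional version adds the random intercepts;
#' both divide by explained plus residual variance, so marginal <=
#' conditional always.
#'
#' @param fit A `gammar_fit`.
#' @param kind `"marginal"` or `"conditional"`.
#' @return A proportion in `[0, 1]`.
#' @export
bayes_r2 <- function(fit, kind = c("marginal", "conditional")) {
  kind <- match.arg(kind)
  tot <- fit$var_fixed_smooth + fit$var_re + fit$var_resid
  if (tot <= 0) abort("Degenerate zero-variance fit; R^2 undefined.")
  num <- if (kind == "marginal") fit$var_fixed_smooth
         else fit$var_fixed_smooth + fit$var_re
  num / tot
}

#' Residual diagnostics for a GAMMAR fit
#'
#' Autocorrelation of the whitened innovations at lags 1–3 (a well
#' specified model leaves no temporal dependency) and a tail-weight
#' summary for judging the heavy-tailed likelihood: excess kurtosis and
#' the fraction of |standardized innovations| > 2 (Gaussian reference
#' 0.0455).
#'
#' @param fit A `gammar_fit`.
#' @return A list with `acf` (tibble lag/acf) and `tails` (tibble).
#' @export
residual_diagnostics <- function(fit) {
  e <- fit$innovations
  s <- sd(e)
  kurt <- mean((e - mean(e))^4) / s^4 - 3
  list(
    acf = tibble(lag = 1:3, acf = fit$resid_acf),
    tails = tibble(
      excess_kurtosis = kurt,
      frac_beyond_2sd = mean(abs(e - mean(e)) > 2 * s),
      gaussian_reference = 2 * stats::pnorm(-2)
    )
  )
}

#' @rdname fit_gammar
#' @param x A `gammar_fit`.
#' @param ... Unused.
#' @export
print.gammar_fit <- function(x, ...) {
  cat("<gammar_fit> response:", x$spec$response,
      " n =", x$n,
      " likelihood:", x$spec$likelihood,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$coefficients, n = Inf)
  if (!is.null(x$ma)) {
    cat("MA coefficients:\n")
    print(x$ma)
  }
  cat(sprintf("R2 marginal %.3f, conditional %.3f\n",
              bayes_r2(x, "marginal"), bayes_r2(x, "conditional")))
  invisible(x)
}

#' Tidy a GAMMAR fit
#'
#' @param x A `gammar_fit`.
#' @param effects Which blocks to return: any of `"fixed"`, `"ma"`,
#'   `"random"`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `effect`.
#' @export
tidy.gammar_fit <- function(x, effects = c("fixed", "ma", "random"), ...) {
  out <- list()
  if ("fixed" %in% effects) {
    out$fixed <- x$coefficients %>% mutate(effect = "fixed")
  }
  if ("ma" %in% effects && !is.null(x$ma)) {
    out$ma <- x$ma %>% mutate(effect = "ma")
  }
  if ("random" %in% effects && !is.null(x$random)) {
    out$random <- x$random %>%
      mutate(term = paste0(.data$group, ":", .data$level),
             effect = "random") %>%
      select("term", "estimate", "std.error", "conf.low", "conf.high",
             "effect")
  }
  bind_rows(out)
}

#' Glance at a GAMMAR fit
#'
#' @param x A `gammar_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit-level summaries.
#' @export
glance.gammar_fit <- function(x, ...) {
  tibble(
    response = x$spec$response,
    nobs = x$n,
    r2_marginal = bayes_r2(x, "marginal"),
    r2_conditional = bayes_r2(x, "conditional"),
    sigma = x$sigma,
    resid_acf1 = x$resid_acf[1],
    iterations = x$iterations,
    converged = x$converged
  )
}
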
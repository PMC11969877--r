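# Mixed-effects inference for accelerometer activity and migration speed.
#
# Acceleration (per zone, log scale):
#   tidal zone:        log(a) ~ circadian * tidal + sex
#   transition / non-tidal: log(a) ~ circadian + sex
# with random intercepts for receiver ID nested within tag ID and an AR1
# residual correlation within each tag x receiver measurement series
# (nlme::lme, corAR1).  Migration speed (log scale):
#   log(speed) ~ sex * tidal class
# with crossed random intercepts for tag ID and receiver ID (lme4::lmer).
#
# Fixed effects are pruned by stepwise backward selection on ML AIC
# (interactions before their main effects); the selected model is refit and
# summarised with omnibus tests, estimated marginal means back-transformed
# to the response scale (geometric means with 95% CI), and pairwise
# contrasts (Tukey adjustment for the 3-level tidal-class factor).

# ---- generic helpers -------------------------------------------------------

# subset a design/weight matrix to the columns actually estimated (lme4 and
# lme drop aliased columns from rank-deficient designs; the dropped
# coefficients are treated as 0, which is exact for the retained terms)
align_to_beta <- function(M, beta) {
  keep <- intersect(names(beta), colnames(M))
  M[, keep, drop = FALSE]
}

# marginal (type-III-like) Wald tests per fixed term
wald_term_tests <- function(beta, V, X_assign, term_labels) {
  out <- lapply(seq_along(term_labels), function(k) {
    J <- which(X_assign == k)
    if (!length(J)) {
      return(NULL)
    }
    W <- tryCatch(
      as.numeric(t(beta[J]) %*% solve(V[J, J, drop = FALSE], beta[J])),
      error = function(e) NA_real_
    )
    data.frame(
      term = term_labels[k], df = length(J), chi2 = W,
      p = pchisq(W, length(J), lower.tail = FALSE), stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# estimated marginal means of `factor_name` on the link (log) scale,
# averaging predictions over an equally weighted grid of the other factors
emm_weights <- function(fixed_rhs, data, factor_name) {
  vars <- all.vars(fixed_rhs)
  lv <- lapply(setNames(vars, vars), function(v) levels(droplevels(factor(data[[v]]))))
  grid <- expand.grid(lv, stringsAsFactors = FALSE)
  gridf <- as.data.frame(
    lapply(setNames(vars, vars), function(v) factor(grid[[v]], levels = lv[[v]])),
    stringsAsFactors = FALSE
  )
  X <- model.matrix(fixed_rhs, data = gridf)
  lev <- lv[[factor_name]]
  W <- t(vapply(lev, function(l) {
    colMeans(X[grid[[factor_name]] == l, , drop = FALSE])
  }, numeric(ncol(X))))
  rownames(W) <- lev
  W
}

emm_table <- function(W, beta, V, df, back = exp) {
  W <- align_to_beta(W, beta)
  beta <- beta[colnames(W)]
  V <- V[colnames(W), colnames(W), drop = FALSE]
  est <- as.numeric(W %*% beta)
  se <- sqrt(rowSums((W %*% V) * W))
  q <- qt(0.975, df)
  data.frame(
    level = rownames(W), emmean_log = est, se_log = se, df = df,
    mean = back(est), lower = back(est - q * se), upper = back(est + q * se),
    stringsAsFactors = FALSE
  )
}

emm_contrasts <- function(W, beta, V, df, adjust = c("none", "tukey"),
                          back = exp) {
  adjust <- match.arg(adjust)
  W <- align_to_beta(W, beta)
  beta <- beta[colnames(W)]
  V <- V[colnames(W), colnames(W), drop = FALSE]
  lev <- rownames(W)
  k <- length(lev)
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    w <- W[a, ] - W[b, ]
    est <- sum(w * beta)
    se <- sqrt(as.numeric(t(w) %*% V %*% w))
    tval <- est / se
    p <- if (adjust == "tukey") {
      ptukey(sqrt(2) * abs(tval), nmeans = k, df = df, lower.tail = FALSE)
    } else {
      2 * stats::pt(-abs(tval), df)
    }
    data.frame(
      contrast = paste(lev[a], "-", lev[b]), estimate_log = est, se_log = se,
      t = tval, df = df, p = p, ratio = back(est),
      adjust = adjust, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# marginal Wald tests for every retained term of a fit
omnibus_tests <- function(fixed_rhs, data, beta, V) {
  tl <- attr(stats::terms(fixed_rhs), "term.labels")
  if (!length(tl)) {
    return(NULL)
  }
  X <- model.matrix(fixed_rhs, data = data)
  assign0 <- setNames(attr(X, "assign"), colnames(X))
  Xa <- align_to_beta(X, beta)
  b <- beta[colnames(Xa)]
  Vs <- V[colnames(Xa), colnames(Xa), drop = FALSE]
  wald_term_tests(b, Vs, assign0[colnames(Xa)], tl)
}

# drop candidates that respect marginality: a main effect is only removable
# once no retained interaction contains it
removable_terms <- function(term_labels) {
  if (!length(term_labels)) {
    return(character())
  }
  parts <- strsplit(term_labels, ":", fixed = TRUE)
  ord <- lengths(parts)
  removable <- vapply(seq_along(term_labels), function(i) {
    !any(vapply(seq_along(term_labels), function(j) {
      j != i && ord[j] > ord[i] && all(parts[[i]] %in% parts[[j]])
    }, logical(1)))
  }, logical(1))
  term_labels[removable]
}

# stepwise backward AIC selection over fixed-effect terms; `fitter` maps a
# character vector of terms (possibly empty -> intercept only) to a fitted
# model whose AIC is comparable across calls (ML fits)
backward_select <- function(terms0, fitter) {
  current_terms <- terms0
  current_fit <- fitter(current_terms)
  path <- data.frame(
    step = 0L, dropped = "<start>", AIC = AIC(current_fit),
    stringsAsFactors = FALSE
  )
  step <- 0L
  repeat {
    cands <- removable_terms(current_terms)
    if (!length(cands)) break
    fits <- lapply(cands, function(tm) fitter(setdiff(current_terms, tm)))
    aics <- vapply(fits, AIC, numeric(1))
    best <- which.min(aics)
    if (aics[best] < AIC(current_fit)) {
      step <- step + 1L
      current_terms <- setdiff(current_terms, cands[best])
      current_fit <- fits[[best]]
      path <- rbind(path, data.frame(
        step = step, dropped = cands[best], AIC = aics[best],
        stringsAsFactors = FALSE
      ))
    } else {
      break
    }
  }
  list(terms = current_terms, fit = current_fit, path = path)
}

terms_to_rhs <- function(terms) {
  if (!length(terms)) "1" else paste(terms, collapse = " + ")
}

#' @export
print.et_fit <- function(x, ...) {
  cat("<et_fit> ", x$label, "\n  fixed: ", deparse(x$fixed_formula),
    "\n  n = ", x$n, ", AIC(ML path) = ",
    round(tail(x$selection_path$AIC, 1), 2), "\n",
    sep = ""
  )
  if (!is.null(x$anova)) {
    cat("  omnibus tests:\n")
    print(x$anova, row.names = FALSE)
  }
  invisible(x)
}

# ---- acceleration models ---------------------------------------------------

#' Fit the per-zone acceleration mixed models
#'
#' One model per zone with sensor data from >= `min_crabs` crabs.  The
#' tidal-zone model starts from `log(accel) ~ circadian * tidal + sex`; the
#' transition and non-tidal models from `log(accel) ~ circadian + sex`
#' (tidal phase is unavailable outside the two-station tidal zone).  Random
#' intercepts: receiver ID nested within tag ID; residuals follow an AR1
#' process within each tag x receiver series (measurement order).  Backward
#' AIC selection (ML) prunes fixed terms, the selection is refit with REML,
#' and the result carries omnibus Wald tests, back-transformed marginal
#' means and pairwise contrasts for each retained factor.
#'
#' If the nested AR1 fit fails to converge the model is refit without the
#' correlation structure, then with a single tag-level intercept, each
#' fallback loudly logged.
#'
#' @param sensor_obs output of [link_sensor_phases()].
#' @param min_crabs minimum crabs per stratum (default 2); smaller strata
#'   are skipped with a warning.
#' @param use_ar1 fit the AR1 residual correlation (default TRUE).
#' @return named list of `et_fit` objects (possibly missing skipped zones).
#' @export
fit_acceleration_models <- function(sensor_obs, min_crabs = 2L, use_ar1 = TRUE) {
  obs <- sensor_obs[!is.na(sensor_obs$accel_ms2) & sensor_obs$accel_ms2 > 0, ]
  fits <- list()
  for (zone in ZONES) {
    sub <- obs[obs$zone == zone, , drop = FALSE]
    if (zone == "tidal") sub <- sub[sub$tidal %in% TIDAL_PHASES, , drop = FALSE]
    if (!nrow(sub)) next
    if (length(unique(sub$tag_id)) < min_crabs) {
      warning("acceleration stratum '", zone, "' has < ", min_crabs,
        " crabs; skipped",
        call. = FALSE
      )
      next
    }
    sub$log_accel <- log(sub$accel_ms2)
    sub$circadian <- droplevels(factor(sub$circadian, levels = CIRCADIAN_PHASES))
    sub$sex <- droplevels(factor(sub$sex, levels = SEXES))
    sub$tag_id <- factor(sub$tag_id)
    sub$receiver_id <- factor(sub$receiver_id)
    # AR1 index: measurement order within each tag x receiver series
    sub <- sub[order(sub$tag_id, sub$receiver_id, sub$t), ]
    sub$obs_index <- stats::ave(
      seq_len(nrow(sub)), sub$tag_id, sub$receiver_id,
      FUN = seq_along
    )
    if (zone == "tidal") {
      sub$tidal <- factor(sub$tidal, levels = c("flood", "ebb"))
      terms0 <- c("circadian", "tidal", "sex", "circadian:tidal")
    } else {
      terms0 <- c("circadian", "sex")
    }
    # single-level factors carry no information; drop them from the scope
    terms0 <- Filter(function(tm) {
      all(vapply(
        strsplit(tm, ":")[[1]],
        function(v) nlevels(sub[[v]]) > 1, logical(1)
      ))
    }, terms0)

    fits[[zone]] <- fit_lme_backward(
      data = sub, response = "log_accel", terms0 = terms0,
      label = paste0("acceleration, ", zone, " zone"),
      use_ar1 = use_ar1
    )
  }
  fits
}

# nlme fit with fallbacks; method switchable so selection uses ML and the
# final report REML
fit_lme_one <- function(data, response, rhs, method, use_ar1) {
  fml <- as.formula(paste(response, "~", rhs))
  strategies <- list(
    list(random = ~ 1 | tag_id / receiver_id, ar1 = use_ar1, note = NULL),
    list(
      random = ~ 1 | tag_id / receiver_id, ar1 = FALSE,
      note = "AR1 correlation dropped (convergence failure)"
    ),
    list(
      random = ~ 1 | tag_id, ar1 = FALSE,
      note = "random structure simplified to tag-level intercept"
    )
  )
  last_err <- NULL
  for (s in strategies) {
    fit <- tryCatch(
      {
        if (s$ar1) {
          nlme::lme(fml,
            random = s$random, data = data, method = method,
            correlation = nlme::corAR1(form = ~ obs_index | tag_id / receiver_id),
            control = nlme::lmeControl(opt = "optim", maxIter = 100, msMaxIter = 100)
          )
        } else {
          nlme::lme(fml,
            random = s$random, data = data, method = method,
            control = nlme::lmeControl(opt = "optim", maxIter = 100, msMaxIter = 100)
          )
        }
      },
      error = function(e) e
    )
    if (!inherits(fit, "error")) {
      if (!is.null(s$note)) et_log("lme fallback: ", s$note)
      attr(fit, "fallback_note") <- s$note
      return(fit)
    }
    last_err <- fit
  }
  stop("lme failed on all fallback strategies: ", conditionMessage(last_err),
    call. = FALSE
  )
}

fit_lme_backward <- function(data, response, terms0, label, use_ar1 = TRUE) {
  sel <- backward_select(terms0, function(tms) {
    fit_lme_one(data, response, terms_to_rhs(tms), method = "ML", use_ar1 = use_ar1)
  })
  final <- fit_lme_one(data, response, terms_to_rhs(sel$terms),
    method = "REML", use_ar1 = use_ar1
  )
  fixed_rhs <- as.formula(paste("~", terms_to_rhs(sel$terms)))
  beta <- nlme::fixef(final)
  V <- as.matrix(vcov(final))
  dimnames(V) <- list(names(beta), names(beta))
  df_resid <- nrow(data) - length(beta)
  anv <- omnibus_tests(fixed_rhs, data, beta, V)

  means <- list(); contrasts <- list()
  for (f in intersect(c("circadian", "tidal", "sex"), unlist(strsplit(sel$terms, ":")))) {
    W <- emm_weights(fixed_rhs, data, f)
    means[[f]] <- emm_table(W, beta, V, df_resid)
    contrasts[[f]] <- emm_contrasts(W, beta, V, df_resid, adjust = "none")
  }
  structure(
    list(
      label = label, fit = final, data = data,
      fixed_formula = as.formula(paste(response, "~", terms_to_rhs(sel$terms))),
      retained_terms = sel$terms, selection_path = sel$path,
      anova = anv, means = means, contrasts = contrasts,
      n = nrow(data), df_resid = df_resid,
      aic = AIC(sel$fit),
      fallback_note = attr(final, "fallback_note")
    ),
    class = "et_fit"
  )
}

# ---- speed model -----------------------------------------------------------

#' Fit the migration-speed mixed model
#'
#' `log(speed) ~ sex * tidal class` with crossed random intercepts for tag
#' ID and receiver ID (the destination receiver of each segment), fit with
#' lme4.  Upstream-flagged records are excluded.  Fixed terms are pruned by
#' backward AIC selection on ML fits; the selected model is refit with REML
#' and summarised with omnibus Wald tests, back-transformed zone means and
#' Tukey-adjusted pairwise contrasts between tidal classes.
#'
#' @param speeds output of [migration_speeds()].
#' @return an `et_fit`.
#' @export
fit_speed_model <- function(speeds) {
  sp <- speeds[speeds$direction == "downstream" & speeds$speed_km_day > 0, ]
  if (length(unique(sp$zone)) < 2) {
    stop("speed records span a single tidal class; no model to fit", call. = FALSE)
  }
  if (length(unique(sp$tag_id)) < 2) {
    stop("need speed records from at least two tags", call. = FALSE)
  }
  sp$log_speed <- log(sp$speed_km_day)
  sp$zone <- factor(sp$zone, levels = intersect(ZONES, unique(sp$zone)))
  sp$sex <- factor(sp$sex %||% NA_character_, levels = SEXES)
  sp$tag_id <- factor(sp$tag_id)
  sp$receiver_id <- factor(sp$to_receiver)

  has_sex <- !anyNA(sp$sex) && nlevels(droplevels(sp$sex)) > 1
  terms0 <- if (has_sex) c("sex", "zone", "sex:zone") else "zone"

  fitter <- function(tms, reml = FALSE) {
    fml <- as.formula(paste(
      "log_speed ~", terms_to_rhs(tms),
      "+ (1 | tag_id) + (1 | receiver_id)"
    ))
    suppressMessages(lme4::lmer(fml, data = sp, REML = reml,
      control = lme4::lmerControl(check.conv.singular = "ignore")
    ))
  }
  sel <- backward_select(terms0, fitter)
  final <- fitter(sel$terms, reml = TRUE)

  fixed_rhs <- as.formula(paste("~", terms_to_rhs(sel$terms)))
  beta <- lme4::fixef(final)
  V <- as.matrix(vcov(final))
  dimnames(V) <- list(names(beta), names(beta))
  df_resid <- nrow(sp) - length(beta)
  anv <- omnibus_tests(fixed_rhs, sp, beta, V)

  means <- list(); contrasts <- list()
  for (f in intersect(c("sex", "zone"), unlist(strsplit(sel$terms, ":")))) {
    W <- emm_weights(fixed_rhs, sp, f)
    means[[f]] <- emm_table(W, beta, V, df_resid)
    contrasts[[f]] <- emm_contrasts(W, beta, V, df_resid,
      adjust = if (f == "zone") "tukey" else "none"
    )
  }
  structure(
    list(
      label = "migration speed", fit = final, data = sp,
      fixed_formula = as.formula(paste("log_speed ~", terms_to_rhs(sel$terms))),
      retained_terms = sel$terms, selection_path = sel$path,
      anova = anv, means = means, contrasts = contrasts,
      n = nrow(sp), df_resid = df_resid, aic = AIC(sel$fit),
      fallback_note = NULL
    ),
    class = "et_fit"
  )
}

# flatten an et_fit for CSV export
fit_to_tables <- function(fit) {
  coefs <- if (inherits(fit$fit, "lme")) nlme::fixef(fit$fit) else lme4::fixef(fit$fit)
  se <- sqrt(diag(as.matrix(vcov(fit$fit))))
  coef_tab <- data.frame(
    term = names(coefs), estimate = as.numeric(coefs), se = se,
    stringsAsFactors = FALSE
  )
  means_tab <- if (length(fit$means)) {
    do.call(rbind, lapply(names(fit$means), function(f) {
      cbind(factor_name = f, fit$means[[f]])
    }))
  } else {
    data.frame()
  }
  contr_tab <- if (length(fit$contrasts)) {
    do.call(rbind, lapply(names(fit$contrasts), function(f) {
      cbind(factor_name = f, fit$contrasts[[f]])
    }))
  } else {
    data.frame()
  }
  list(
    coefficients = coef_tab, means = means_tab, contrasts = contr_tab,
    anova = fit$anova %||% data.frame(), selection = fit$selection_path
  )
}
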
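# Nuisance estimation: outcome regression Qbar(A, W, C) and propensity
# g(a(s) | W), full-sample or cross-fit. Models are fitted once per fold and
# queried at the observed treatments and at arbitrary vertex level
# assignments (treatment columns overwritten, design matrix rebuilt with the
# same factor coding).

design_matrix <- function(df, cols) {
  mm <- stats::model.matrix(~ ., data = df[, cols, drop = FALSE])
  mm[, -1L, drop = FALSE]
}

q_family <- function(y) if (is_binary(y)) "binomial" else "gaussian"

# Fit outcome-regression model(s); one model per fold when plan is given.
fit_q_models <- function(df, spec, learner, plan = NULL) {
  y <- df[[spec$outcome]]
  fam <- q_family(y)
  cols <- c(spec$treatments, spec$confounders, spec$covariates)
  x <- design_matrix(df, cols)
  if (is.null(plan)) {
    if (fam == "binomial" && length(unique(y)) < 2L)
      stop("degenerate fit: single-class binary outcome", call. = FALSE)
    models <- list(fit_learner(learner, x, y, fam))
    folds <- NULL
  } else {
    models <- vector("list", plan$k)
    for (f in seq_len(plan$k)) {
      tr <- plan$folds != f
      if (fam == "binomial" && length(unique(y[tr])) < 2L)
        stop("degenerate fit: single-class binary outcome in training split of fold ",
             f, call. = FALSE)
      models[[f]] <- fit_learner(learner, x[tr, , drop = FALSE], y[tr], fam)
    }
    folds <- plan$folds
  }
  list(models = models, folds = folds, cols = cols, family = fam, spec = spec)
}

# Predict Qbar at the observed treatments (assign = NULL) or with treatment
# columns overwritten to the level assignment `assign` (named character).
predict_q <- function(qm, df, assign = NULL) {
  newdf <- df
  if (!is.null(assign)) {
    for (tn in names(assign))
      newdf[[tn]] <- factor(rep(assign[[tn]], nrow(df)),
                            levels = levels(df[[tn]]))
  }
  x <- design_matrix(newdf, qm$cols)
  if (is.null(qm$folds)) return(predict_learner(qm$models[[1L]], x))
  out <- numeric(nrow(df))
  for (f in seq_along(qm$models)) {
    idx <- qm$folds == f
    out[idx] <- predict_learner(qm$models[[f]], x[idx, , drop = FALSE])
  }
  out
}

# Fit propensity model(s). Product factorization (default): one multinomial
# model per treatment given W. Joint: a single model over the observed joint
# treatment categories.
fit_g_models <- function(df, spec, learner, plan = NULL, joint = FALSE) {
  x <- design_matrix(df, spec$confounders)
  fit_one <- function(y) {
    y <- factor(y)
    if (is.null(plan))
      return(list(models = list(fit_learner(learner, x, y, "multinomial")),
                  folds = NULL, levels = levels(y)))
    models <- lapply(seq_len(plan$k), function(f) {
      tr <- plan$folds != f
      fit_learner(learner, x[tr, , drop = FALSE], droplevels_keep(y[tr]),
                  "multinomial")
    })
    list(models = models, folds = plan$folds, levels = levels(y))
  }
  if (joint) {
    yjoint <- interaction(df[, spec$treatments, drop = FALSE],
                          drop = TRUE, sep = "\r")
    gm <- list(joint = TRUE, treatments = spec$treatments, fit = fit_one(yjoint))
  } else {
    fits <- lapply(stats::setNames(nm = spec$treatments),
                   function(tn) fit_one(df[[tn]]))
    gm <- list(joint = FALSE, treatments = spec$treatments, fits = fits)
  }
  gm$confounders <- spec$confounders
  gm
}

predict_g_one <- function(fit, x, level) {
  prob_of <- function(model, xx) {
    p <- predict_learner(model, xx)
    if (!level %in% colnames(p)) return(rep(0, nrow(xx)))
    p[, level]
  }
  if (is.null(fit$folds)) return(prob_of(fit$models[[1L]], x))
  out <- numeric(nrow(x))
  for (f in seq_along(fit$models)) {
    idx <- fit$folds == f
    out[idx] <- prob_of(fit$models[[f]], x[idx, , drop = FALSE])
  }
  out
}

# Joint propensity of the level assignment `assign` (named character vector,
# one level per treatment); assign = NULL gives g at the observed treatments.
predict_g <- function(gm, df, assign = NULL) {
  x <- design_matrix(df, gm$confounders)
  if (gm$joint) {
    lv <- if (is.null(assign)) {
      as.character(interaction(df[, gm$treatments, drop = FALSE],
                               drop = FALSE, sep = "\r"))
    } else {
      rep(paste(assign[gm$treatments], collapse = "\r"), nrow(df))
    }
    p <- if (is.null(gm$fit$folds)) {
      pm <- predict_learner(gm$fit$models[[1L]], x)
      pm[cbind(seq_len(nrow(df)), match(lv, colnames(pm)))]
    } else {
      out <- numeric(nrow(df))
      for (f in seq_along(gm$fit$models)) {
        idx <- gm$fit$folds == f
        pm <- predict_learner(gm$fit$models[[f]], x[idx, , drop = FALSE])
        out[idx] <- pm[cbind(seq_len(sum(idx)), match(lv[idx], colnames(pm)))]
      }
      out
    }
    p[is.na(p)] <- 0
    return(p)
  }
  p <- rep(1, nrow(df))
  for (tn in gm$treatments) {
    lvls <- if (is.null(assign)) as.character(df[[tn]]) else rep(assign[[tn]], nrow(df))
    fit <- gm$fits[[tn]]
    if (length(unique(lvls)) == 1L) {
      p <- p * predict_g_one(fit, x, lvls[1L])
    } else {
      pl <- vapply(stats::setNames(nm = unique(lvls)),
                   function(l) predict_g_one(fit, x, l), numeric(nrow(df)))
      p <- p * pl[cbind(seq_len(nrow(df)), match(lvls, colnames(pl)))]
    }
  }
  p
}

#' Fit both nuisance functions for an estimand
#'
#' Fits the outcome regression Qbar(A, W, C) and the propensity g(a(s) | W)
#' (product factorization over treatments by default), full-sample or
#' cross-fit, and evaluates them at the observed data and at every vertex of
#' the estimand's baseline/target hypercube. Under a cross-fit plan each
#' individual's predictions come from the model fitted without their fold.
#'
#' @param data A `cohort` or data.frame.
#' @param spec An `estimand`.
#' @param q_learner,g_learner Learner objects (see [learners]).
#' @param plan Optional [crossfit_plan()]; `NULL` for full-sample fits.
#' @param joint_propensity Model the joint treatment categories with a single
#'   multinomial model instead of the per-treatment product.
#' @param g_floor Propensity clipping floor; vertex and observed propensities
#'   are clipped into `[g_floor, 1 - g_floor]` to guard the inverse weights.
#' @return A `nuisance_fits` object: observed and vertex Qbar predictions,
#'   vertex propensities, observed-treatment propensity, vertex match
#'   indicators, outcome, vertices and fold provenance.
#' @export
fit_nuisances <- function(data, spec, q_learner = lrn_glm(),
                          g_learner = lrn_glm(), plan = NULL,
                          joint_propensity = FALSE, g_floor = 1e-5) {
  df <- analysis_sample(data, spec)
  vertices <- vertex_weights(spec)
  check_vertex_support(df, spec, vertices)
  qm <- fit_q_models(df, spec, q_learner, plan)
  gm <- fit_g_models(df, spec, g_learner, plan, joint = joint_propensity)
  assemble_fits(df, spec, vertices, qm, gm, plan, g_floor)
}

check_vertex_support <- function(df, spec, vertices) {
  for (tn in spec$treatments) {
    used <- unique(vertices$a[, tn])
    absent <- setdiff(used, as.character(unique(df[[tn]])))
    if (length(absent))
      stop("positivity error: level(s) ", paste(absent, collapse = ", "),
           " of treatment '", tn, "' absent from the data", call. = FALSE)
  }
}

assemble_fits <- function(df, spec, vertices, qm, gm, plan, g_floor) {
  n <- nrow(df)
  nv <- nrow(vertices)
  qbar_vertex <- matrix(NA_real_, n, nv)
  g_vertex <- matrix(NA_real_, n, nv)
  match_vertex <- matrix(FALSE, n, nv)
  obs <- vapply(spec$treatments, function(tn) as.character(df[[tn]]),
                character(n))
  obs <- matrix(obs, nrow = n, dimnames = list(NULL, spec$treatments))
  for (v in seq_len(nv)) {
    assign <- stats::setNames(vertices$a[v, ], colnames(vertices$a))
    qbar_vertex[, v] <- predict_q(qm, df, assign)
    g_vertex[, v] <- predict_g(gm, df, assign)
    match_vertex[, v] <- rowSums(obs != matrix(assign[spec$treatments],
                                               n, length(assign),
                                               byrow = TRUE)) == 0L
  }
  y <- df[[spec$outcome]]
  fam <- qm$family
  clip <- function(p) pmin(pmax(p, g_floor), 1 - g_floor)
  qbar_obs <- predict_q(qm, df, NULL)
  if (fam == "binomial") {
    qbar_obs <- pmin(pmax(qbar_obs, 1e-6), 1 - 1e-6)
    qbar_vertex <- pmin(pmax(qbar_vertex, 1e-6), 1 - 1e-6)
  }
  structure(list(spec = spec, df = df, y = y, family = fam,
                 vertices = vertices,
                 qbar_obs = qbar_obs, qbar_vertex = qbar_vertex,
                 g_vertex = clip(g_vertex),
                 g_obs = clip(predict_g(gm, df, NULL)),
                 match_vertex = match_vertex,
                 folds = if (is.null(plan)) NULL else plan$folds,
                 q_models = qm, g_models = gm, g_floor = g_floor),
            class = "nuisance_fits")
}

#' @export
print.nuisance_fits <- function(x, ...) {
  cat("<nuisance_fits> n =", length(x$y), "family =", x$family,
      "vertices =", nrow(x$vertices),
      if (is.null(x$folds)) "(full-sample)" else
        paste0("(cross-fit, k = ", length(unique(x$folds)), ")"), "\n")
  invisible(x)
}
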
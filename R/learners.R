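# Nuisance learners. Each learner is a small spec object; fitting goes
# through fit_learner()/predict_learner() with a numeric design matrix and a
# family in {gaussian, binomial, multinomial}. Multinomial is only used for
# propensity models. Binomial/multinomial predictions are probabilities.

new_learner <- function(name, params = list()) {
  structure(list(name = name, params = params),
            class = c(paste0("lrn_", name), "learner"))
}

#' Nuisance learner constructors
#'
#' @description
#' * `lrn_constant()` — the marginal mean / class frequencies; ignores all
#'   predictors. Useful as a deliberately misspecified fit and as an ensemble
#'   floor.
#' * `lrn_glm()` — main-effects (optionally interacted) generalized linear
#'   model. Multinomial outcomes are fitted one-vs-rest and renormalized.
#' * `lrn_glmnet()` — penalized GLM via [glmnet::cv.glmnet()]; `alpha = 0`
#'   is the ridge recommended for routine nuisance fitting.
#' * `lrn_boost()` — native gradient-boosted regression stumps (squared-error
#'   fit to pseudo-residuals, Newton leaf values for binomial); a flexible,
#'   overfit-prone learner standing in for boosted-tree libraries.
#' * `lrn_stack()` — stacked cross-validated ensemble (super learner) over
#'   two or more base learners; `meta = "convex"` fits simplex weights
#'   minimizing CV loss, `meta = "discrete"` picks the single CV-best
#'   learner.
#' * `lrn_hal()` — reserved slot for the Highly Adaptive Lasso; not
#'   implemented, errors on fit.
#'
#' @param interactions For `lrn_glm`: include all pairwise interaction terms.
#' @param alpha,nlambda,nfolds Passed to [glmnet::cv.glmnet()].
#' @param n_rounds,eta,min_obs Boosting rounds, learning rate, minimum
#'   observations per leaf.
#' @param ... For `lrn_stack`: two or more base learners.
#' @param meta Metalearner: convex weights or discrete selection.
#' @return A `learner` object.
#' @name learners
NULL

#' @rdname learners
#' @export
lrn_constant <- function() new_learner("constant")

#' @rdname learners
#' @export
lrn_glm <- function(interactions = FALSE)
  new_learner("glm", list(interactions = interactions))

#' @rdname learners
#' @export
lrn_glmnet <- function(alpha = 0, nlambda = 30, nfolds = 3)
  new_learner("glmnet", list(alpha = alpha, nlambda = nlambda, nfolds = nfolds))

#' @rdname learners
#' @export
lrn_boost <- function(n_rounds = 100, eta = 0.1, min_obs = 10)
  new_learner("boost", list(n_rounds = n_rounds, eta = eta, min_obs = min_obs))

#' @rdname learners
#' @export
lrn_stack <- function(..., meta = c("convex", "discrete")) {
  base <- list(...)
  if (length(base) == 1L && is.list(base[[1]]) && !inherits(base[[1]], "learner"))
    base <- base[[1]]
  if (length(base) < 2L)
    stop("stacked ensemble needs at least 2 base learners", call. = FALSE)
  new_learner("stack", list(base = base, meta = match.arg(meta)))
}

#' @rdname learners
#' @export
lrn_hal <- function() new_learner("hal")

#' @export
print.learner <- function(x, ...) {
  cat("<learner:", x$name, ">\n"); invisible(x)
}

# ---- fitting dispatch -------------------------------------------------------

fit_learner <- function(learner, x, y, family, plan = NULL) {
  UseMethod("fit_learner")
}

predict_learner <- function(object, x) UseMethod("predict_learner")

check_binary_fold <- function(y, what = "training data") {
  if (length(unique(y)) < 2L)
    stop("degenerate fit: single-class binary outcome in ", what, call. = FALSE)
}

# constant --------------------------------------------------------------------

fit_learner.lrn_constant <- function(learner, x, y, family, plan = NULL) {
  fit <- if (family == "multinomial") {
    p <- table(y) / length(y)
    list(levels = names(p), prob = as.numeric(p))
  } else {
    list(mean = mean(y))
  }
  structure(c(fit, list(family = family)), class = "fit_constant")
}

predict_learner.fit_constant <- function(object, x) {
  n <- nrow(x)
  if (object$family == "multinomial")
    matrix(object$prob, n, length(object$prob), byrow = TRUE,
           dimnames = list(NULL, object$levels))
  else rep(object$mean, n)
}

# glm -------------------------------------------------------------------------

expand_interactions <- function(x) {
  p <- ncol(x)
  if (p < 2L) return(x)
  extra <- list()
  for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p))
    extra[[paste0(colnames(x)[i], ":", colnames(x)[j])]] <- x[, i] * x[, j]
  cbind(x, do.call(cbind, extra))
}

fit_glm_vec <- function(x, y, family) {
  xx <- cbind(`(Intercept)` = 1, x)
  fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
  fit <- suppressWarnings(stats::glm.fit(xx, y, family = fam))
  list(coef = ifelse(is.na(fit$coefficients), 0, fit$coefficients),
       family = family)
}

predict_glm_vec <- function(fit, x) {
  eta <- as.vector(cbind(1, x) %*% fit$coef)
  if (fit$family == "binomial") stats::plogis(eta) else eta
}

fit_learner.lrn_glm <- function(learner, x, y, family, plan = NULL) {
  if (isTRUE(learner$params$interactions)) x <- expand_interactions(x)
  if (family == "binomial") check_binary_fold(y)
  fit <- if (family == "multinomial") {
    y <- droplevels_keep(y)
    # one-vs-rest logits, renormalized at prediction time
    lapply(stats::setNames(nm = levels(y)), function(lv)
      fit_glm_vec(x, as.numeric(y == lv), "binomial"))
  } else {
    fit_glm_vec(x, y, family)
  }
  structure(list(fit = fit, family = family,
                 interactions = isTRUE(learner$params$interactions)),
            class = "fit_glm")
}

droplevels_keep <- function(y) {
  y <- as.factor(y)
  if (any(table(y) == 0L)) y <- droplevels(y)
  y
}

predict_learner.fit_glm <- function(object, x) {
  if (object$interactions) x <- expand_interactions(x)
  if (object$family == "multinomial") {
    p <- vapply(object$fit, predict_glm_vec, numeric(nrow(x)), x = x)
    p <- matrix(p, nrow = nrow(x), dimnames = list(NULL, names(object$fit)))
    p / rowSums(p)
  } else {
    predict_glm_vec(object$fit, x)
  }
}

# glmnet ----------------------------------------------------------------------

fit_learner.lrn_glmnet <- function(learner, x, y, family, plan = NULL) {
  if (family == "binomial") check_binary_fold(y)
  p <- learner$params
  if (ncol(x) < 2L) # glmnet needs >= 2 columns; fall back to glm
    return(fit_learner(lrn_glm(), x, y, family))
  fam <- family
  yy <- if (family == "multinomial") droplevels_keep(y) else y
  if (fam == "multinomial" && nlevels(yy) == 2L) {
    fit2 <- fit_learner(learner, x, as.numeric(yy == levels(yy)[2L]), "binomial")
    return(structure(list(fit2 = fit2, levels = levels(yy)), class = "fit_glmnet2"))
  }
  cv <- glmnet::cv.glmnet(x, yy, family = fam, alpha = p$alpha,
                          nlambda = p$nlambda, nfolds = p$nfolds)
  structure(list(cv = cv, family = fam), class = "fit_glmnet")
}

predict_learner.fit_glmnet <- function(object, x) {
  pr <- stats::predict(object$cv, newx = x, s = "lambda.min", type = "response")
  if (object$family == "multinomial") {
    p <- pr[, , 1L]
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L, dimnames = list(NULL, dimnames(pr)[[2]]))
    p
  } else as.vector(pr)
}

predict_learner.fit_glmnet2 <- function(object, x) {
  p1 <- predict_learner(object$fit2, x)
  cbind(matrix(1 - p1, dimnames = list(NULL, object$levels[1L])),
        matrix(p1, dimnames = list(NULL, object$levels[2L])))
}

# gradient-boosted stumps -----------------------------------------------------

best_stump <- function(x, g, h, min_obs) {
  # squared-error fit of pseudo-residuals g, Newton leaf values g/h
  best <- NULL; best_gain <- -Inf
  tot_g <- sum(g); tot_h <- sum(h)
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    cuts <- unique(stats::quantile(xj, probs = seq(0.1, 0.9, by = 0.1),
                                   names = FALSE, type = 1L))
    for (cut in cuts) {
      left <- xj <= cut
      nl <- sum(left)
      if (nl < min_obs || (length(g) - nl) < min_obs) next
      gl <- sum(g[left]); hl <- sum(h[left])
      gain <- gl^2 / hl + (tot_g - gl)^2 / (tot_h - hl)
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(j = j, cut = cut, vl = gl / hl,
                     vr = (tot_g - gl) / (tot_h - hl))
      }
    }
  }
  best
}

boost_fit_vec <- function(x, y, family, n_rounds, eta, min_obs) {
  f0 <- if (family == "binomial") stats::qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6))
        else mean(y)
  f <- rep(f0, length(y))
  stumps <- vector("list", n_rounds)
  for (m in seq_len(n_rounds)) {
    if (family == "binomial") {
      p <- stats::plogis(f); g <- y - p; h <- pmax(p * (1 - p), 1e-6)
    } else {
      g <- y - f; h <- rep(1, length(y))
    }
    st <- best_stump(x, g, h, min_obs)
    if (is.null(st)) break
    stumps[[m]] <- st
    f <- f + eta * ifelse(x[, st$j] <= st$cut, st$vl, st$vr)
  }
  list(f0 = f0, stumps = Filter(Negate(is.null), stumps),
       eta = eta, family = family)
}

boost_predict_vec <- function(fit, x) {
  f <- rep(fit$f0, nrow(x))
  for (st in fit$stumps)
    f <- f + fit$eta * ifelse(x[, st$j] <= st$cut, st$vl, st$vr)
  if (fit$family == "binomial") stats::plogis(f) else f
}

fit_learner.lrn_boost <- function(learner, x, y, family, plan = NULL) {
  p <- learner$params
  if (family == "binomial") check_binary_fold(y)
  fit <- if (family == "multinomial") {
    y <- droplevels_keep(y)
    lapply(stats::setNames(nm = levels(y)), function(lv)
      boost_fit_vec(x, as.numeric(y == lv), "binomial",
                    p$n_rounds, p$eta, p$min_obs))
  } else {
    boost_fit_vec(x, y, family, p$n_rounds, p$eta, p$min_obs)
  }
  structure(list(fit = fit, family = family), class = "fit_boost")
}

predict_learner.fit_boost <- function(object, x) {
  if (object$family == "multinomial") {
    p <- vapply(object$fit, boost_predict_vec, numeric(nrow(x)), x = x)
    p <- matrix(p, nrow = nrow(x), dimnames = list(NULL, names(object$fit)))
    p / rowSums(p)
  } else boost_predict_vec(object$fit, x)
}

# hal (pluggable slot only) ---------------------------------------------------

fit_learner.lrn_hal <- function(learner, x, y, family, plan = NULL)
  stop("the Highly Adaptive Lasso learner slot is not implemented", call. = FALSE)

# stacked ensemble ------------------------------------------------------------

cv_loss <- function(pred, y, family) {
  if (family == "gaussian") return(mean((y - pred)^2))
  eps <- 1e-12
  if (family == "binomial") {
    p <- pmin(pmax(pred, eps), 1 - eps)
    return(-mean(y * log(p) + (1 - y) * log(1 - p)))
  }
  # multinomial log-loss: pred is a matrix with class columns
  p <- pmin(pmax(pred[cbind(seq_along(y), match(as.character(y), colnames(pred)))],
                 eps), 1)
  -mean(log(p))
}

simplex_weights <- function(preds, y, family) {
  # preds: list of out-of-fold prediction vectors/matrices, one per learner
  m <- length(preds)
  obj <- function(w) {
    w <- pmax(w, 0); s <- sum(w)
    if (s <= 0) return(Inf)
    w <- w / s
    comb <- Reduce(`+`, Map(function(p, wi) p * wi, preds, w))
    cv_loss(comb, y, family)
  }
  opt <- stats::optim(rep(1 / m, m), obj, method = "L-BFGS-B",
                      lower = 0, upper = 1)
  w <- pmax(opt$par, 0); w / sum(w)
}

#' Fit a stacked cross-validated ensemble
#'
#' Computes out-of-fold predictions for every base learner over the folds of
#' `plan`, chooses a convex (or discrete winner-take-all) weighting
#' minimizing the cross-validated loss (squared error for gaussian, log-loss
#' for binomial/multinomial), then refits every base learner on the full
#' sample.
#'
#' @param base_learners List of two or more `learner` objects.
#' @param x Numeric design matrix.
#' @param y Response (factor for multinomial).
#' @param plan A [crossfit_plan()] for the internal CV split.
#' @param family `"gaussian"`, `"binomial"` or `"multinomial"`.
#' @param meta `"convex"` or `"discrete"`.
#' @return A fitted ensemble with `$weights` and `$cv_losses`, usable with
#'   the internal prediction generic.
#' @export
stacked_ensemble_fit <- function(base_learners, x, y, plan, family,
                                 meta = "convex") {
  if (length(base_learners) < 2L)
    stop("stacked ensemble needs at least 2 base learners", call. = FALSE)
  folds <- plan$folds
  n <- length(y)
  oof <- vector("list", length(base_learners))
  errors <- character()
  for (b in seq_along(base_learners)) {
    pred <- NULL
    ok <- TRUE
    for (f in sort(unique(folds))) {
      tr <- folds != f
      fit <- tryCatch(
        fit_learner(base_learners[[b]], x[tr, , drop = FALSE],
                    if (is.factor(y)) droplevels_keep(y[tr]) else y[tr], family),
        error = function(e) e)
      if (inherits(fit, "error")) {
        errors <- c(errors, conditionMessage(fit)); ok <- FALSE; break
      }
      p <- predict_learner(fit, x[!tr, , drop = FALSE])
      if (is.null(pred))
        pred <- if (is.matrix(p)) matrix(NA_real_, n, ncol(p),
                                         dimnames = list(NULL, colnames(p)))
                else rep(NA_real_, n)
      if (is.matrix(p)) pred[!tr, colnames(p)] <- p else pred[!tr] <- p
    }
    oof[[b]] <- if (ok) pred else NULL
  }
  keep <- !vapply(oof, is.null, TRUE)
  if (!any(keep))
    stop("ensemble error: all base learners failed: ",
         paste(unique(errors), collapse = "; "), call. = FALSE)
  losses <- rep(NA_real_, length(base_learners))
  losses[keep] <- vapply(oof[keep], cv_loss, 0, y = y, family = family)
  weights <- numeric(length(base_learners))
  if (meta == "discrete") {
    weights[which.min(losses)] <- 1
  } else {
    weights[keep] <- simplex_weights(oof[keep], y, family)
  }
  fits <- vector("list", length(base_learners))
  for (b in which(weights > 1e-8))
    fits[[b]] <- fit_learner(base_learners[[b]], x, y, family)
  structure(list(fits = fits, weights = weights, cv_losses = losses,
                 family = family, meta = meta),
            class = "fit_stack")
}

fit_learner.lrn_stack <- function(learner, x, y, family, plan = NULL) {
  if (is.null(plan))
    plan <- crossfit_plan(length(y), k_folds = 3L,
                          strata = if (is.factor(y) || is_binary(y)) y,
                          seed = 104729L)
  stacked_ensemble_fit(learner$params$base, x, y, plan, family,
                       meta = learner$params$meta)
}

predict_learner.fit_stack <- function(object, x) {
  preds <- Map(function(fit, w) if (w > 1e-8) predict_learner(fit, x) * w,
               object$fits, object$weights)
  Reduce(`+`, Filter(Negate(is.null), preds))
}

# ---- cross-fitting plan -----------------------------------------------------

#' Cross-fitting fold assignment
#'
#' Partitions the sample into `k_folds` folds, optionally stratified (e.g.
#' jointly on genotype and a binary outcome) so every fold sees all classes.
#'
#' @param n Sample size.
#' @param k_folds Number of folds (>= 2; default 3).
#' @param strata Optional vector (or data.frame of vectors) of stratification
#'   labels of length `n`.
#' @param seed Integer seed for the fold shuffle.
#' @return A `crossfit_plan`: list with `$folds` (integer in 1..k) and `$k`.
#' @export
crossfit_plan <- function(n, k_folds = 3L, strata = NULL, seed = 1L) {
  k_folds <- as.integer(k_folds)
  if (k_folds < 2L) stop("k_folds must be >= 2", call. = FALSE)
  if (!is.null(strata)) {
    if (is.list(strata)) strata <- interaction(strata, drop = TRUE)
    stopifnot(length(strata) == n)
  }
  folds <- integer(n)
  groups <- if (is.null(strata)) list(seq_len(n)) else split(seq_len(n), strata)
  withr::with_seed(seed, {
    for (idx in groups)
      folds[sample(idx)] <- rep_len(seq_len(k_folds), length(idx))
  })
  structure(list(folds = folds, k = k_folds, seed = seed),
            class = "crossfit_plan")
}

#' Adaptive fold count for rare binary outcomes
#'
#' `k = min(20, max(3, floor(rare_count / 10)))` where `rare_count` is the
#' size of the rarest outcome class — more folds for rarer cases so each
#' training split retains enough of them.
#'
#' @param y Binary outcome vector.
#' @return Integer fold count in 3..20.
#' @export
adaptive_k_folds <- function(y) {
  rare <- min(table(y))
  as.integer(min(20L, max(3L, floor(rare / 10))))
}

# HWE allele-count logistic propensity ---------------------------------------

#' @rdname learners
#' @details `lrn_hwe_glm()` models a genotype's allele count as
#'   `Binomial(2, expit(W b))` — a Hardy-Weinberg-consistent logistic allele
#'   model — and converts the fitted allele probability into the three
#'   genotype probabilities. Only valid as a propensity learner for
#'   treatments whose levels are allele counts `0/1/2` (or two of them).
#' @export
lrn_hwe_glm <- function() new_learner("hwe_glm")

fit_learner.lrn_hwe_glm <- function(learner, x, y, family, plan = NULL) {
  if (family != "multinomial")
    stop("lrn_hwe_glm is a propensity (multinomial) learner", call. = FALSE)
  y <- droplevels_keep(y)
  lv <- levels(y)
  if (!all(lv %in% c("0", "1", "2")))
    stop("lrn_hwe_glm needs genotype levels coded 0/1/2", call. = FALSE)
  d <- as.numeric(as.character(y))
  xx <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(stats::glm.fit(xx, cbind(d, 2 - d),
                                         family = stats::binomial()))
  structure(list(coef = ifelse(is.na(fit$coefficients), 0,
                               fit$coefficients), levels = lv),
            class = "fit_hwe_glm")
}

predict_learner.fit_hwe_glm <- function(object, x) {
  p <- stats::plogis(as.vector(cbind(1, x) %*% object$coef))
  probs <- cbind(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
  probs <- probs[, object$levels, drop = FALSE]
  probs / rowSums(probs)
}
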
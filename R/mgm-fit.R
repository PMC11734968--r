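#' Extended Bayesian information criterion
#'
#' `EBIC = -2 loglik + df log(n) + 2 gamma df log(q)`, where `df` is the
#' number of nonzero coefficients and `q` the number of candidate predictor
#' terms of the nodewise regression. With `gamma = 0` this reduces to the
#' ordinary BIC; larger `gamma` penalizes dense models more heavily. The
#' pipeline default is the conservative `gamma = 0.25`.
#'
#' @param loglik Log-likelihood of the fitted model.
#' @param df Number of nonzero coefficients.
#' @param n Number of observations.
#' @param q Number of candidate predictor terms.
#' @param gamma Nonnegative EBIC hyper-parameter.
#' @return The EBIC value (smaller is better).
#' @export
#' @examples
#' ebic_score(-150, df = 3, n = 100, q = 29, gamma = 0.25)
ebic_score <- function(loglik, df, n, q, gamma) {
  stopifnot(n >= 1, q >= 1, gamma >= 0)
  -2 * loglik + df * log(n) + 2 * gamma * df * log(q)
}

# Design matrix for the regression of `node` on all other variables:
# continuous predictors enter as-is (the dataset is standardized upstream),
# categorical predictors are dummy-coded against their first level. With a
# moderator, product terms term_j * x_m are appended for all j outside
# {node, moderator}.
nodewise_design <- function(x, node, moderator = NULL) {
  spec <- x$spec
  others <- setdiff(spec$name, node)
  cols <- list()
  targets <- character()
  kinds <- character()
  for (nm in others) {
    i <- match(nm, spec$name)
    if (spec$domain[i] == "continuous") {
      v <- x$data[[nm]]
      if (stats::sd(v) == 0) stop(sprintf("zero-variance predictor '%s'", nm))
      cols[[nm]] <- v
      targets[nm] <- nm
      kinds[nm] <- "base"
    } else {
      lev <- levels(x$data[[nm]])
      f <- x$data[[nm]]
      for (l in lev[-1]) {
        tn <- paste0(nm, ".", l)
        cols[[tn]] <- as.numeric(f == l)
        targets[tn] <- nm
        kinds[tn] <- "base"
      }
    }
  }
  if (!is.null(moderator) && moderator != node) {
    m <- x$data[[moderator]]
    base_terms <- names(cols)
    for (tn in base_terms) {
      if (targets[tn] == moderator) next
      pn <- paste0(tn, ":", moderator)
      cols[[pn]] <- cols[[tn]] * m
      targets[pn] <- targets[tn]
      kinds[pn] <- "product"
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, targets = targets, kinds = kinds)
}

#' Fit one nodewise l1-regularized regression with EBIC selection
#'
#' Regresses `node` on all other variables of the dataset: a penalized
#' linear regression for continuous nodes, a penalized multinomial logistic
#' regression for categorical nodes. The penalty path holds `nlambda`
#' log-spaced values from the smallest all-zero penalty `lambda_max` down to
#' `lambda_min_ratio * lambda_max`. For each penalty the EBIC is computed
#' with `df` equal to the nonzero coefficient count and `q` the number of
#' candidate terms; the penalty minimizing the EBIC is selected, with ties
#' broken toward the larger penalty (sparser model).
#'
#' @param x A standardized [mixed_data()] (see [standardize_continuous()]).
#' @param node Name of the response variable.
#' @param gamma EBIC hyper-parameter (default 0.25).
#' @param nlambda Number of penalty values on the path.
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty.
#' @param lambda_grid Optional explicit descending penalty sequence
#'   overriding the automatic path.
#' @param moderator Optional continuous moderator; adds product terms (used
#'   by [fit_moderated()]).
#' @param select `"ebic"` (default) selects the EBIC-minimizing penalty;
#'   `"min_lambda"` selects the weakest penalty on the path (the
#'   near-unpenalized fit used to check estimator consistency against
#'   closed-form partial correlations).
#'
#' @return An object of class `nodewise_fit`.
#' @export
fit_nodewise <- function(x, node, gamma = 0.25, nlambda = 50,
                         lambda_min_ratio = 0.01, lambda_grid = NULL,
                         moderator = NULL, select = c("ebic", "min_lambda")) {
  select <- match.arg(select)
  stopifnot(inherits(x, "mixed_data"))
  i <- match(node, x$spec$name)
  if (is.na(i)) stop("unknown node: ", node)
  des <- nodewise_design(x, node, moderator = moderator)
  X <- des$X
  n <- nrow(X)
  q <- ncol(X)
  real_terms <- colnames(X)
  if (q == 1) {
    # glmnet needs >= 2 columns; an all-zero pad never enters the model
    X <- cbind(X, `.pad.` = 0)
  }
  domain <- x$spec$domain[i]
  if (domain == "continuous") {
    y <- x$data[[node]]
    fit <- glmnet::glmnet(X, y, family = "gaussian",
                          standardize = FALSE, intercept = TRUE,
                          nlambda = nlambda,
                          lambda.min.ratio = lambda_min_ratio,
                          lambda = lambda_grid)
    beta <- as.matrix(fit$beta)[real_terms, , drop = FALSE]
    df <- colSums(beta != 0)
    pred <- stats::predict(fit, X)
    rss <- colSums((y - pred)^2)
    loglik <- -n / 2 * (log(2 * pi * rss / n) + 1)
  } else {
    y <- x$data[[node]]
    fit <- glmnet::glmnet(X, y, family = "multinomial",
                          standardize = FALSE, intercept = TRUE,
                          nlambda = nlambda,
                          lambda.min.ratio = lambda_min_ratio,
                          lambda = lambda_grid)
    beta_list <- lapply(fit$beta, function(b) {
      as.matrix(b)[real_terms, , drop = FALSE]
    })
    df <- Reduce(`+`, lapply(beta_list, function(b) colSums(b != 0)))
    prob <- stats::predict(fit, X, type = "response")
    yi <- as.integer(y)
    loglik <- vapply(seq_along(fit$lambda), function(l) {
      pl <- prob[cbind(seq_len(n), yi, l)]
      sum(log(pmax(pl, 1e-12)))
    }, numeric(1))
  }
  ebic <- ebic_score(loglik, df, n, q, gamma)
  bad <- !is.finite(ebic)
  if (any(bad)) {
    warning(sprintf("skipping %d non-finite penalty value(s) for node '%s'",
                    sum(bad), node))
    ebic[bad] <- Inf
  }
  sel <- if (select == "min_lambda") {
    length(fit$lambda)
  } else {
    which.min(ebic)  # lambda is descending: ties go to the sparser fit
  }
  if (domain == "continuous") {
    coefs <- stats::setNames(beta[, sel], rownames(beta))
    intercept <- fit$a0[sel]
    resp <- stats::predict(fit, X, s = fit$lambda[sel])[, 1]
    r2 <- 1 - sum((y - resp)^2) / sum((y - mean(y))^2)
    accuracy <- NA_real_
    baseline <- NA_real_
    targets <- des$targets
    kinds <- des$kinds
  } else {
    coefs <- unlist(lapply(names(beta_list), function(cl) {
      b <- stats::setNames(beta_list[[cl]][, sel], rownames(beta_list[[cl]]))
      stats::setNames(b, paste0(cl, "~", names(b)))
    }))
    intercept <- fit$a0[, sel]
    names(intercept) <- names(beta_list)
    pr <- prob[, , sel]
    pred_class <- levels(y)[max.col(pr, ties.method = "first")]
    accuracy <- mean(pred_class == as.character(y))
    baseline <- max(table(y)) / n
    r2 <- NA_real_
    targets <- stats::setNames(
      rep(des$targets, length(beta_list)),
      unlist(lapply(names(beta_list), function(cl) paste0(cl, "~", names(des$targets))))
    )
    kinds <- stats::setNames(
      rep(des$kinds, length(beta_list)),
      names(targets)
    )
  }
  structure(
    list(node = node, domain = domain,
         lambda_grid = fit$lambda,
         selected_lambda = fit$lambda[sel],
         coefficients = coefs,
         intercept = intercept,
         term_targets = targets,
         term_kinds = kinds,
         moderator = moderator,
         loglik = unname(loglik[sel]), df = unname(df[sel]),
         ebic = unname(ebic[sel]),
         r_squared = r2, accuracy = accuracy, baseline = baseline,
         path = tibble::tibble(lambda = fit$lambda, df = as.integer(df),
                               loglik = unname(loglik), ebic = unname(ebic)),
         n = n, q = q, gamma = gamma),
    class = "nodewise_fit"
  )
}

#' @export
print.nodewise_fit <- function(x, ...) {
  cat(sprintf("<nodewise_fit> node '%s' (%s): lambda = %.4g, df = %d, EBIC = %.2f\n",
              x$node, x$domain, x$selected_lambda, x$df, x$ebic))
  invisible(x)
}

# Directed magnitude of i -> j: mean absolute value over all coefficient
# terms in i's fit that involve variable j (several terms when categorical
# levels are involved), restricted to `kind`.
directed_magnitudes <- function(fits, nodes, kind = "base") {
  p <- length(nodes)
  M <- matrix(0, p, p, dimnames = list(nodes, nodes))
  S <- matrix(0, p, p, dimnames = list(nodes, nodes))  # directed sign
  for (f in fits) {
    i <- match(f$node, nodes)
    keep <- f$term_kinds == kind
    co <- f$coefficients[keep]
    tg <- f$term_targets[keep]
    for (j_nm in unique(tg)) {
      j <- match(j_nm, nodes)
      if (is.na(j)) next
      vals <- co[tg == j_nm]
      M[i, j] <- mean(abs(vals))
      if (length(vals) == 1) S[i, j] <- sign(vals)
    }
  }
  list(magnitude = M, sign = S)
}

#' Aggregate nodewise fits into a weighted network
#'
#' Combines the two directed regressions of each node pair into one
#' undirected edge. The directed magnitude i -> j is the mean absolute value
#' of all coefficient terms linking j in i's fit. Under the `AND` rule an
#' edge is present only when both directions are nonzero (magnitude = mean
#' of the two); under `OR` when at least one is (magnitude = mean of the
#' nonzero ones). An edge sign is defined only for continuous-continuous
#' pairs and only when the nonzero directed coefficients agree in sign;
#' edges involving a categorical variable are unsigned.
#'
#' @param fits List of [fit_nodewise()] results, one per node.
#' @param rule `"AND"` (default) or `"OR"`.
#' @return An object of class `mgm_network`.
#' @export
aggregate_network <- function(fits, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  nodes <- unname(vapply(fits, function(f) f$node, character(1)))
  if (anyDuplicated(nodes)) stop("duplicate nodewise fits")
  domains <- unname(vapply(fits, function(f) f$domain, character(1)))
  targets_all <- unique(unlist(lapply(fits, function(f) unname(f$term_targets))))
  if (!all(targets_all %in% nodes)) {
    stop("mismatched node sets between fits")
  }
  p <- length(nodes)
  dm <- directed_magnitudes(fits, nodes, kind = "base")
  magnitude <- matrix(0, p, p, dimnames = list(nodes, nodes))
  sign_m <- matrix(0, p, p, dimnames = list(nodes, nodes))
  inv_cat <- outer(domains == "categorical", domains == "categorical", `|`)
  dimnames(inv_cat) <- list(nodes, nodes)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      a <- dm$magnitude[i, j]
      b <- dm$magnitude[j, i]
      nz <- c(a, b)[c(a, b) > 0]
      mag <- if (rule == "AND") {
        if (a > 0 && b > 0) mean(c(a, b)) else 0
      } else {
        if (length(nz)) mean(nz) else 0
      }
      magnitude[i, j] <- magnitude[j, i] <- mag
      if (mag > 0 && !inv_cat[i, j]) {
        s <- c(dm$sign[i, j], dm$sign[j, i])
        s <- s[s != 0]
        if (length(s) && length(unique(s)) == 1) {
          sign_m[i, j] <- sign_m[j, i] <- s[1]
        }
      }
    }
  }
  diag(inv_cat) <- FALSE
  new_mgm_network(nodes, magnitude, sign_m, inv_cat, domains)
}

new_mgm_network <- function(nodes, magnitude, sign, involves_categorical,
                            domains) {
  stopifnot(isSymmetric(unname(magnitude)), all(magnitude >= 0),
            all(diag(magnitude) == 0))
  structure(
    list(nodes = nodes, magnitude = magnitude, sign = sign,
         involves_categorical = involves_categorical, domains = domains),
    class = "mgm_network"
  )
}

#' @export
print.mgm_network <- function(x, ...) {
  ne <- sum(x$magnitude[upper.tri(x$magnitude)] > 0)
  cat(sprintf("<mgm_network> %d nodes, %d edges\n", length(x$nodes), ne))
  invisible(x)
}

#' Tidy a weighted network into an edge list
#'
#' @param x An `mgm_network`.
#' @param all If `TRUE`, include zero-magnitude pairs.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `magnitude`, `sign`,
#'   `involves_categorical`.
#' @export
tidy.mgm_network <- function(x, all = FALSE, ...) {
  p <- length(x$nodes)
  idx <- upper_pairs(p)
  out <- tibble::tibble(
    from = x$nodes[idx[, 1]],
    to = x$nodes[idx[, 2]],
    magnitude = x$magnitude[idx],
    sign = x$sign[idx],
    involves_categorical = x$involves_categorical[idx]
  )
  if (!all) out <- dplyr::filter(out, .data$magnitude > 0)
  out
}

#' Fit a pairwise mixed graphical model
#'
#' Runs one nodewise l1-regularized regression per variable (linear for
#' continuous nodes, multinomial for categorical nodes), selects each
#' penalty by EBIC, and aggregates the fits into a signed weighted network.
#' Continuous variables are standardized internally so edge weights are
#' comparable across variable pairs (cf. partial correlations).
#'
#' @inheritParams fit_nodewise
#' @param rule Edge combination rule, `"AND"` (default) or `"OR"`.
#' @return An object of class `mgm_fit` with elements `fits`, `network`,
#'   `data` (the standardized dataset), `gamma` and `rule`.
#' @export
#' @examples
#' sim <- study_mimic(seed = 1, n = 300)
#' fit <- fit_mgm(sim$data)
#' tidy(fit)
fit_mgm <- function(x, gamma = 0.25, rule = c("AND", "OR"), nlambda = 50,
                    lambda_min_ratio = 0.01, select = c("ebic", "min_lambda")) {
  rule <- match.arg(rule)
  select <- match.arg(select)
  stopifnot(inherits(x, "mixed_data"))
  xs <- standardize_continuous(x)
  fits <- lapply(xs$spec$name, function(nm) {
    fit_nodewise(xs, nm, gamma = gamma, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio, select = select)
  })
  names(fits) <- xs$spec$name
  network <- aggregate_network(fits, rule = rule)
  structure(list(fits = fits, network = network, data = xs,
                 gamma = gamma, rule = rule),
            class = "mgm_fit")
}

#' @export
print.mgm_fit <- function(x, ...) {
  cat(sprintf("<mgm_fit> gamma = %.2f, %s rule\n", x$gamma, x$rule))
  print(x$network)
  invisible(x)
}

#' @export
tidy.mgm_fit <- function(x, ...) tidy(x$network, ...)

#' @export
glance.mgm_fit <- function(x, ...) {
  tibble::tibble(
    nodes = length(x$network$nodes),
    edges = sum(x$network$magnitude[upper.tri(x$network$magnitude)] > 0),
    gamma = x$gamma,
    rule = x$rule,
    n = x$data$n
  )
}

predict_nodewise <- function(fit, x) {
  des <- nodewise_design(x, fit$node, moderator = fit$moderator)
  if (fit$domain == "continuous") {
    keep <- names(fit$coefficients)
    as.vector(des$X[, keep, drop = FALSE] %*% fit$coefficients) + fit$intercept
  } else {
    classes <- names(fit$intercept)
    eta <- vapply(classes, function(cl) {
      pre <- paste0(cl, "~")
      co <- fit$coefficients[startsWith(names(fit$coefficients), pre)]
      terms <- sub(pre, "", names(co), fixed = TRUE)
      as.vector(des$X[, terms, drop = FALSE] %*% co) + fit$intercept[[cl]]
    }, numeric(nrow(des$X)))
    classes[max.col(eta, ties.method = "first")]
  }
}

#' Nodewise predictability
#'
#' How well each node is predicted by its selected neighborhood: in-sample
#' proportion of explained variance (R squared) for continuous nodes, and
#' in-sample classification accuracy for categorical nodes, reported next to
#' the marginal-mode baseline accuracy (the accuracy of always predicting
#' the most frequent level). A categorical node with an empty neighborhood
#' has accuracy exactly equal to that baseline.
#'
#' @param x The [mixed_data()] the fits were estimated on (standardized
#'   internally), or an `mgm_fit` (in which case `fits` is ignored).
#' @param fits List of [fit_nodewise()] results (when `x` is a dataset).
#' @return A tibble with columns `node`, `domain`, `r_squared`, `accuracy`,
#'   `baseline`.
#' @export
predictability <- function(x, fits = NULL) {
  if (inherits(x, "mgm_fit")) {
    fits <- x$fits
    xs <- x$data
  } else {
    stopifnot(inherits(x, "mixed_data"), !is.null(fits))
    xs <- standardize_continuous(x)
  }
  rows <- lapply(fits, function(f) {
    if (f$domain == "continuous") {
      yhat <- predict_nodewise(f, xs)
      y <- xs$data[[f$node]]
      r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
      tibble::tibble(node = f$node, domain = f$domain,
                     r_squared = r2, accuracy = NA_real_,
                     baseline = NA_real_)
    } else {
      yhat <- predict_nodewise(f, xs)
      y <- as.character(xs$data[[f$node]])
      tibble::tibble(node = f$node, domain = f$domain,
                     r_squared = NA_real_,
                     accuracy = mean(yhat == y),
                     baseline = max(table(y)) / length(y))
    }
  })
  dplyr::bind_rows(rows)
}
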
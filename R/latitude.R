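## Latitudinal analysis of thermal sensitivity: predictor transforms, a
## candidate set of species random-intercept models (with or without
## phylogenetic correlation), information-criterion model selection, and
## marginal/conditional variance partitioning.

#' Latitude predictor transforms
#'
#' @param lat Latitude(s) in decimal degrees, |lat| <= 90.
#' @param bin_edges Two increasing thresholds (degrees absolute latitude)
#'   separating the low / intermediate / high bins. Default 20 and 40.
#' @return data.frame with `abs_deg` (absolute degrees), `cos_rad`
#'   (cosine of the latitude in radians) and `bin` (factor low /
#'   intermediate / high).
#' @examples
#' latitude_transforms(c(0, -35, 62))
#' @export
latitude_transforms <- function(lat, bin_edges = c(20, 40)) {
  if (any(abs(lat) > 90, na.rm = TRUE)) stop("latitude out of [-90, 90]")
  stopifnot(length(bin_edges) == 2, bin_edges[1] < bin_edges[2])
  abs_deg <- abs(lat)
  bin <- cut(abs_deg, c(-Inf, bin_edges, Inf),
             labels = c("low", "intermediate", "high"), right = FALSE)
  data.frame(abs_deg = abs_deg, cos_rad = cos(lat * pi / 180), bin = bin)
}

## Profiled-ML linear mixed model with one random intercept per species:
##   y = X beta + Z u + e,  u ~ N(0, tau2 * K),  e ~ N(0, sigma2 * I).
## K is the identity (non-phylogenetic) or a phylogenetic correlation
## matrix among species. The variance ratio gamma = tau2/sigma2 is
## optimised on the log scale with sigma2 and beta profiled out.
.fit_species_mixed <- function(y, X, species, K = NULL) {
  n <- length(y)
  sp <- factor(species)
  Z <- stats::model.matrix(~ sp - 1)
  if (is.null(K)) {
    ZKZ <- tcrossprod(Z)
  } else {
    idx <- match(levels(sp), rownames(K))
    if (anyNA(idx)) stop("species missing from the phylogenetic ",
                         "correlation matrix: ",
                         paste(levels(sp)[is.na(idx)], collapse = ", "))
    ZKZ <- Z %*% K[idx, idx] %*% t(Z)
  }
  p <- ncol(X)
  if (p + 2 >= n) stop("fewer observations than parameters")

  prof <- function(log_gamma) {
    g <- exp(log_gamma)
    V0 <- diag(n) + g * ZKZ
    L <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(L)) return(list(loglik = -Inf))
    Xw <- backsolve(L, X, transpose = TRUE)
    yw <- backsolve(L, y, transpose = TRUE)
    fit <- stats::lm.fit(Xw, yw)
    s2 <- sum(fit$residuals^2) / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + 2 * sum(log(diag(L))) + n)
    beta <- stats::setNames(fit$coefficients, colnames(X))
    list(loglik = ll, beta = beta, sigma2 = s2, gamma = g, Xw = Xw)
  }
  opt <- stats::optimize(function(lg) -prof(lg)$loglik, c(-12, 8))
  cand <- list(prof(opt$minimum), prof(-Inf))  # include gamma -> 0 limit
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "loglik"))]]
  beta <- best$beta
  vc <- best$sigma2 * chol2inv(chol(crossprod(best$Xw)))
  se <- stats::setNames(sqrt(diag(vc)), colnames(X))
  ci <- cbind(lower = beta - stats::qnorm(0.975) * se,
              upper = beta + stats::qnorm(0.975) * se)
  eta <- drop(X %*% beta)
  k_par <- p + 2  # fixed effects + tau2 + sigma2
  list(beta = beta, se = se, ci = ci,
       tau2 = best$gamma * best$sigma2, sigma2 = best$sigma2,
       var_fixed = stats::var(eta),
       loglik = best$loglik, aic = -2 * best$loglik + 2 * k_par,
       n = n, n_species = nlevels(sp))
}

#' Fit the candidate set of latitude models
#'
#' Response is a transformed thermal-sensitivity value (ln E or ln W_op);
#' candidate fixed-effect structures are latitude-only, trait-only,
#' latitude + trait, and latitude x trait, each fitted by maximum
#' likelihood with a species random intercept. When a tree is supplied,
#' a phylogenetic variant of each candidate (species effects correlated by
#' the tree) is fitted as well. An intercept-only model is always included
#' as the fallback.
#'
#' @param records data.frame with columns `species_id`, `trait_name`,
#'   `value` (the response) and `latitude` (decimal degrees).
#' @param tree Optional rooted ape `phylo` tree covering the species.
#' @param latitude_form Which latitude transform enters the fixed effects:
#'   `"abs_deg"` (default), `"cos_rad"`, or `"bin"`.
#' @param bin_edges Bin thresholds for `latitude_form = "bin"`.
#' @return Object of class `"latitude_model_set"`: list of candidates,
#'   each with `name`, `phylo`, and the fit (`beta`, `se`, `ci`, `aic`,
#'   `tau2`, `sigma2`, `var_fixed`, ...).
#' @export
fit_latitude_models <- function(records, tree = NULL,
                                latitude_form = c("abs_deg", "cos_rad",
                                                  "bin"),
                                bin_edges = c(20, 40)) {
  latitude_form <- match.arg(latitude_form)
  need <- c("species_id", "trait_name", "value", "latitude")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  records <- records[stats::complete.cases(records[, need]), , drop = FALSE]
  if (!nrow(records)) stop("no complete records")
  lt <- latitude_transforms(records$latitude, bin_edges)
  records$lat_pred <- switch(latitude_form,
                             abs_deg = lt$abs_deg,
                             cos_rad = lt$cos_rad,
                             bin = lt$bin)
  n_traits <- length(unique(records$trait_name))
  lat_varies <- length(unique(records$lat_pred)) > 1
  if (n_traits < 2 && !lat_varies)
    stop("need at least 2 trait groups or non-constant latitude")

  K <- NULL
  if (!is.null(tree)) {
    .check_tree(tree)
    keep <- intersect(tree$tip.label, unique(records$species_id))
    if (length(keep) < length(unique(records$species_id)))
      stop("species missing from the tree: ",
           paste(setdiff(unique(records$species_id), keep), collapse = ", "))
    Csp <- phylo_vcv(ape::keep.tip(tree, keep))
    K <- stats::cov2cor(Csp)
  }

  forms <- list(intercept_only = ~ 1)
  if (lat_varies) forms$latitude <- ~ lat_pred
  if (n_traits >= 2) forms$trait <- ~ trait_name
  if (lat_varies && n_traits >= 2) {
    forms$`latitude+trait` <- ~ lat_pred + trait_name
    forms$`latitude:trait` <- ~ lat_pred * trait_name
  }

  out <- list()
  for (nm in names(forms)) {
    X <- stats::model.matrix(forms[[nm]], data = records)
    for (ph in if (is.null(K)) FALSE else c(FALSE, TRUE)) {
      fit <- tryCatch(
        .fit_species_mixed(records$value, X, records$species_id,
                           K = if (ph) K else NULL),
        error = function(e) {
          message("candidate '", nm, "' skipped: ", conditionMessage(e))
          NULL
        })
      if (is.null(fit)) next
      out[[paste0(nm, if (ph) "+phylo" else "")]] <-
        c(list(name = nm, phylo = ph), fit)
    }
  }
  structure(out, class = "latitude_model_set",
            latitude_form = latitude_form)
}

#' @export
print.latitude_model_set <- function(x, ...) {
  cat("Latitude candidate models (ML, species random intercept):\n")
  for (nm in names(x))
    cat(sprintf("  %-24s AIC = %.2f\n", nm, x[[nm]]$aic))
  invisible(x)
}

#' Select among fitted latitude models
#'
#' Candidates with any non-intercept coefficient whose 95% CI includes 0
#' are discarded; among the survivors the lowest-AIC model wins. When
#' every candidate with predictors is discarded, the intercept-only model
#' is returned with `fallback = TRUE`.
#'
#' @param candidates A `"latitude_model_set"` from [fit_latitude_models].
#' @return The chosen candidate (list), with elements `model_name` and
#'   `fallback` added.
#' @export
select_model <- function(candidates) {
  stopifnot(inherits(candidates, "latitude_model_set"),
            length(candidates) >= 1)
  survives <- function(m) {
    keep <- setdiff(names(m$beta), "(Intercept)")
    if (!length(keep)) return(TRUE)
    all(m$ci[keep, "lower"] > 0 | m$ci[keep, "upper"] < 0)
  }
  with_pred <- Filter(function(m) m$name != "intercept_only", candidates)
  ok <- Filter(survives, with_pred)
  if (length(ok)) {
    aics <- vapply(ok, `[[`, numeric(1), "aic")
    chosen <- ok[[which.min(aics)]]
    chosen$model_name <- names(ok)[which.min(aics)]
    chosen$fallback <- FALSE
    return(chosen)
  }
  base <- candidates[grep("^intercept_only", names(candidates))]
  aics <- vapply(base, `[[`, numeric(1), "aic")
  chosen <- base[[which.min(aics)]]
  chosen$model_name <- names(base)[which.min(aics)]
  chosen$fallback <- TRUE
  chosen
}

#' Marginal and conditional coefficients of determination
#'
#' For a fitted mixed model, the marginal R-squared is the share of total
#' variance explained by the fixed effects,
#' `R2m = var_fixed / (var_fixed + var_random + var_resid)`, and the
#' conditional R-squared adds the species random effect,
#' `R2c = (var_fixed + var_random) / (same denominator)`.
#'
#' @param model A fitted candidate from [fit_latitude_models] /
#'   [select_model], or a list with `var_fixed`, `tau2`, `sigma2`.
#' @return List with `r2_marginal`, `r2_conditional`, and the three
#'   variance components.
#' @export
variance_partition <- function(model) {
  vf <- model$var_fixed
  vr <- model$tau2
  ve <- model$sigma2
  if (any(c(vf, vr, ve) < 0)) stop("negative variance component")
  tot <- vf + vr + ve
  if (tot <= 0) stop("zero total variance: R-squared undefined")
  list(r2_marginal = vf / tot, r2_conditional = (vf + vr) / tot,
       var_fixed = vf, var_random = vr, var_resid = ve)
}
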
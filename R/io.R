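## File I/O and the pipeline driver: TPC measurement CSVs, Newick trees,
## fit tables, analysis results, and an end-to-end seeded run with a
## machine-readable manifest.

#' Derive a reproducible per-stage seed
#'
#' All randomness in a pipeline run flows from one global seed, forked per
#' stage by a stable hash of the stage name, so partial re-runs of a stage
#' reproduce exactly.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character).
#' @return An integer seed in \[0, 2^31).
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Read a TPC measurement CSV
#'
#' Expected columns: `curve_id`, `species_id`, `trait_name`,
#' `temperature_C`, `trait_value`, and optionally `latitude`. Temperatures
#' are converted to Kelvin. Rows with non-finite or non-positive trait
#' values are skipped with a message; curves left with fewer than 2
#' distinct temperatures are dropped.
#'
#' @param path Path to the CSV file.
#' @return Named list of [tpc_curve] objects.
#' @export
read_tpc_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("curve_id", "species_id", "trait_name", "temperature_C",
            "trait_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (!nrow(df)) stop("empty input: ", path, " has a header but no rows")
  if (!"latitude" %in% names(df)) df$latitude <- NA_real_
  bad <- !is.finite(df$trait_value) | df$trait_value <= 0 |
    !is.finite(df$temperature_C)
  if (any(bad)) {
    message("skipping ", sum(bad), " malformed row(s) ",
            "(non-positive or non-finite values)")
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("no valid rows after filtering: ", path)
  curves <- list()
  for (id in unique(df$curve_id)) {
    sub <- df[df$curve_id == id, , drop = FALSE]
    cv <- tryCatch(
      tpc_curve(id, sub$species_id[1], sub$temperature_C,
                sub$trait_value, sub$trait_name[1],
                latitude = sub$latitude[1], unit = "C"),
      error = function(e) {
        message("dropping curve '", id, "': ", conditionMessage(e))
        NULL
      })
    if (!is.null(cv)) curves[[id]] <- cv
  }
  if (!length(curves)) stop("no usable curves in ", path)
  curves
}

#' Write TPC curves back to the measurement CSV schema
#'
#' @param curves List of [tpc_curve] objects, or a data.frame already in
#'   the schema.
#' @param path Output path.
#' @export
write_tpc_csv <- function(curves, path) {
  if (is.data.frame(curves)) {
    utils::write.csv(curves, path, row.names = FALSE)
    return(invisible(path))
  }
  rows <- lapply(curves, function(cv) {
    data.frame(curve_id = cv$curve_id, species_id = cv$species_id,
               trait_name = cv$trait_name,
               temperature_C = kelvin_to_celsius(cv$temperature),
               trait_value = cv$value, latitude = cv$latitude,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a Newick tree
#'
#' @param path Path to a single-tree Newick file with branch lengths.
#' @param normalize Rescale to unit root-to-tip height (and resolve
#'   polytomies) when `TRUE`.
#' @return An ape `phylo` tree.
#' @export
read_newick <- function(path, normalize = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree in ", path)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  .check_tree(tree)
  if (normalize) tree <- normalize_tree_height(tree)
  tree
}

#' One-row-per-curve summary table of TPC fits
#'
#' @param fits List of `"tpc_fit"` objects.
#' @param ses Optional named list (by curve id) of SE vectors from
#'   [estimate_uncertainty].
#' @return data.frame with ids, parameters on linear and log scales,
#'   derived quantities, R-squared, point counts, quality flags, and SEs.
#' @export
fits_to_table <- function(fits, ses = NULL) {
  rows <- lapply(fits, function(f) {
    base <- data.frame(curve_id = f$curve_id, species_id = f$species_id,
                       trait_name = f$trait_name, latitude = f$latitude,
                       n_points = f$n_points, converged = f$converged,
                       stringsAsFactors = FALSE)
    if (!f$converged) {
      num <- stats::setNames(rep(NA_real_, 12),
                             c("b0", "e", "t_pk", "e_d", "b_pk", "w_op",
                               "ln_b0", "ln_e", "ln_e_d", "ln_b_pk",
                               "ln_w_op", "r_squared"))
      cnt <- c(n_below_pk = NA_integer_, n_above_pk = NA_integer_)
    } else {
      p <- f$params
      d <- f$derived
      num <- c(b0 = p$b0, e = p$e, t_pk = p$t_pk, e_d = p$e_d,
               b_pk = if (is.null(d)) NA_real_ else d$b_pk,
               w_op = if (is.null(d)) NA_real_ else d$w_op,
               ln_b0 = log(p$b0), ln_e = log(p$e), ln_e_d = log(p$e_d),
               ln_b_pk = if (is.null(d)) NA_real_ else log(d$b_pk),
               ln_w_op = if (is.null(d)) NA_real_ else log(d$w_op),
               r_squared = f$r_squared)
      cnt <- c(n_below_pk = f$n_below_pk, n_above_pk = f$n_above_pk)
    }
    qc <- as.data.frame(t(f$qc))
    names(qc) <- paste0("ok_", names(qc))
    se_row <- stats::setNames(rep(NA_real_, 6),
                              paste0("se_", c("ln_b0", "ln_e", "t_pk",
                                              "ln_e_d", "ln_b_pk",
                                              "ln_w_op")))
    if (!is.null(ses) && f$curve_id %in% names(ses)) {
      se <- ses[[f$curve_id]]
      se_row[paste0("se_", names(se))] <- unname(se)
    }
    cbind(base, as.data.frame(t(num)), as.data.frame(t(cnt)), qc,
          as.data.frame(t(se_row)))
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Chains the stages: obtain inputs (simulate a synthetic scenario or read
#' files), fit every curve, apply quality filters, build per-species trait
#' tables, and run the requested comparative analyses. All outputs are
#' written under `out_dir` together with a machine-readable manifest; runs
#' with the same config and seed are byte-identical.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{seed}{Global integer seed (mandatory).}
#'     \item{out_dir}{Output directory (created if absent).}
#'     \item{tpc_csv, tree_file}{Input paths; omit both to simulate.}
#'     \item{simulate}{List: `n_tips`, `model`, plus optional overrides of
#'       [evolution_scenario], [measurement_design] and
#'       [assign_latitudes] arguments.}
#'     \item{analyses}{Character subset of `c("herit", "dtt", "trend",
#'       "latitude", "mantel")`; default all.}
#'     \item{variable}{Trait-table variable analysed; default `"ln_e"`.}
#'     \item{n_sim, n_perm, n_boot}{Simulation / permutation / bootstrap
#'       counts (defaults 1000, 9999, 0).}
#'     \item{t_ref_C}{Reference temperature in Celsius (default 0).}
#'   }
#' @return Invisibly, a list with the fits, trait table, analysis results
#'   and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must specify a seed")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir %||% stop("config must specify out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  analyses <- config$analyses %||%
    c("herit", "dtt", "trend", "latitude", "mantel")
  variable <- config$variable %||% "ln_e"
  n_sim <- config$n_sim %||% 1000
  n_perm <- config$n_perm %||% 9999
  n_boot <- config$n_boot %||% 0
  t_ref <- celsius_to_kelvin(config$t_ref_C %||% 0)
  results <- list()

  ## stage: inputs -----------------------------------------------------
  truth <- NULL
  if (!is.null(config$tpc_csv)) {
    curves <- read_tpc_csv(config$tpc_csv)
    tree <- if (!is.null(config$tree_file))
      read_newick(config$tree_file, normalize = TRUE) else NULL
  } else {
    sim <- config$simulate %||% list()
    n_tips <- sim$n_tips %||% 50
    tree <- simulate_tree(n_tips, sim$birth %||% 1, sim$death %||% 0,
                          seed = stage_seed(seed, "tree"))
    scen <- evolution_scenario(model = sim$model %||% "BM",
                               jump_intensity = sim$jump_intensity %||% 0.5,
                               jump_sd = sim$jump_sd %||% 1,
                               trend = sim$trend %||% -0.5)
    truth <- evolve_parameters(tree, scen,
                               seed = stage_seed(seed, "evolve"),
                               t_ref = t_ref)
    design <- measurement_design(
      temperatures_C = sim$temperatures_C %||% seq(2, 46, by = 4),
      noise_sd = sim$noise_sd %||% 0.05,
      seed = stage_seed(seed, "measure"))
    meas <- generate_measurements(truth$tips, design, t_ref = t_ref)
    lat <- assign_latitudes(
      stats::setNames(truth$tips$ln_e, truth$tips$species_id),
      slope = sim$lat_slope %||% -0.01,
      intercept = sim$lat_intercept %||% log(0.65),
      noise_sd = sim$lat_noise_sd %||% 0.1,
      seed = stage_seed(seed, "latitude"))
    meas$latitude <- lat[meas$species_id]
    write_tpc_csv(meas, file.path(out_dir, "synthetic_tpc.csv"))
    ape::write.tree(tree, file.path(out_dir, "synthetic_tree.nwk"))
    utils::write.csv(truth$tips, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    curves <- read_tpc_csv(file.path(out_dir, "synthetic_tpc.csv"))
  }

  ## stage: fit --------------------------------------------------------
  ctrl <- tpc_fit_control(n_boot = n_boot)
  fits <- lapply(curves, function(cv)
    suppressWarnings(fit_sharpe_schoolfield(cv, ctrl, t_ref = t_ref)))
  ses <- NULL
  if (n_boot > 0) {
    ses <- lapply(names(fits), function(id) {
      f <- fits[[id]]
      if (!f$converged) return(NULL)
      estimate_uncertainty(f, curves[[id]], n_boot = n_boot,
                           seed = stage_seed(seed, paste0("boot_", id)))
    })
    names(ses) <- names(fits)
    ses <- Filter(Negate(is.null), ses)
  }
  fit_table <- fits_to_table(fits, ses)
  utils::write.csv(fit_table, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  results$n_fits <- sum(fit_table$converged)
  results$n_accepted_e <- sum(fit_table$ok_e, na.rm = TRUE)

  ## stage: per-species trait table ------------------------------------
  best <- best_fit_per_species(fits)
  trait_rows <- lapply(best, function(f) {
    se <- if (!is.null(ses)) ses[[f$curve_id]] else NULL
    transform_parameters(f, se)
  })
  trait_table <- do.call(rbind, c(trait_rows,
                                  list(make.row.names = FALSE)))
  utils::write.csv(trait_table, file.path(out_dir, "trait_table.csv"),
                   row.names = FALSE)
  tvec <- local({
    sub <- trait_table[trait_table$variable == variable, , drop = FALSE]
    stats::setNames(sub$value, sub$species_id)
  })

  ## stage: comparative analyses ---------------------------------------
  if (!is.null(tree) && length(tvec) >= 3) {
    common <- intersect(tree$tip.label, names(tvec))
    tre <- normalize_tree_height(ape::keep.tip(tree, common))
    tv <- tvec[common]
    if ("herit" %in% analyses) {
      h <- pagels_lambda(tv, tre)
      results$heritability <- list(variable = variable,
                                   lambda = h$lambda, ci = unname(h$ci),
                                   n = h$n)
    }
    if ("dtt" %in% analyses) {
      d <- dtt_rank_envelope(tre, tv, n_sim = n_sim,
                             seed = stage_seed(seed, "dtt"))
      utils::write.csv(
        data.frame(time = d$time, observed = d$observed,
                   env_lo = d$env_lo, env_hi = d$env_hi),
        file.path(out_dir, "dtt_profile.csv"), row.names = FALSE)
      results$dtt <- list(p_lower = d$p_lower, p_upper = d$p_upper,
                          n_sim = d$n_sim)
    }
    if ("trend" %in% analyses && length(tv) >= 10) {
      tr <- trend_regression(tre, tv)
      results$trend <- list(theta = tr$theta, log_theta = tr$log_theta,
                            slope = tr$slope,
                            ci_slope = tr$ci_slope,
                            ci_log_theta = tr$ci_log_theta)
    }
    if ("mantel" %in% analyses) {
      lat_sp <- vapply(best, function(f) f$latitude, numeric(1))
      lat_sp <- lat_sp[!is.na(lat_sp)]
      common_m <- intersect(names(lat_sp), tre$tip.label)
      if (length(common_m) >= 5) {
        d_phy <- stats::cophenetic(ape::keep.tip(tre, common_m))
        d_lat <- as.matrix(stats::dist(lat_sp[rownames(d_phy)]))
        dimnames(d_lat) <- dimnames(d_phy)
        m <- mantel_test(d_phy, d_lat, n_perm = n_perm,
                         seed = stage_seed(seed, "mantel"))
        results$mantel <- list(r = m$r, p = m$p, n_perm = m$n_perm,
                               n_species = length(common_m))
      }
    }
  }
  if ("latitude" %in% analyses) {
    recs <- fit_table[fit_table$converged & fit_table$ok_e &
                        !is.na(fit_table$latitude), , drop = FALSE]
    if (nrow(recs) >= 10) {
      records <- data.frame(species_id = recs$species_id,
                            trait_name = recs$trait_name,
                            value = recs$ln_e,
                            latitude = recs$latitude)
      cand <- fit_latitude_models(records, tree = tree)
      chosen <- select_model(cand)
      vp <- variance_partition(chosen)
      utils::write.csv(
        data.frame(model = names(cand),
                   aic = vapply(cand, `[[`, numeric(1), "aic"),
                   selected = names(cand) == chosen$model_name),
        file.path(out_dir, "latitude_models.csv"), row.names = FALSE)
      results$latitude <- list(model = chosen$model_name,
                               fallback = chosen$fallback,
                               coefficients = as.list(chosen$beta),
                               r2_marginal = vp$r2_marginal,
                               r2_conditional = vp$r2_conditional)
    }
  }

  ## stage: manifest ----------------------------------------------------
  manifest <- list(
    package = "thermevol",
    version = as.character(utils::packageVersion("thermevol")),
    seed = seed,
    analyses = analyses,
    variable = variable,
    config = config[setdiff(names(config), "out_dir")])
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fits = fits, fit_table = fit_table,
                 trait_table = trait_table, results = results,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
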
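# End-to-end orchestration: Fourier -> segmentation -> clustering ->
# fire selectivity -> environmental association, from in-memory objects or
# from a YAML configuration pointing at on-disk artifacts. Every stage
# records the seeds and parameters actually used; a completed run is
# reproducible from the configuration alone.

#' Run the full phenological fuel-mapping pipeline
#'
#' @param stack an `ndvi_stack`.
#' @param fires an `ignition_set` in the same map frame.
#' @param covariates named list of categorical covariate rasters
#'   ([pheno_grid()]) on the same grid (may be empty).
#' @param params [seg_params()] for the segmentation stage.
#' @param k number of phenological fuel classes to cut.
#' @param split_largest split the largest class into two spatial
#'   subgroups ([split_largest_spatial()]).
#' @param standardize z-score unit features before clustering.
#' @param min_years_valid see [mean_seasonal_profile()].
#' @param n_reps randomizations for every test (default 9999).
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir optional directory; when given, all intermediate
#'   artifacts (ASCII grids, CSVs) and a JSON report are written there.
#' @return a `phenofuel_run` with components `fourier`, `labels`,
#'   `features`, `tree`, `assignment`, `pfc_map`, `pu_selectivity`,
#'   `pfc_selectivity`, `anova`, `pairwise`, `associations`, `config`.
#' @export
run_phenofuel <- function(stack, fires, covariates = list(),
                          params = seg_params(), k = 3,
                          split_largest = TRUE, standardize = FALSE,
                          min_years_valid = ceiling(dim(stack)[1] / 2),
                          n_reps = 9999, seed = 1L, out_dir = NULL) {
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
  }
  prof <- run_stage("fourier", mean_seasonal_profile(stack, min_years_valid))
  fi <- run_stage("fourier", tfa_image(prof))
  labels <- run_stage("segment", segment_image(fi, params))
  feats <- attr(labels, "units")
  tree <- run_stage("cluster", upgma_linkage(feats, standardize))
  assignment <- run_stage("cluster", cut_to_classes(tree, k, feats))
  if (split_largest) {
    cs0 <- attr(assignment, "classes")
    big <- as.character(cs0$pfc[which.max(cs0$area_km2)])
    if (sum(assignment$pfc == big) >= 2)
      assignment <- run_stage("cluster",
                              split_largest_spatial(assignment, feats,
                                                    seed = seed))
  }
  pfc_map <- pfc_raster(labels, assignment)

  pu_counts <- run_stage("selectivity",
                         count_fires_per_zone(labels, fires))
  pu_sel <- selection_ratios(pu_counts, feats$area_km2)
  pu_sel$pfc <- assignment$pfc[match(pu_sel$zone, assignment$unit_id)]
  cs <- attr(assignment, "classes")
  pfc_counts <- count_fires_per_zone(pfc_map, fires,
                                     levels = seq_along(levels(assignment$pfc)))
  names(pfc_counts) <- levels(assignment$pfc)
  pfc_test <- run_stage("selectivity",
                        monte_carlo_sigma_test(pfc_counts,
                                               cs$area_km2[
                                                 match(names(pfc_counts), cs$pfc)],
                                               n_reps, seed = seed + 1L))
  aov_res <- pair_res <- NULL
  if (nlevels(assignment$pfc) >= 2 &&
      length(pu_sel$sigma) - nlevels(assignment$pfc) >= 1) {
    aov_res <- run_stage("selectivity",
                         permutation_anova(pu_sel$sigma, pu_sel$pfc,
                                           n_reps, seed = seed + 2L))
    pair_res <- run_stage("selectivity",
                          pairwise_permutation_f(pu_sel$sigma, pu_sel$pfc,
                                                 n_reps, seed = seed + 3L))
  }
  assoc <- list()
  if (length(covariates)) {
    fire_pfc <- fire_labels(pfc_map, fires)
    for (nm in names(covariates)) {
      fire_cov <- fire_labels(covariates[[nm]], fires)
      keep <- !is.na(fire_pfc) & !is.na(fire_cov)
      assoc[[nm]] <- run_stage(
        "associate",
        margin_fixed_randomization(
          levels(assignment$pfc)[fire_pfc[keep]], fire_cov[keep],
          n_reps, seed = seed + 4L))
      attr(assoc[[nm]], "n_dropped") <- sum(!keep)
    }
  }
  out <- structure(list(fourier = fi, labels = labels, features = feats,
                        tree = tree, assignment = assignment,
                        pfc_map = pfc_map,
                        pu_selectivity = pu_sel, pfc_selectivity = pfc_test,
                        anova = aov_res, pairwise = pair_res,
                        associations = assoc,
                        config = list(params = unclass(params), k = k,
                                      split_largest = split_largest,
                                      standardize = standardize,
                                      min_years_valid = min_years_valid,
                                      n_reps = n_reps, seed = seed,
                                      n_fires = nrow(fires),
                                      n_fires_excluded =
                                        attr(pu_counts, "n_excluded"))),
                   class = "phenofuel_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

# covariate/class value under each fire point (NA outside / nodata)
fire_labels <- function(grid, fires) {
  rc <- cell_from_xy(grid, fires$x, fires$y)
  out <- rep(NA_integer_, nrow(rc))
  inside <- !is.na(rc$row)
  out[inside] <- unclass(grid)[cbind(rc$row[inside], rc$col[inside])]
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (b in c("A0", "A1", "A2"))
    write_ascii_grid(pheno_grid(fourier_band(run$fourier, b),
                                xll = attr(run$fourier, "grid")$xll,
                                yll = attr(run$fourier, "grid")$yll,
                                cellsize = attr(run$fourier, "grid")$cellsize),
                     file.path(out_dir, paste0("fourier_", b, ".asc")))
  write_ascii_grid(run$labels, file.path(out_dir, "units.asc"))
  write_ascii_grid(run$pfc_map, file.path(out_dir, "pfc.asc"))
  utils::write.csv(run$features, file.path(out_dir, "unit_features.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(unit_id = run$assignment$unit_id,
                              pfc = as.character(run$assignment$pfc)),
                   file.path(out_dir, "assignment.csv"), row.names = FALSE)
  utils::write.csv(run$pu_selectivity,
                   file.path(out_dir, "pu_selectivity.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$pfc_selectivity),
                   file.path(out_dir, "pfc_selectivity.csv"),
                   row.names = FALSE)
  report <- list(
    config = run$config,
    classes = attr(run$assignment, "classes"),
    pfc_selectivity = as.data.frame(run$pfc_selectivity),
    anova = if (!is.null(run$anova))
      run$anova[c("F_observed", "p_value", "n_perms", "seed")],
    associations = lapply(run$associations, function(a)
      list(chi2 = a$chi2_observed, p_overall = a$p_overall,
           n_reps = a$n_reps, seed = a$seed)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.phenofuel_run <- function(x, ...) {
  cat("Phenological fuel-mapping run\n")
  cat(sprintf("  %d unit(s) -> %d class(es); %d fire(s) (%d excluded)\n",
              nrow(x$features), nlevels(x$assignment$pfc),
              x$config$n_fires, x$config$n_fires_excluded))
  print(x$pfc_selectivity)
  if (!is.null(x$anova))
    cat(sprintf("  between-class permutational F = %.4g (p = %s)\n",
                x$anova$F_observed,
                format.pval(x$anova$p_value, digits = 3, eps = 1e-4)))
  for (nm in names(x$associations))
    cat(sprintf("  association with %s: chi2 = %.2f (p = %s)\n", nm,
                x$associations[[nm]]$chi2_observed,
                format.pval(x$associations[[nm]]$p_overall,
                            digits = 3, eps = 1e-4)))
  invisible(x)
}

#' @export
summary.phenofuel_run <- function(object, ...) {
  print(object)
  cat("\nPer-class summary:\n")
  print(attr(object$assignment, "classes"), row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
plot.phenofuel_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  m <- unclass(x$pfc_map)
  graphics::image(t(m[nrow(m):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(nlevels(x$assignment$pfc),
                                              "Zissou 1"),
                  axes = FALSE, main = "Phenological fuel classes")
  plot(stats::as.dendrogram(x$tree), main = "UPGMA dendrogram",
       leaflab = "none")
  invisible(x)
}

#' Run the pipeline from a YAML configuration
#'
#' The configuration lists input paths (`stack_dir` with
#' `ndvi_<year>_<composite>.asc` layers, `fires`, optional named
#' `covariates`), an `out_dir`, and any of the parameters of
#' [run_phenofuel()] (`scale`, `shape_weight`, `compactness_weight`,
#' `min_pixels`, `k`, `split_largest`, `standardize`, `n_reps`, `seed`,
#' ...).
#'
#' @param config path to a YAML file or an equivalent named list.
#' @return the `phenofuel_run` (artifacts are written to `out_dir`).
#' @export
run_phenofuel_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (p in c("stack_dir", "fires"))
    if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
      stop("config path `", p, "` is missing or does not exist")
  stack <- read_stack_dir(cfg$stack_dir)
  fires <- read_ignitions(cfg$fires)
  covs <- list()
  for (nm in names(cfg$covariates))
    covs[[nm]] <- read_ascii_grid(cfg$covariates[[nm]], integer = TRUE)
  sp <- seg_params(scale = cfg$scale %||% 500,
                   shape_weight = cfg$shape_weight %||% 0.2,
                   compactness_weight = cfg$compactness_weight %||% 0.8,
                   min_pixels = cfg$min_pixels %||% 25)
  run_phenofuel(stack, fires, covs, params = sp,
                k = cfg$k %||% 3,
                split_largest = cfg$split_largest %||% TRUE,
                standardize = cfg$standardize %||% FALSE,
                n_reps = cfg$n_reps %||% 9999,
                seed = as.integer(cfg$seed %||% 1L),
                out_dir = cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an NDVI stack from a directory of ASCII grids
#'
#' Layers follow the filename pattern `ndvi_<year>_<composite>.asc`; all
#' must share one grid.
#'
#' @param dir directory path.
#' @param first_day,time_lag composite calendar (defaults: Julian day 113,
#'   16-day lag).
#' @return an `ndvi_stack`.
#' @export
read_stack_dir <- function(dir, first_day = 113L, time_lag = 16L) {
  files <- list.files(dir, pattern = "^ndvi_\\d+_\\d+\\.asc$",
                      full.names = TRUE)
  if (!length(files)) stop("no ndvi_<year>_<composite>.asc layers in ", dir)
  info <- do.call(rbind, regmatches(basename(files),
                                    regexec("^ndvi_(\\d+)_(\\d+)\\.asc$",
                                            basename(files))))
  yr <- as.integer(info[, 2]); comp <- as.integer(info[, 3])
  years <- sort(unique(yr)); comps <- sort(unique(comp))
  g1 <- read_ascii_grid(files[1])
  vals <- array(NA_real_,
                dim = c(length(years), length(comps), length(g1)))
  for (i in seq_along(files)) {
    g <- read_ascii_grid(files[i])
    if (!same_grid(g, g1)) stop("layer ", files[i], " is on a different grid")
    vals[match(yr[i], years), match(comp[i], comps), ] <- as.vector(g)
  }
  structure(vals, grid = grid_template(g1), years = years,
            composite_days = first_day + time_lag * (comps - min(comps)),
            time_lag = time_lag, class = "ndvi_stack")
}

#' Write an NDVI stack as one ASCII grid per (year, composite)
#'
#' @param stack an `ndvi_stack`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_stack_dir <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- attr(stack, "grid")
  years <- attr(stack, "years")
  for (y in seq_along(years)) for (t in seq_len(dim(stack)[2])) {
    m <- matrix(stack[y, t, ], g$nrow, g$ncol)
    write_ascii_grid(pheno_grid(m, g$xll, g$yll, g$cellsize),
                     file.path(dir, sprintf("ndvi_%d_%d.asc", years[y], t)))
  }
  invisible(dir)
}
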
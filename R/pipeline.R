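#' Run configuration for the end-to-end pipeline
#'
#' A run is driven by one plain-text configuration (YAML or JSON file,
#' or an equivalent named list) with sections:
#'
#' * `out_dir`: output directory (created if needed).
#' * `seed`: integer seed for every stochastic stage (default 1, logged).
#' * `grid`: `target_n` *or* `spacing`, defining the hexagonal analysis
#'   grid over the region.
#' * `simulate`: arguments for [simulation_config()] (synthetic runs).
#' * `files`: input paths for real-data runs (`cohort`, `genotypes`,
#'   `gwas`, `region`, `env`); filled in automatically after
#'   [run_simulate()].
#' * `model`: `trait`, `covariates`, and optionally `pgs` column names.
#' * `thresholds`: p-value thresholds for score construction.
#' * `compare`: `M` (permutations, >= 99), `scheme` (`joint` or `one`),
#'   `env_transforms` (named, `identity`/`log`), `bonferroni_k`.
#' * `figures`: logical; render optional map figures (needs ggplot2).
#'
#' All defaults are written into the returned config so the manifest
#' records the run fully.
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @return Normalized `run_config` list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(
    out_dir = "pgsmap_run",
    seed = 1L,
    grid = list(target_n = 300),
    simulate = list(),
    files = list(),
    model = list(trait = "trait", covariates = c("sex", "age")),
    thresholds = c(5e-8, 1e-5, 0.5),
    compare = list(M = 10000, scheme = "joint", env_transforms = NULL,
                   bonferroni_k = NULL),
    figures = FALSE
  )
  cfg <- modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$compare$M < 99) {
    pgsmap_error("compare$M must be >= 99", "pgsmap_config_error")
  }
  structure(cfg, class = "run_config")
}

# Internal: append one entry per written file to the run manifest.
.manifest_add <- function(out_dir, files, cfg) {
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else {
    list(package = "pgsmap",
         version = as.character(utils::packageVersion("pgsmap")),
         seed = cfg$seed, config_hash = .config_hash(cfg), files = list())
  }
  for (f in files) {
    manifest$files[[basename(f)]] <- list(
      md5 = unname(tools::md5sum(f)), written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    )
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

# Internal: hash of the canonicalized config (seed included; the output
# directory is incidental to the run and excluded).
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  x <- unclass(cfg)
  x$region <- NULL
  x$out_dir <- NULL
  x$files <- NULL
  writeLines(jsonlite::toJSON(.jsonable(x), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.jsonable <- function(x) {
  if (is.function(x)) return(NULL)
  if (inherits(x, "study_region")) return(list(vertices = x$vertices))
  if (is.list(x)) return(lapply(x, .jsonable))
  x
}

# Internal: study region from a run config (region file, simulate
# section, or bbox of the cohort as a fallback).
.run_region <- function(cfg, cohort = NULL) {
  if (!is.null(cfg$files$region)) return(read_geojson_polygon(cfg$files$region))
  if (inherits(cfg$simulate$region, "study_region")) return(cfg$simulate$region)
  if (!is.null(cohort)) {
    pad <- 0.02 * max(diff(range(cohort$x)), diff(range(cohort$y)))
    return(region_rectangle(min(cohort$x) - pad, min(cohort$y) - pad,
                            max(cohort$x) + pad, max(cohort$y) + pad))
  }
  # the generator's default region
  simulation_config(seed = cfg$seed)$region
}

.run_grid <- function(cfg, cohort = NULL) {
  region <- .run_region(cfg, cohort)
  if (!is.null(cfg$grid$spacing)) {
    build_hex_grid(region, spacing = cfg$grid$spacing)
  } else {
    build_hex_grid(region, target_n = cfg$grid$target_n %||% 300)
  }
}

#' Generate and write a synthetic dataset
#'
#' Builds a [simulation_config()] from the `simulate` section (the run
#' seed and thresholds are injected), simulates the cohort and the
#' environmental surfaces on the analysis grid, and writes everything as
#' plain text under `out_dir`: `cohort.tsv`, `genotypes.tsv`,
#' `gwas.tsv`, `region.geojson`, `grid.geojson` + `grid_edges.tsv`,
#' `env_surfaces.tsv`, `truth_beta.geojson` (true coefficient surface at
#' the nodes), and a `manifest.json` carrying the seed, a config hash
#' and per-file checksums. The `files` section of the returned config is
#' pointed at the written files so [run_map()] can follow on directly.
#'
#' @param config A [read_run_config()] input.
#' @return The updated `run_config`, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- cfg$simulate
  sim_args$seed <- cfg$seed
  sim_args$thresholds <- threshold_set(cfg$thresholds)
  scfg <- do.call(simulation_config, sim_args)
  sim <- simulate_cohort(scfg)
  grid <- build_hex_grid(scfg$region,
                         spacing = cfg$grid$spacing,
                         target_n = if (is.null(cfg$grid$spacing)) {
                           cfg$grid$target_n %||% 300
                         })
  env <- simulate_env_surfaces(grid, sim$truth, scfg)

  paths <- list(
    cohort = file.path(cfg$out_dir, "cohort.tsv"),
    genotypes = file.path(cfg$out_dir, "genotypes.tsv"),
    gwas = file.path(cfg$out_dir, "gwas.tsv"),
    region = file.path(cfg$out_dir, "region.geojson"),
    grid = file.path(cfg$out_dir, "grid.geojson"),
    grid_edges = file.path(cfg$out_dir, "grid_edges.tsv"),
    env = file.path(cfg$out_dir, "env_surfaces.tsv"),
    truth = file.path(cfg$out_dir, "truth_beta.geojson")
  )
  write_cohort(sim$cohort, paths$cohort)
  write_dosages(sim$genotypes, paths$genotypes)
  write_gwas(sim$gwas, paths$gwas)
  write_geojson_polygon(scfg$region, paths$region)
  write_grid_geojson(grid, paths$grid)
  write_grid_edges(grid, paths$grid_edges)
  write.table(env, paths$env, sep = "\t", quote = FALSE, row.names = FALSE)
  tb <- data.frame(x = grid$nodes$x, y = grid$nodes$y, node = grid$nodes$node,
                   beta_true = sim$truth$beta_at(grid$nodes$x, grid$nodes$y))
  write_geojson_points(tb, paths$truth)
  .manifest_add(cfg$out_dir, unlist(paths), cfg)

  cfg$files <- modifyList(cfg$files, paths)
  message(sprintf("run_simulate: wrote %d files to %s (seed %d)",
                  length(paths), cfg$out_dir, cfg$seed))
  invisible(cfg)
}

#' Fit and write genetic-influence maps for every threshold
#'
#' Loads the cohort; if PGS columns are absent, builds them from the
#' genotype and GWAS files at the configured thresholds. Fits the
#' unweighted per-threshold models ([select_best_threshold()], written
#' as `threshold_fits.tsv`) and one spatially weighted map per
#' threshold, written as `map_<threshold>.tsv` and `.geojson`.
#'
#' @param config A [read_run_config()] input (typically the value
#'   returned by [run_simulate()]).
#' @return List with `maps` (named list of `local_fit_map`s), `best`
#'   (threshold selection), `grid`, and the updated config, invisibly.
#' @export
run_map <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$files$cohort)) {
    pgsmap_error("config$files$cohort is required for run_map", "pgsmap_config_error")
  }
  cohort <- read_cohort(cfg$files$cohort)
  thr <- threshold_set(cfg$thresholds)
  cols <- vapply(thr, pgs_column, character(1))
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    if (is.null(cfg$files$genotypes) || is.null(cfg$files$gwas)) {
      pgsmap_error(paste0("cohort lacks PGS columns (", paste(missing_cols, collapse = ", "),
                          ") and no genotypes/gwas files are configured"),
                   "pgsmap_config_error")
    }
    dos <- read_dosages(cfg$files$genotypes)
    gw <- read_gwas(cfg$files$gwas)
    pm <- build_pgs_matrix(dos, gw, thr)
    cohort <- cbind(cohort, pm[, setdiff(names(pm), names(cohort)), drop = FALSE])
  }
  grid <- .run_grid(cfg, cohort)
  kernel <- weight_kernel(power = cfg$kernel$power %||% 0.5,
                          min_distance = cfg$kernel$min_distance %||% 50)
  spec0 <- model_spec(cfg$model$trait, cols[1], cfg$model$covariates)
  best <- select_best_threshold(cohort, thr, spec0)
  write.table(best$table, file.path(cfg$out_dir, "threshold_fits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  maps <- list()
  written <- file.path(cfg$out_dir, "threshold_fits.tsv")
  for (cl in intersect(cols, names(cohort))) {
    spec <- model_spec(cfg$model$trait, cl, cfg$model$covariates)
    m <- map_associations(cohort, grid, kernel, spec)
    maps[[cl]] <- m
    stem <- file.path(cfg$out_dir, paste0("map_", sub("^pgs_", "", cl)))
    write_fit_map(m, paste0(stem, ".tsv"))
    write_fit_map(m, paste0(stem, ".geojson"))
    written <- c(written, paste0(stem, ".tsv"), paste0(stem, ".geojson"))
    message(sprintf("run_map: %s — n = %d analysed, %d/%d nodes converged",
                    cl, attr(m, "n_used"), sum(m$converged), nrow(m)))
  }
  .manifest_add(cfg$out_dir, written, cfg)
  invisible(list(maps = maps, best = best, grid = grid, config = cfg))
}

#' Compare maps across thresholds and against environmental surfaces
#'
#' Runs the Lee permutation test for every pair of threshold maps and
#' for every environmental surface against the best-threshold map, and
#' writes one row per comparison to `lee_results.tsv` (pair, transforms,
#' L, M, p, Bonferroni flag, scheme, seed). Positively skewed surfaces
#' can be log-transformed via `compare$env_transforms`. Optional
#' diverging-scale point maps and histograms are rendered when
#' `figures = TRUE` and ggplot2 is installed.
#'
#' @param config A [read_run_config()] input.
#' @param mapped Optional result of [run_map()] (avoids re-fitting);
#'   otherwise [run_map()] is called.
#' @return Data frame of comparison results, invisibly.
#' @export
run_compare <- function(config, mapped = NULL) {
  cfg <- read_run_config(config)
  if (is.null(mapped)) mapped <- run_map(cfg)
  maps <- mapped$maps
  grid <- mapped$grid
  W <- contiguity_weights(grid)
  M <- cfg$compare$M
  scheme <- cfg$compare$scheme %||% "joint"

  rows <- list()
  add_row <- function(res, pair) {
    rows[[length(rows) + 1]] <<- data.frame(
      map_a = pair[1], map_b = pair[2],
      transform_a = res$transforms[1], transform_b = res$transforms[2],
      L = res$L, M = res$M, p = res$p, scheme = res$scheme, seed = cfg$seed
    )
  }

  nm <- names(maps)
  if (length(nm) > 1) {
    for (i in seq_along(nm)[-length(nm)]) {
      for (j in seq((i + 1), length(nm))) {
        res <- compare_maps(maps[[i]], maps[[j]], W, M = M, seed = cfg$seed,
                            scheme = scheme)
        add_row(res, c(nm[i], nm[j]))
      }
    }
  }

  if (!is.null(cfg$files$env) && file.exists(cfg$files$env)) {
    env <- read.delim(cfg$files$env, check.names = FALSE)
    best_col <- mapped$best$best_column
    best_map <- maps[[best_col]] %||% maps[[1]]
    env_names <- setdiff(names(env), c("node", "x", "y"))
    for (en in env_names) {
      tr <- cfg$compare$env_transforms[[en]] %||% "identity"
      res <- compare_maps(best_map, env, W, M = M, seed = cfg$seed,
                          value_b = en, transform_b = tr, scheme = scheme)
      add_row(res, c(best_col, en))
    }
  }

  out <- do.call(rbind, rows)
  k <- cfg$compare$bonferroni_k %||% nrow(out)
  out$strong_evidence <- bonferroni_flag(out$p, k = k)
  res_path <- file.path(cfg$out_dir, "lee_results.tsv")
  write.table(out, res_path, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- res_path

  if (isTRUE(cfg$figures) && requireNamespace("ggplot2", quietly = TRUE)) {
    for (cl in names(maps)) {
      fp <- file.path(cfg$out_dir, paste0("map_", sub("^pgs_", "", cl), ".png"))
      grDevices::png(fp, width = 1400, height = 700)
      print(plot_fit_map(maps[[cl]], region = grid$region))
      grDevices::dev.off()
      written <- c(written, fp)
    }
  }
  .manifest_add(cfg$out_dir, written, cfg)
  message(sprintf("run_compare: %d comparisons written to %s", nrow(out), res_path))
  invisible(out)
}

#' Run the whole pipeline: simulate, map, compare
#'
#' @param config A [read_run_config()] input with a `simulate` section.
#' @return List with the simulation config, map results and comparison
#'   table, invisibly.
#' @export
run_all <- function(config) {
  cfg <- run_simulate(config)
  mapped <- run_map(cfg)
  comparisons <- run_compare(cfg, mapped)
  invisible(list(config = cfg, mapped = mapped, comparisons = comparisons))
}
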
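#' Run the full comparative analysis pipeline
#'
#' Executes the four analysis stages in order on a species trait table and
#' a phylogeny: life-stage comparison ([run_lifestage_stage()]),
#' metamorphosis deltas ([run_metamorphosis_stage()]), adult ecology
#' ([run_ecology_stage()]) and relative lens size
#' ([run_relative_size_stage()]). Inputs are validated up front
#' (fail-fast); per-specimen tables are collapsed with [species_means()].
#' If `out_dir` is given, writes a JSON summary, coefficient CSVs and a
#' run manifest (config hash, seeds, package version, per-stage sample
#' sizes). With the same inputs, config and seed, the written JSON is
#' byte-identical across runs.
#'
#' Without a tree, the phylogenetic stages are skipped and the life-stage
#' stage runs its non-phylogenetic parts with a prominent warning.
#'
#' @param traits a trait data.frame or path to a trait CSV.
#' @param tree an [ape::phylo], a path to a Newick/NEXUS file, or `NULL`.
#' @param config a [lens_config()] or path to a YAML config.
#' @param out_dir optional output directory.
#' @return A list of class `lens_run`: `reports` (named stage reports),
#'   `manifest`.
#' @export
run_all <- function(traits, tree = NULL, config = lens_config(),
                    out_dir = NULL) {
  if (is.character(traits)) traits <- read_trait_table(traits)
  if (anyDuplicated(traits[c("species", "life_stage")])) {
    traits <- species_means(traits)
  }
  traits <- validate_trait_table(traits)
  if (is.character(tree)) tree <- read_phylogeny(tree)
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "lens_config"))

  reports <- list()
  reports$lifestage <- run_lifestage_stage(traits, tree, config)
  if (!is.null(tree)) {
    reports$metamorphosis <- run_metamorphosis_stage(traits, tree, config)
    reports$ecology <- run_ecology_stage(traits, tree, config)
    reports$relative_size <- run_relative_size_stage(traits, tree, config)
  } else {
    warning("no tree: metamorphosis, ecology and relative-size stages ",
            "were NOT run", call. = FALSE)
  }

  manifest <- list(
    package = "lensmorph",
    version = as.character(utils::packageVersion("lensmorph")),
    config = unclass(config),
    config_hash = .config_hash(config),
    seed = config$seed,
    n = lapply(reports, `[[`, "n"),
    species = sort(unique(traits$species))
  )
  run <- structure(list(reports = reports, manifest = manifest),
                   class = "lens_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.lens_run <- function(x, ...) {
  cat("<lens_run> stages:", paste(names(x$reports), collapse = ", "), "\n")
  for (r in x$reports) print(r)
  invisible(x)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# stage report -> JSON-friendly list (reproducible: fixed statistic set)
.report_summary <- function(report) {
  st <- report$statistics
  out <- list(stage = report$stage, n = report$n,
              seeds = as.list(report$seeds))
  if (!is.null(st$pca)) {
    out$pca <- list(proportion = round(st$pca$proportion, 10),
                    loadings = round(st$pca$loadings, 10))
  }
  if (!is.null(st$t_tests)) out$t_tests <- st$t_tests
  for (nm in c("kmult_adult", "kmult_tadpole", "kmult_delta")) {
    if (!is.null(st[[nm]])) {
      out[[nm]] <- st[[nm]][c("K", "p.value", "n", "n_perm", "seed")]
    }
  }
  if (!is.null(st$pgls)) out$pgls <- st$pgls
  if (!is.null(st$slopes)) out$slopes <- st$slopes
  if (!is.null(st$factor_tests)) out$factor_tests <- st$factor_tests
  if (!is.null(st$posthoc)) {
    out$posthoc <- lapply(st$posthoc, function(ph) {
      list(letters = as.list(ph$letters), method = ph$method,
           alpha = ph$alpha)
    })
  }
  if (length(report$notes)) out$notes <- report$notes
  out
}

#' Write pipeline outputs to a directory
#'
#' Emits `summary.json` (statistics, sample sizes, seeds, manifest),
#' per-stage coefficient CSVs, and `residuals_relative_size.csv`.
#'
#' @param run a [run_all()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "lens_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(manifest = run$manifest,
                  stages = lapply(run$reports, .report_summary))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 12, force = TRUE,
                       pretty = TRUE)
  for (nm in names(run$reports)) {
    st <- run$reports[[nm]]$statistics
    if (!is.null(st$pgls)) {
      write.csv(st$pgls, file.path(out_dir, paste0("pgls_", nm, ".csv")),
                row.names = FALSE)
    }
    fits <- st$fits
    if (length(fits)) {
      coefs <- do.call(rbind, lapply(names(fits), function(f) {
        ct <- fits[[f]]$coefficients
        cbind(data.frame(model = f, term = rownames(ct)), ct)
      }))
      rownames(coefs) <- NULL
      write.csv(coefs, file.path(out_dir, paste0("coefficients_", nm, ".csv")),
                row.names = FALSE)
    }
    if (!is.null(st$residuals)) {
      write.csv(data.frame(species = names(st$residuals),
                           residual = as.numeric(st$residuals)),
                file.path(out_dir, "residuals_relative_size.csv"),
                row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' Recompute the headline benchmark statistics from deposited data
#'
#' Given the deposited species measurement table and the published
#' amphibian phylogeny (both downloaded separately; neither ships with the
#' package), runs the pipeline and extracts the headline statistics of the
#' original study for comparison: the adult-vs-tadpole Welch t per metric,
#' adult and tadpole K_mult, the pooled-PCA variance proportions, and the
#' per-environment anisotropy delta estimates.
#'
#' @param traits_csv path to the species trait CSV (documented header
#'   contract; see [validate_trait_table()]).
#' @param tree_file path to the phylogeny (Newick or NEXUS).
#' @param config a [lens_config()].
#' @return A list: `t_anisotropy`, `kmult_adult`, `kmult_tadpole`,
#'   `pc1_percent`, `beta_terrestrial_anisotropy`, `beta_aquatic_anisotropy`,
#'   plus the full `lens_run`.
#' @export
reproduce_benchmarks <- function(traits_csv, tree_file,
                                 config = lens_config()) {
  if (!file.exists(traits_csv)) {
    stop("benchmark trait table not found: ", traits_csv,
         " (download the deposited species measurements to run this)")
  }
  if (!file.exists(tree_file)) {
    stop("benchmark phylogeny not found: ", tree_file)
  }
  run <- run_all(traits_csv, tree_file, config)
  ls <- run$reports$lifestage$statistics
  mm <- run$reports$metamorphosis$statistics
  sl <- mm$slopes
  b_terr <- sl[sl$metric == "anisotropy" & sl$environment == "terrestrial",
               "estimate"]
  b_aq <- sl[sl$metric == "anisotropy" & sl$environment == "aquatic",
             "estimate"]
  list(t_anisotropy = ls$t_tests$t[ls$t_tests$metric == "anisotropy"],
       kmult_adult = ls$kmult_adult$K,
       kmult_tadpole = ls$kmult_tadpole$K,
       pc1_percent = 100 * ls$pca$proportion[1],
       beta_terrestrial_anisotropy = b_terr,
       beta_aquatic_anisotropy = b_aq,
       run = run)
}
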
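SHAPE_METRICS_3 <- c("anisotropy", "sphericity", "elongation")

#' Analysis configuration
#'
#' Collects the tunable switches of the analysis pipeline with their
#' defaults: the RNG seed, permutation count for K_mult, the lambda mode of
#' PGLS fits (`"ML"` to estimate, or a fixed number), the likelihood flavor
#' (`REML = FALSE`, plain ML, for fidelity to the reference analyses), PCA
#' scaling (correlation matrix by default, since the three shape metrics
#' differ strongly in variance), the post-hoc adjustment and alpha, the
#' collinearity threshold, mesh smoothing iterations for the imaging
#' module, and whether diameters are modelled on the log10 scale.
#'
#' @param seed integer seed used to derive all stage seeds.
#' @param n_perm K_mult permutations.
#' @param lambda `"ML"` or fixed value in \[0, 1\].
#' @param REML use REML for the lambda profile.
#' @param pca_scale analyse the correlation (TRUE) or covariance matrix.
#' @param posthoc p-adjustment for pairwise comparisons.
#' @param alpha significance level for letter groupings.
#' @param collinearity_threshold |r| above which a metric is dropped.
#' @param smoothing mesh smoothing iterations.
#' @param size_log model diameters on the log10 scale.
#' @return A list of class `lens_config`.
#' @export
lens_config <- function(seed = 1L, n_perm = 999L, lambda = "ML",
                        REML = FALSE, pca_scale = TRUE, posthoc = "holm",
                        alpha = 0.05, collinearity_threshold = 0.9,
                        smoothing = 20L, size_log = FALSE) {
  structure(list(seed = as.integer(seed), n_perm = as.integer(n_perm),
                 lambda = lambda, REML = isTRUE(REML),
                 pca_scale = isTRUE(pca_scale), posthoc = posthoc,
                 alpha = alpha,
                 collinearity_threshold = collinearity_threshold,
                 smoothing = as.integer(smoothing),
                 size_log = isTRUE(size_log)),
            class = "lens_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; keys as in [lens_config()]; absent keys default.
#' @return A `lens_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(lens_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(lens_config, vals[intersect(names(vals), known)])
}

# deterministic per-stage sub-seeds, kept well below .Machine$integer.max
.stage_seed <- function(config, offset) {
  (config$seed %% 1000000L) * 1000L + offset
}

.new_report <- function(stage, statistics, n, seeds, config, notes = NULL) {
  structure(list(stage = stage, statistics = statistics, n = n,
                 seeds = seeds, config = unclass(config), notes = notes),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("<stage_report> %s\n", x$stage))
  cat("  n:", paste(names(x$n), unlist(x$n), sep = "=", collapse = ", "), "\n")
  for (nm in names(x$statistics)) cat("  -", nm, "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

.require_tree <- function(tree, stage) {
  if (is.null(tree)) {
    warning("no tree supplied: ", stage,
            " runs WITHOUT its phylogenetic components", call. = FALSE)
    FALSE
  } else {
    TRUE
  }
}

.complete_metric_rows <- function(table, stage) {
  sub <- table[table$life_stage == stage, , drop = FALSE]
  sub[stats::complete.cases(sub[SHAPE_METRICS_3]), , drop = FALSE]
}

.pgls_stat_row <- function(fit, label) {
  data.frame(model = label, F = fit$F, df1 = fit$df[1], df2 = fit$df[2],
             lambda = fit$lambda, r2_adj = fit$r.squared.adj,
             p = fit$p.value, n = fit$n)
}

#' Life-stage comparison of lens shape
#'
#' Runs the first analysis stage on a species trait table: (i) a pooled
#' PCA of adult and tadpole species means of anisotropy, sphericity and
#' elongation; (ii) a Welch t-test per metric comparing adults with
#' tadpoles; (iii) multivariate phylogenetic signal (K_mult) of the
#' 3-metric matrix, separately within adults and within tadpoles.
#'
#' @param table species trait table ([validate_trait_table()]).
#' @param tree an [ape::phylo], or `NULL` to run only the non-phylogenetic
#'   parts (with a prominent warning).
#' @param config a [lens_config()].
#' @return A `stage_report` with `pca`, `t_tests`, `kmult_adult`,
#'   `kmult_tadpole`.
#' @export
run_lifestage_stage <- function(table, tree = NULL, config = lens_config()) {
  table <- validate_trait_table(table)
  adults <- .complete_metric_rows(table, "adult")
  tads <- .complete_metric_rows(table, "tadpole")
  if (nrow(adults) < 2L || nrow(tads) < 2L) {
    stop("need >= 2 species per life stage")
  }
  pooled <- rbind(adults, tads)
  pm <- as.matrix(pooled[SHAPE_METRICS_3])
  rownames(pm) <- paste(pooled$species, pooled$life_stage, sep = ":")
  pca_res <- pca(pm, scale = config$pca_scale)

  tt <- do.call(rbind, lapply(SHAPE_METRICS_3, function(m) {
    w <- welch_t(adults[[m]], tads[[m]])
    data.frame(metric = m, t = w$t, df = w$df, p = w$p.value,
               mean_adult = mean(adults[[m]]), mean_tadpole = mean(tads[[m]]))
  }))

  km_a <- km_t <- NULL
  if (.require_tree(tree, "life-stage stage")) {
    ma <- as.matrix(adults[SHAPE_METRICS_3]); rownames(ma) <- adults$species
    mt <- as.matrix(tads[SHAPE_METRICS_3]); rownames(mt) <- tads$species
    km_a <- kmult(ma, tree, n_perm = config$n_perm,
                  seed = .stage_seed(config, 1L))
    km_t <- kmult(mt, tree, n_perm = config$n_perm,
                  seed = .stage_seed(config, 2L))
  }
  .new_report("lifestage",
              list(pca = pca_res, t_tests = tt,
                   kmult_adult = km_a, kmult_tadpole = km_t),
              n = list(adult = nrow(adults), tadpole = nrow(tads)),
              seeds = c(kmult_adult = .stage_seed(config, 1L),
                        kmult_tadpole = .stage_seed(config, 2L)),
              config = config)
}

#' Ontogenetic change in lens shape across metamorphosis
#'
#' For species with both life stages, computes per-species deltas
#' (adult - tadpole) of each shape metric, estimates their multivariate
#' phylogenetic signal (K_mult), and fits a univariate PGLS of each delta
#' on the post-metamorphic environment (aquatic vs terrestrial), with
#' per-environment mean shifts obtained by releveling the factor and
#' refitting under the same fitted covariance.
#'
#' @inheritParams run_lifestage_stage
#' @return A `stage_report` with `deltas`, `kmult_delta`, `pgls` (one row
#'   per metric), `slopes` (per-environment estimates), `fits`.
#' @export
run_metamorphosis_stage <- function(table, tree = NULL,
                                    config = lens_config()) {
  table <- validate_trait_table(table)
  adults <- .complete_metric_rows(table, "adult")
  tads <- .complete_metric_rows(table, "tadpole")
  paired <- intersect(adults$species, tads$species)
  excluded <- setdiff(union(adults$species, tads$species), paired)
  if (length(paired) < 3L) stop("need >= 3 species with both stages")
  a <- adults[match(paired, adults$species), ]
  t_ <- tads[match(paired, tads$species), ]
  deltas <- as.data.frame(
    as.matrix(a[SHAPE_METRICS_3]) - as.matrix(t_[SHAPE_METRICS_3]))
  names(deltas) <- paste0("delta_", SHAPE_METRICS_3)
  env <- a$adult_environment
  if (anyNA(env)) {
    stop("adult_environment missing for paired species: ",
         paste(paired[is.na(env)], collapse = ", "))
  }
  deltas <- cbind(data.frame(species = paired,
                             adult_environment = droplevels(env)), deltas)

  km <- NULL; pgls_tab <- NULL; slopes <- NULL; fits <- list()
  notes <- character()
  if (.require_tree(tree, "metamorphosis stage")) {
    dm <- as.matrix(deltas[paste0("delta_", SHAPE_METRICS_3)])
    rownames(dm) <- paired
    km <- tryCatch(kmult(dm, tree, n_perm = config$n_perm,
                         seed = .stage_seed(config, 3L)),
                   error = function(e) {
                     notes <<- c(notes, paste("K_mult not computed:",
                                              conditionMessage(e)))
                     NULL
                   })
    one_level <- nlevels(deltas$adult_environment) < 2L
    if (one_level) {
      notes <- c(notes, paste(
        "single post-metamorphic environment among paired species;",
        "environment effect not testable, reporting per-level means only"))
    }
    rows <- list(); srows <- list()
    for (m in SHAPE_METRICS_3) {
      fml <- if (one_level) {
        stats::as.formula(paste0("delta_", m, " ~ 1"))
      } else {
        stats::as.formula(paste0("delta_", m, " ~ adult_environment"))
      }
      fit <- fit_pgls(fml, deltas, tree, lambda = config$lambda,
                      REML = config$REML)
      fits[[m]] <- fit
      rows[[m]] <- .pgls_stat_row(fit, m)
      for (lev in levels(deltas$adult_environment)) {
        rf <- if (one_level) fit else pgls_relevel(fit, "adult_environment", lev)
        srows[[paste(m, lev)]] <- data.frame(
          metric = m, environment = lev,
          estimate = rf$coefficients["(Intercept)", "estimate"],
          std.error = rf$coefficients["(Intercept)", "std.error"])
      }
    }
    pgls_tab <- do.call(rbind, rows)
    slopes <- do.call(rbind, srows)
    rownames(pgls_tab) <- rownames(slopes) <- NULL
  }
  .new_report("metamorphosis",
              list(deltas = deltas, kmult_delta = km, pgls = pgls_tab,
                   slopes = slopes, fits = fits),
              n = list(paired = length(paired), excluded = length(excluded)),
              seeds = c(kmult_delta = .stage_seed(config, 3L)),
              config = config,
              notes = c(notes, if (length(excluded)) {
                paste("species with one stage only, excluded:",
                      paste(sort(excluded), collapse = ", "))
              }))
}

#' Adult lens shape across habits and activity patterns
#'
#' Fits a univariate PGLS of each adult shape metric on habit (six-level
#' factor) and on activity pattern (two-level), with pairwise post-hoc
#' comparisons among habit levels (multiplicity-corrected) summarized as
#' compact letter groupings. Habit levels represented by fewer than two
#' species are dropped with a warning; species lacking a score for a trait
#' are excluded from that trait's models only.
#'
#' @inheritParams run_lifestage_stage
#' @return A `stage_report` with `pgls` (per metric x trait), `posthoc`
#'   (per metric letter displays for habit), `fits`.
#' @export
run_ecology_stage <- function(table, tree = NULL, config = lens_config()) {
  table <- validate_trait_table(table)
  adults <- .complete_metric_rows(table, "adult")
  if (!.require_tree(tree, "ecology stage")) {
    stop("the ecology stage is entirely phylogenetic; a tree is required")
  }
  rows <- list(); posthoc <- list(); fits <- list()
  ns <- list()
  for (trait in c("habit", "activity")) {
    sub <- adults[!is.na(adults[[trait]]), , drop = FALSE]
    f <- droplevels(factor(sub[[trait]]))
    small <- names(which(table(f) < 2L))
    if (length(small)) {
      warning("dropping ", trait, " level(s) with < 2 species: ",
              paste(small, collapse = ", "))
      sub <- sub[!sub[[trait]] %in% small, , drop = FALSE]
    }
    sub[[trait]] <- droplevels(factor(sub[[trait]]))
    ns[[trait]] <- nrow(sub)
    for (m in SHAPE_METRICS_3) {
      fml <- stats::as.formula(paste(m, "~", trait))
      fit <- fit_pgls(fml, sub, tree, lambda = config$lambda,
                      REML = config$REML)
      fits[[paste(m, trait, sep = "_")]] <- fit
      rows[[paste(m, trait)]] <- cbind(
        data.frame(metric = m, trait = trait), .pgls_stat_row(fit, m)[-1])
      if (trait == "habit") {
        posthoc[[m]] <- pgls_pairwise(fit, "habit", method = config$posthoc,
                                      alpha = config$alpha)
      }
    }
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  .new_report("ecology", list(pgls = tab, posthoc = posthoc, fits = fits),
              n = ns, seeds = integer(), config = config)
}

#' Relative lens size across adult ecologies
#'
#' Fits PGLS models of lens diameter on eye diameter plus habit, and on
#' eye diameter plus activity pattern, among adults with both diameters.
#' Reports the overall model F and the covariate-adjusted F of the
#' ecological factor, and exports residuals of the diameter-only PGLS
#' (lens ~ eye) for display of relative lens size.
#'
#' @inheritParams run_lifestage_stage
#' @return A `stage_report` with `pgls` (overall model rows), `factor_tests`
#'   (factor-term F tests), `residuals` (diameter-only PGLS residuals),
#'   `fits`.
#' @export
run_relative_size_stage <- function(table, tree = NULL,
                                    config = lens_config()) {
  table <- validate_trait_table(table)
  adults <- table[table$life_stage == "adult", , drop = FALSE]
  adults <- adults[stats::complete.cases(
    adults[c("lens_diameter_mm", "eye_diameter_mm")]), , drop = FALSE]
  if (!.require_tree(tree, "relative-size stage")) {
    stop("the relative-size stage is entirely phylogenetic; a tree is required")
  }
  if (config$size_log) {
    adults$lens_size <- log10(adults$lens_diameter_mm)
    adults$eye_size <- log10(adults$eye_diameter_mm)
  } else {
    adults$lens_size <- adults$lens_diameter_mm
    adults$eye_size <- adults$eye_diameter_mm
  }
  rows <- list(); ftests <- list(); fits <- list(); ns <- list()
  for (trait in c("habit", "activity")) {
    sub <- adults[!is.na(adults[[trait]]), , drop = FALSE]
    sub[[trait]] <- droplevels(factor(sub[[trait]]))
    small <- names(which(table(sub[[trait]]) < 2L))
    if (length(small)) {
      warning("dropping ", trait, " level(s) with < 2 species: ",
              paste(small, collapse = ", "))
      sub <- sub[!sub[[trait]] %in% small, , drop = FALSE]
      sub[[trait]] <- droplevels(sub[[trait]])
    }
    ns[[trait]] <- nrow(sub)
    fml <- stats::as.formula(paste("lens_size ~ eye_size +", trait))
    fit <- fit_pgls(fml, sub, tree, lambda = config$lambda,
                    REML = config$REML)
    fits[[trait]] <- fit
    rows[[trait]] <- .pgls_stat_row(fit, paste0("lens~eye+", trait))
    tt <- pgls_term_test(fit, trait)
    ftests[[trait]] <- data.frame(trait = trait, F = tt$F, df1 = tt$df[1],
                                  df2 = tt$df[2], p = tt$p.value)
  }
  size_fit <- fit_pgls(lens_size ~ eye_size, adults, tree,
                       lambda = config$lambda, REML = config$REML)
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  ft <- do.call(rbind, ftests); rownames(ft) <- NULL
  .new_report("relative_size",
              list(pgls = tab, factor_tests = ft,
                   residuals = residuals(size_fit),
                   size_fit = size_fit, fits = fits),
              n = c(ns, list(diameters = nrow(adults))),
              seeds = integer(), config = config)
}
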
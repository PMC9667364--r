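#' Specification of a synthetic comparative study
#'
#' Parameterizes the generator for a full synthetic trait table: sample
#' sizes, ecological category frequencies, baseline tadpole lens-shape
#' means, ontogenetic effect sizes by post-metamorphic environment, habit
#' offsets on adult shape, the lens/eye allometry, and the phylogenetic
#' signal of trait deviations. Defaults mirror the study conditions of the
#' anuran lens dataset: 126 species (121 with adult data, 50 with tadpole
#' data, 45 paired), a terrestrial anisotropy delta of +0.15 versus +0.01
#' for species remaining aquatic, and weak phylogenetic signal in the
#' residuals (lambda 0.4 tadpoles / 0.45 adults).
#'
#' @param n_species number of species (tree tips used).
#' @param paired_fraction fraction of species with both tadpole and adult
#'   data (default 0.36, about 45 of 126).
#' @param n_tadpole_only species with tadpole data only (default 5).
#' @param habit_freq named frequencies over the six habit levels (sum 1).
#' @param activity_freq named frequencies over nocturnal / non-nocturnal.
#' @param habit_missing,activity_missing,diameter_missing fraction of adult
#'   records lacking each ecological score / the diameter pair.
#' @param baseline named means of tadpole anisotropy, sphericity, elongation.
#' @param sigma named sd of the species-level i.i.d. effect per metric,
#'   shared by both life stages of a species (sets the cross-sectional
#'   spread together with `phylo_sigma`).
#' @param stage_sigma named sd of the stage-specific measurement noise per
#'   metric; only this (plus `delta_phylo_sigma`) enters within-species
#'   ontogenetic deltas, whose spread is about
#'   `sqrt(2 * stage_sigma^2 + delta_phylo_sigma^2)`.
#' @param phylo_sigma named sd of the phylogenetic (lambda-BM) deviation at
#'   tree height 1, per metric; shared across stages (lens shape heritage
#'   persists through metamorphosis).
#' @param delta_phylo_sigma named sd of an additional lambda-BM field on
#'   the adult stage, giving ontogenetic change itself phylogenetic signal.
#' @param lambda_tadpole,lambda_adult Pagel's lambda of the shared and the
#'   adult-delta phylogenetic fields respectively.
#' @param delta_terrestrial,delta_aquatic named ontogenetic shifts
#'   (adult - tadpole) per metric for terrestrial- and aquatic-adult species.
#' @param habit_anisotropy,habit_sphericity named additive habit offsets on
#'   adult metrics (levels absent from the vector get 0).
#' @param allometry list: `intercept`, `slope`, `sigma` of
#'   `log10(lens) = intercept + slope * log10(eye) + offset + noise`, plus
#'   `eye_log_mean`, `eye_log_sd`, and `habit_offset` (named, log10 units).
#' @param seed integer RNG seed.
#' @return A list of class `study_spec`.
#' @export
study_spec <- function(
    n_species = 126L,
    paired_fraction = 0.36,
    n_tadpole_only = 5L,
    habit_freq = c("aquatic" = 0.10, "semiaquatic" = 0.13,
                   "scansorial" = 0.28, "ground-dwelling" = 0.29,
                   "subfossorial" = 0.10, "fossorial" = 0.10),
    activity_freq = c("nocturnal" = 0.7, "non-nocturnal" = 0.3),
    habit_missing = 0.017,
    activity_missing = 0.116,
    diameter_missing = 0.34,
    baseline = c(anisotropy = 0.10, sphericity = 0.95, elongation = 0.93),
    sigma = c(anisotropy = 0.05, sphericity = 0.02, elongation = 0.03),
    stage_sigma = c(anisotropy = 0.02, sphericity = 0.007,
                    elongation = 0.01),
    phylo_sigma = c(anisotropy = 0.035, sphericity = 0.015,
                    elongation = 0.02),
    delta_phylo_sigma = c(anisotropy = 0.015, sphericity = 0.006,
                          elongation = 0.008),
    lambda_tadpole = 0.4,
    lambda_adult = 0.45,
    delta_terrestrial = c(anisotropy = 0.15, sphericity = -0.03,
                          elongation = 0),
    delta_aquatic = c(anisotropy = 0.01, sphericity = -0.01, elongation = 0),
    habit_anisotropy = c("aquatic" = -0.05, "fossorial" = -0.05),
    habit_sphericity = c("aquatic" = 0.05, "fossorial" = 0.05),
    allometry = list(intercept = log10(0.45) + 0.1 * log10(4), slope = 0.9,
                     sigma = 0.03, eye_log_mean = log10(4), eye_log_sd = 0.2,
                     habit_offset = c("aquatic" = -0.022,
                                      "semiaquatic" = -0.022)),
    seed = 1L) {
  if (abs(sum(habit_freq) - 1) > 1e-8) stop("habit frequencies must sum to 1")
  if (abs(sum(activity_freq) - 1) > 1e-8) {
    stop("activity frequencies must sum to 1")
  }
  if (!setequal(names(habit_freq), HABIT_LEVELS)) {
    stop("habit_freq must name all six habit levels")
  }
  if (any(sigma <= 0) || any(stage_sigma <= 0) || any(phylo_sigma < 0) ||
      any(delta_phylo_sigma < 0)) {
    stop("sigma must be > 0")
  }
  n_paired <- round(paired_fraction * n_species)
  if (n_paired + n_tadpole_only > n_species) {
    stop("infeasible paired/tadpole-only counts for n_species")
  }
  structure(as.list(environment()), class = "study_spec")
}

#' Generate a synthetic species trait table with known ground truth
#'
#' Simulates a full comparative dataset on a given tree: habits and
#' activity patterns drawn from the specified frequencies; the post-
#' metamorphic environment set to aquatic for aquatic-habit species and
#' terrestrial otherwise. Each metric is built from a species-level latent
#' value (baseline + shared lambda-BM phylogenetic deviation + shared
#' species effect) that persists through metamorphosis; the two life
#' stages add independent stage-specific measurement noise, and adults
#' additionally receive the environment delta, habit offsets, and a small
#' lambda-BM delta field (so ontogenetic change carries phylogenetic
#' signal). Lens/eye diameters follow the log-log allometry with habit
#' offsets. Metrics are clipped to \[0, 1\] with a warning. All ground
#' truth parameters are returned so pipeline estimates can be scored.
#'
#' @param spec a [study_spec()].
#' @param tree an [ape::phylo] with at least `n_species` tips (default: a
#'   fresh [make_tree()] under the spec's seed).
#' @return A list of class `study_bundle`: `table` (species trait table),
#'   `tree` (the pruned tree used), `truth` (spec plus per-species latent
#'   values).
#' @export
make_study <- function(spec = study_spec(), tree = NULL) {
  stopifnot(inherits(spec, "study_spec"))
  if (is.null(tree)) tree <- make_tree(spec$n_species, seed = spec$seed)
  if (length(tree$tip.label) < spec$n_species) {
    stop("tree has fewer tips than n_species")
  }
  if (length(tree$tip.label) > spec$n_species) {
    tree <- ape::keep.tip(tree, tree$tip.label[seq_len(spec$n_species)])
  }
  n <- spec$n_species
  sp <- tree$tip.label
  metrics <- names(spec$baseline)

  # phylogenetic deviations: one shared lambda-BM field per metric
  # (persists through metamorphosis) and a small adult-delta field
  dev_shared <- vapply(seq_along(metrics), function(j) {
    simulate_bm(tree, 1, rate = spec$phylo_sigma[j]^2,
                lambda = spec$lambda_tadpole,
                seed = spec$seed + 1000L + j)[, 1]
  }, numeric(n))
  dev_delta <- vapply(seq_along(metrics), function(j) {
    simulate_bm(tree, 1, rate = spec$delta_phylo_sigma[j]^2,
                lambda = spec$lambda_adult,
                seed = spec$seed + 2000L + j)[, 1]
  }, numeric(n))
  colnames(dev_shared) <- colnames(dev_delta) <- metrics

  out <- .with_seed(spec$seed, {
    n_paired <- round(spec$paired_fraction * n)
    roles <- rep("adult_only", n)
    pick <- sample.int(n, n_paired + spec$n_tadpole_only)
    roles[pick[seq_len(n_paired)]] <- "paired"
    if (spec$n_tadpole_only > 0) {
      roles[pick[n_paired + seq_len(spec$n_tadpole_only)]] <- "tadpole_only"
    }
    habit <- sample(names(spec$habit_freq), n, TRUE, spec$habit_freq)
    activity <- sample(names(spec$activity_freq), n, TRUE,
                       spec$activity_freq)
    env <- ifelse(habit == "aquatic", "aquatic", "terrestrial")
    habit_obs <- habit
    habit_obs[runif(n) < spec$habit_missing] <- NA
    activity_obs <- activity
    activity_obs[runif(n) < spec$activity_missing] <- NA

    latent <- sapply(metrics, function(m) {
      spec$baseline[m] + dev_shared[, m] + rnorm(n, 0, spec$sigma[m])
    })
    tad <- sapply(metrics, function(m) {
      latent[, m] + rnorm(n, 0, spec$stage_sigma[m])
    })
    delta <- sapply(metrics, function(m) {
      ifelse(env == "terrestrial", spec$delta_terrestrial[m],
             spec$delta_aquatic[m])
    })
    hab_off <- cbind(
      anisotropy = unname(ifelse(habit %in% names(spec$habit_anisotropy),
                                 spec$habit_anisotropy[habit], 0)),
      sphericity = unname(ifelse(habit %in% names(spec$habit_sphericity),
                                 spec$habit_sphericity[habit], 0)),
      elongation = 0)
    adult <- sapply(metrics, function(m) {
      latent[, m] + delta[, m] + hab_off[, m] + dev_delta[, m] +
        rnorm(n, 0, spec$stage_sigma[m])
    })

    eye_log <- rnorm(n, spec$allometry$eye_log_mean, spec$allometry$eye_log_sd)
    size_off <- ifelse(habit %in% names(spec$allometry$habit_offset),
                       spec$allometry$habit_offset[habit], 0)
    lens_log <- spec$allometry$intercept +
      spec$allometry$slope * eye_log + size_off +
      rnorm(n, 0, spec$allometry$sigma)
    has_diam <- runif(n) >= spec$diameter_missing
    list(roles = roles, habit = habit, habit_obs = habit_obs,
         activity = activity, activity_obs = activity_obs, env = env,
         tad = tad, adult = adult, delta = delta, hab_off = hab_off,
         eye_log = eye_log, lens_log = lens_log, has_diam = has_diam)
  })

  clip <- function(x) {
    if (any(x < 0 | x > 1)) {
      warning("metric values clipped to [0, 1]")
      x <- pmin(pmax(x, 0), 1)
    }
    x
  }

  rows <- list()
  for (i in seq_len(n)) {
    role <- out$roles[i]
    if (role %in% c("paired", "tadpole_only")) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp[i], life_stage = "tadpole",
        habit = NA, activity = NA,
        adult_environment = if (role == "paired") out$env[i] else NA,
        anisotropy = out$tad[i, "anisotropy"],
        sphericity = out$tad[i, "sphericity"],
        elongation = out$tad[i, "elongation"],
        lens_diameter_mm = NA_real_, eye_diameter_mm = NA_real_)
    }
    if (role %in% c("paired", "adult_only")) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp[i], life_stage = "adult",
        habit = out$habit_obs[i], activity = out$activity_obs[i],
        adult_environment = out$env[i],
        anisotropy = out$adult[i, "anisotropy"],
        sphericity = out$adult[i, "sphericity"],
        elongation = out$adult[i, "elongation"],
        lens_diameter_mm = if (out$has_diam[i]) 10^out$lens_log[i] else NA_real_,
        eye_diameter_mm = if (out$has_diam[i]) 10^out$eye_log[i] else NA_real_)
    }
  }
  table <- do.call(rbind, rows)
  for (m in metrics) table[[m]] <- clip(table[[m]])
  table <- validate_trait_table(table)

  truth <- list(spec = spec,
                habit = setNames(out$habit, sp),
                activity = setNames(out$activity, sp),
                adult_environment = setNames(out$env, sp),
                roles = setNames(out$roles, sp),
                tadpole_latent = out$tad, adult_latent = out$adult,
                delta_true = out$delta,
                allometry = spec$allometry)
  structure(list(table = table, tree = tree, truth = truth),
            class = "study_bundle")
}

#' Write a ready-to-analyze synthetic bundle to disk
#'
#' Emits the trait CSV, the Newick tree and a ground-truth JSON into a
#' directory, in the same dialects the pipeline reads.
#'
#' @param bundle a [make_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$table, file.path(dir, "traits.csv"), row.names = FALSE)
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  truth <- bundle$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
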
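HABIT_LEVELS <- c("aquatic", "semiaquatic", "scansorial", "ground-dwelling",
                  "subfossorial", "fossorial")
ACTIVITY_LEVELS <- c("nocturnal", "non-nocturnal")
STAGE_LEVELS <- c("tadpole", "adult")
ENVIRONMENT_LEVELS <- c("aquatic", "terrestrial")
METRIC_COLS <- c("anisotropy", "flatness", "elongation", "sphericity")

#' Validate a species trait table
#'
#' Checks the header contract of the species-level trait table: one row per
#' (species, life_stage); `life_stage` in tadpole/adult; `habit`, `activity`
#' and `adult_environment` limited to their documented categories (missing
#' allowed); shape metrics in \[0, 1\]; diameters positive when present.
#' Unknown columns are preserved but ignored.
#'
#' @param table data.frame.
#' @return The table, with categorical columns as factors with the full
#'   level sets, invisibly checked.
#' @export
validate_trait_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("species", "life_stage")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("trait table lacks columns: ", paste(miss, collapse = ", "))
  table$species <- normalize_species(table$species)
  bad_stage <- !table$life_stage %in% STAGE_LEVELS
  if (any(bad_stage)) {
    stop("unknown life_stage value(s): ",
         paste(unique(table$life_stage[bad_stage]), collapse = ", "))
  }
  if (anyDuplicated(table[c("species", "life_stage")])) {
    d <- table[duplicated(table[c("species", "life_stage")]), ]
    stop("multiple rows per species x stage (average specimens first): ",
         paste(unique(d$species), collapse = ", "))
  }
  .check_cat <- function(col, levels) {
    if (!col %in% names(table)) return(factor(rep(NA, nrow(table)), levels))
    v <- as.character(table[[col]])
    bad <- !is.na(v) & !v %in% levels
    if (any(bad)) {
      stop(sprintf("unknown %s value(s): %s", col,
                   paste(unique(v[bad]), collapse = ", ")))
    }
    factor(v, levels)
  }
  table$habit <- .check_cat("habit", HABIT_LEVELS)
  table$activity <- .check_cat("activity", ACTIVITY_LEVELS)
  table$adult_environment <- .check_cat("adult_environment", ENVIRONMENT_LEVELS)
  for (m in intersect(METRIC_COLS, names(table))) {
    v <- table[[m]]
    if (any(!is.na(v) & (v < 0 | v > 1))) stop(m, " values outside [0, 1]")
  }
  for (d in intersect(c("lens_diameter_mm", "eye_diameter_mm"), names(table))) {
    if (any(!is.na(table[[d]]) & table[[d]] <= 0)) stop(d, " must be > 0")
  }
  table
}

#' Collapse specimen measurements to species x stage means
#'
#' Averages metric and diameter columns over specimens within each
#' (species, life_stage) pair with equal weight, retaining specimen counts.
#' Ecological scores (`habit`, `activity`, `adult_environment`, `family`)
#' must agree across specimens of a species; conflicts raise an error
#' naming every conflicted species.
#'
#' @param specimens data.frame with one row per specimen: `species`,
#'   `life_stage`, metric columns, optionally diameters and ecology columns.
#' @return A species trait table (one row per species x stage) with an
#'   `n_specimens` column.
#' @export
species_means <- function(specimens) {
  stopifnot(is.data.frame(specimens))
  need <- c("species", "life_stage")
  miss <- setdiff(need, names(specimens))
  if (length(miss)) stop("specimen table lacks: ", paste(miss, collapse = ", "))
  specimens$species <- normalize_species(specimens$species)
  bad_stage <- is.na(specimens$life_stage) |
    !specimens$life_stage %in% STAGE_LEVELS
  if (any(bad_stage)) {
    stop("specimens with unknown or missing life_stage: rows ",
         paste(which(bad_stage), collapse = ", "))
  }
  eco_cols <- intersect(c("family", "habit", "activity", "adult_environment"),
                        names(specimens))
  conflicts <- character()
  for (col in eco_cols) {
    agg <- tapply(as.character(specimens[[col]]), specimens$species,
                  function(v) length(unique(v[!is.na(v)])))
    conflicts <- union(conflicts, names(agg)[!is.na(agg) & agg > 1])
  }
  if (length(conflicts)) {
    stop("conflicting ecological scores within species: ",
         paste(sort(conflicts), collapse = ", "))
  }
  num_cols <- intersect(c(METRIC_COLS, "lens_diameter_mm", "eye_diameter_mm"),
                        names(specimens))
  key <- interaction(specimens$species, specimens$life_stage, drop = TRUE)
  first <- !duplicated(key)
  out <- specimens[first, c(need, eco_cols), drop = FALSE]
  for (col in num_cols) {
    means <- tapply(specimens[[col]], key, mean)  # NA specimens propagate
    out[[col]] <- as.numeric(means[as.character(key[first])])
  }
  out$n_specimens <- as.integer(table(key)[as.character(key[first])])
  rownames(out) <- NULL
  validate_trait_table(out[order(out$species, out$life_stage), ])
}

#' Read a species trait table from CSV
#'
#' @param path CSV path following the documented header contract
#'   (see [validate_trait_table()]).
#' @param collapse if `TRUE` (default) and the file holds several specimens
#'   per species x stage, collapse them with [species_means()].
#' @return A validated species trait table.
#' @export
read_trait_table <- function(path, collapse = TRUE) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (collapse && anyDuplicated(tab[c("species", "life_stage")])) {
    species_means(tab)
  } else {
    validate_trait_table(tab)
  }
}

#' Read a phylogeny from Newick or NEXUS
#'
#' @param path tree file; NEXUS detected by a leading `#NEXUS`.
#' @return An [ape::phylo] with normalized tip labels.
#' @export
read_phylogeny <- function(path) {
  first <- toupper(trimws(readLines(path, n = 1L)))
  tree <- if (startsWith(first, "#NEXUS")) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  tree$tip.label <- normalize_species(tree$tip.label)
  tree
}
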
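#' Write the synthetic input bundle as delimited text tables
#'
#' Emits RFC-4180 CSVs (UTF-8, header row, '.' decimal separator):
#' `population.csv`, `beverages.csv`, `elasticities.csv`,
#' `diseases.csv`, `mortality.csv`, `child_utility.csv`, plus a
#' `synth.yaml` echo of the generating configuration.
#'
#' @param inputs A [synth_inputs()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_inputs <- function(inputs, dir) {
  stopifnot(inherits(inputs, "synth_inputs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                           row.names = FALSE, quote = FALSE)

  pop <- as.data.frame(inputs$population)
  wcsv(pop, "population.csv")

  bev <- inputs$beverages
  cons_long <- data.frame(
    category = rep(rownames(bev$consumption), times = ncol(bev$consumption)),
    band = rep(colnames(bev$consumption), each = nrow(bev$consumption)),
    ml_per_day = as.vector(bev$consumption),
    energy_density = rep(bev$energy_density[rownames(bev$consumption)],
                         times = ncol(bev$consumption)))
  wcsv(cons_long, "beverages.csv")

  ela <- do.call(rbind, lapply(names(bev$elasticities), function(lbl) {
    E <- bev$elasticities[[lbl]]
    data.frame(set = lbl,
               category = rep(rownames(E), times = ncol(E)),
               price_of = rep(colnames(E), each = nrow(E)),
               elasticity = as.vector(E))
  }))
  wcsv(ela, "elasticities.csv")

  dis <- do.call(rbind, lapply(inputs$diseases, function(d) {
    do.call(rbind, lapply(c("female", "male"), function(sx)
      data.frame(disease = d$name, sex = sx, age = model_ages(),
                 incidence = d$incidence[, sx],
                 prevalence = d$prevalence[, sx],
                 case_fatality = d$case_fatality[, sx],
                 log_rr_per_bmi = d$log_rr_per_bmi,
                 disability_weight = d$disability_weight,
                 cost_basis = d$cost_basis,
                 cost_per_case = d$cost_per_case)))
  }))
  rownames(dis) <- NULL
  wcsv(dis, "diseases.csv")

  mort <- do.call(rbind, lapply(c("female", "male"), function(sx)
    data.frame(sex = sx, age = model_ages(),
               all_cause_rate = unclass(inputs$mortality)[, sx])))
  wcsv(mort, "mortality.csv")

  cu <- inputs$child_utility
  thr <- cu$thresholds
  thr$set <- NA
  util_rows <- do.call(rbind, lapply(names(cu$sets), function(s)
    data.frame(age = NA, sex = NA, overweight_bmi = cu$sets[[s]][["overweight"]],
               obese_bmi = cu$sets[[s]][["obese"]], set = s)))
  wcsv(rbind(thr, util_rows), "child_utility.csv")

  yaml::write_yaml(list(seed = inputs$config$seed, scale = inputs$config$scale,
                        noise = inputs$config$noise),
                   file.path(dir, "synth.yaml"))
  invisible(dir)
}

#' Read a synthetic input bundle written by [write_synth_inputs()]
#'
#' @param dir Directory containing the CSV tables.
#' @return A list of class `synth_inputs` (the `config` element carries
#'   the echoed seed/scale/noise).
#' @export
read_synth_inputs <- function(dir) {
  rcsv <- function(f) utils::read.csv(file.path(dir, f),
                                      stringsAsFactors = FALSE)
  pop <- rcsv("population.csv")
  attr(pop, "reference_year") <- 2018L
  class(pop) <- c("population_spec", "data.frame")

  bev <- rcsv("beverages.csv")
  cats <- unique(bev$category)
  bands <- unique(bev$band)
  cons <- matrix(bev$ml_per_day, nrow = length(cats),
                 dimnames = list(cats, bands))
  dens <- stats::setNames(bev$energy_density[seq_along(cats)], cats)

  ela <- rcsv("elasticities.csv")
  elasticities <- lapply(split(ela, ela$set), function(df) {
    E <- matrix(df$elasticity, nrow = length(cats),
                dimnames = list(cats, cats))
    attr(E, "label") <- df$set[1]
    E
  })

  dis <- rcsv("diseases.csv")
  diseases <- lapply(split(dis, factor(dis$disease, unique(dis$disease))),
                     function(df) {
    mk <- function(col) {
      m <- matrix(0, length(model_ages()), 2,
                  dimnames = list(model_ages(), c("female", "male")))
      for (sx in c("female", "male"))
        m[, sx] <- df[[col]][df$sex == sx]
      m
    }
    list(name = df$disease[1], incidence = mk("incidence"),
         prevalence = mk("prevalence"), case_fatality = mk("case_fatality"),
         log_rr_per_bmi = df$log_rr_per_bmi[1],
         disability_weight = df$disability_weight[1],
         cost_basis = df$cost_basis[1], cost_per_case = df$cost_per_case[1])
  })
  diseases <- diseases[unique(dis$disease)]
  class(diseases) <- "disease_set"

  mort_df <- rcsv("mortality.csv")
  mort <- matrix(0, length(model_ages()), 2,
                 dimnames = list(model_ages(), c("female", "male")))
  for (sx in c("female", "male"))
    mort[, sx] <- mort_df$all_cause_rate[mort_df$sex == sx]
  class(mort) <- c("mortality_table", class(mort))

  cu_df <- rcsv("child_utility.csv")
  thr <- cu_df[is.na(cu_df$set), c("age", "sex", "overweight_bmi", "obese_bmi")]
  rownames(thr) <- NULL
  sets_df <- cu_df[!is.na(cu_df$set), ]
  sets <- lapply(split(sets_df, sets_df$set), function(df)
    c(overweight = df$overweight_bmi, obese = df$obese_bmi))
  child_utility <- structure(list(sets = sets, thresholds = thr),
                             class = "child_utility")

  cfg <- yaml::read_yaml(file.path(dir, "synth.yaml"))
  structure(list(population = pop,
                 beverages = structure(list(consumption = cons,
                                            energy_density = dens,
                                            elasticities = elasticities),
                                       class = "beverage_inputs"),
                 diseases = diseases, mortality = mort,
                 child_utility = child_utility,
                 config = synth_config(cfg$seed, cfg$scale, cfg$noise)),
            class = "synth_inputs")
}

#' Read a tax-scenario YAML file
#'
#' Recognised keys: `name`, `rate_per_litre` (scalar or per-category
#' map), `included_categories`, `pass_through`, `mean_price`,
#' `elasticity_set`, `healthcare_cost_multiplier`,
#' `implementation_cost_multiplier`, `child_utility_set`.
#'
#' @param path Path to a YAML file.
#' @return A [tax_scenario()].
#' @export
read_tax_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$name)) stop("scenario file must carry a name: ", path)
  rate <- y$rate_per_litre %||% 0
  if (is.list(rate)) rate <- unlist(rate)
  tax_scenario(
    name = y$name, rate_per_litre = rate,
    included_categories = unlist(y$included_categories) %||% character(),
    pass_through = y$pass_through %||% 1,
    mean_price = y$mean_price %||% 45.05,
    elasticity_set = y$elasticity_set %||% "mexico",
    healthcare_cost_multiplier = y$healthcare_cost_multiplier %||% 1,
    implementation_cost_multiplier = y$implementation_cost_multiplier %||% 1,
    child_utility_set = y$child_utility_set %||% "default")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load the bundled tax-scenario files
#'
#' The package ships YAML scenario files for the do-nothing comparator,
#' the originally proposed design (10/litre, coffee-based beverages
#' included), the implemented design (6/litre, coffee- and milk-based
#' beverages excluded), and sensitivity scenarios A-G (rate and tax-base
#' variants, an alternative elasticity set, halved per-case healthcare
#' costs, doubled implementation costs, alternative child utility
#' weights).
#'
#' @param names Optional subset of scenario names to load.
#' @return Named list of [tax_scenario()] objects.
#' @export
bundled_scenarios <- function(names = NULL) {
  dir <- system.file("extdata", "scenarios", package = "sbtaxsim")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  sc <- lapply(files, read_tax_scenario)
  names(sc) <- vapply(sc, `[[`, character(1), "name")
  if (!is.null(names)) {
    missing <- setdiff(names, names(sc))
    if (length(missing)) stop("config error: unknown scenario name(s): ",
                              paste(missing, collapse = ", "))
    sc <- sc[names]
  }
  sc
}
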
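#' Default genus panel for the simulated goat cohort
#'
#' Twenty-seven abundant hindgut genera with their family assignments and
#' per-enterotype mean relative abundances (percent), emulating a 76-animal
#' young-goat cohort that splits into two community types: one dominated by
#' fibrolytic/saccharolytic taxa (*Prevotella*, *Succinivibrio*, Muribaculaceae)
#' and one by *Christensenellaceae R-7 group*, *Rikenellaceae RC9 gut group*
#' and relatives. The remaining mass is pooled into an `"other"` feature so
#' each component mean vector sums to 1 after normalization.
#'
#' @return A tibble with columns `genus`, `family`, `mean_pct_1`,
#'   `mean_pct_2`.
#' @export
goat_genus_panel <- function() {
  tibble::tribble(
    ~genus,                                        ~family,                              ~mean_pct_1, ~mean_pct_2,
    "Oscillospiraceae_UCG-005",                    "Oscillospiraceae",                   10.82, 10.38,
    "unclassified_f_Lachnospiraceae",              "Lachnospiraceae",                     7.84,  8.62,
    "Rikenellaceae_RC9_gut_group",                 "Rikenellaceae",                       4.18,  7.96,
    "Christensenellaceae_R-7_group",               "Christensenellaceae",                 3.17,  8.23,
    "Treponema",                                   "Spirochaetaceae",                     4.93,  5.31,
    "Bacteroides",                                 "Bacteroidaceae",                      2.49,  4.82,
    "Norank_f_Muribaculaceae",                     "Muribaculaceae",                      4.72,  1.78,
    "Norank_f_UCG-010",                            "Oscillospirales_UCG-010",             2.80,  3.50,
    "Turicibacter",                                "Erysipelotrichaceae",                 3.53,  1.99,
    "Succinivibrio",                               "Succinivibrionaceae",                 3.84,  1.60,
    "Norank_f_norank_o_Clostridia_UCG-014",        "norank_o_Clostridia_UCG-014",         2.74,  1.96,
    "Ruminococcus",                                "Ruminococcaceae",                     2.07,  2.45,
    "Norank_f_Bacteroidales_RF16_group",           "Bacteroidales_RF16_group",            2.02,  2.47,
    "Alistipes",                                   "Rikenellaceae",                       1.96,  2.43,
    "Prevotella",                                  "Prevotellaceae",                      3.32,  0.93,
    "Norank_f_Eubacterium_coprostanoligenes_group","Eubacterium_coprostanoligenes_group", 1.88,  2.14,
    "Oscillospiraceae_UCG-002",                    "Oscillospiraceae",                    1.69,  1.70,
    "Oscillospiraceae_NK4A214_group",              "Oscillospiraceae",                    1.02,  1.78,
    "Phascolarctobacterium",                       "Acidaminococcaceae",                  1.65,  1.21,
    "Norank_f_F082",                               "F082",                                0.84,  1.88,
    "Romboutsia",                                  "Peptostreptococcaceae",               1.15,  1.44,
    "Monoglobus",                                  "Monoglobaceae",                       1.05,  1.51,
    "Roseburia",                                   "Lachnospiraceae",                     1.91,  0.52,
    "Prevotellaceae_UCG-003",                      "Prevotellaceae",                      1.75,  0.78,
    "Clostridium_sensu_stricto_1",                 "Clostridiaceae",                      0.95,  1.37,
    "Norank_f_Ruminococcaceae",                    "Ruminococcaceae",                     1.54,  0.76,
    "Prevotellaceae_NK3B31_group",                 "Prevotellaceae",                      2.08,  0.16
  )
}

#' Default phenotype panel for the simulated cohort
#'
#' Per-trait component means and a common standard deviation, in each
#' trait's own units, chosen as physiologically plausible values for
#' 6-month-old goat kids. Traits that differ between enterotypes do so in
#' the directions reported for growth and metabolism in two-community goat
#' cohorts: growth rate, fecal VFA (except butyrate), serum glucose and
#' cholesterol fractions higher in community 1; serum IgG and urea nitrogen
#' higher in community 2; intake, fecal ammonia, globulin, total protein and
#' triglycerides unchanged.
#'
#' @return A tibble with columns `trait`, `unit`, `mean_1`, `mean_2`, `sd`.
#' @export
goat_phenotype_panel <- function() {
  tibble::tribble(
    ~trait,              ~unit,      ~mean_1, ~mean_2, ~sd,
    "adg",               "kg/d",       0.149,   0.137, 0.018,
    "dmi",               "kg/d",       0.72,    0.72,  0.08,
    "acetate",           "mmol/kg",   32.0,    28.0,   6.0,
    "propionate",        "mmol/kg",    7.5,     6.3,   1.8,
    "butyrate",          "mmol/kg",    4.0,     4.0,   1.2,
    "valerate",          "mmol/kg",    0.90,    0.75,  0.25,
    "total_vfa",         "mmol/kg",   45.0,    39.5,   8.0,
    "nh3_n",             "mg/kg",    220,     220,    40,
    "albumin",           "g/L",       31.0,    29.0,   2.8,
    "globulin",          "g/L",       30.0,    30.0,   4.0,
    "total_protein",     "g/L",       61.0,    61.0,   5.0,
    "alb_glob_ratio",    "ratio",      1.05,    0.97,  0.12,
    "igg",               "g/L",        9.5,    11.0,   2.2,
    "glucose",           "mmol/L",     3.6,     3.3,   0.45,
    "urea_nitrogen",     "mmol/L",     4.6,     5.3,   1.0,
    "total_cholesterol", "mmol/L",     2.10,    1.85,  0.35,
    "hdl_c",             "mmol/L",     1.25,    1.10,  0.22,
    "ldl_c",             "mmol/L",     0.72,    0.62,  0.15,
    "triglycerides",     "mmol/L",     0.30,    0.30,  0.08
  )
}

#' Configuration for the enterotype-structured cohort simulator
#'
#' @param n_samples Integer vector of per-component sample counts
#'   (default `c(39, 37)`).
#' @param genus_panel Tibble like [goat_genus_panel()] with one `mean_pct_`
#'   column per component; means are renormalized and any shortfall below
#'   100% is assigned to an `"other"` feature.
#' @param concentration Dirichlet concentration scalar (default 200):
#'   per-sample genus proportions are drawn from
#'   Dirichlet(concentration x component mean vector), so larger values give
#'   tighter, better-separated communities.
#' @param depth Sequencing depth: multinomial total counts per sample
#'   (default 20000).
#' @param phenotype_panel Tibble like [goat_phenotype_panel()].
#' @param coupling Named list `trait = list(genus = ..., rho = ...)` adding
#'   rank (Gaussian-copula) dependence between a trait and one genus'
#'   realized relative abundance, on top of the component shift. The default
#'   couples growth rate positively to a community-1 fermenter, total VFA to
#'   Muribaculaceae, and urea nitrogen positively to
#'   *Christensenellaceae R-7 group*.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = c(39L, 37L),
                              genus_panel = goat_genus_panel(),
                              concentration = 200,
                              depth = 20000L,
                              phenotype_panel = goat_phenotype_panel(),
                              coupling = list(
                                adg = list(genus = "Prevotellaceae_NK3B31_group",
                                           rho = 0.35),
                                total_vfa = list(genus = "Norank_f_Muribaculaceae",
                                                 rho = 0.35),
                                urea_nitrogen = list(
                                  genus = "Christensenellaceae_R-7_group",
                                  rho = 0.30)
                              )) {
  stopifnot(length(n_samples) >= 2, all(n_samples >= 1),
            concentration > 0, depth > 0,
            all(phenotype_panel$sd > 0))
  mean_cols <- grep("^mean_pct_", names(genus_panel), value = TRUE)
  if (length(mean_cols) != length(n_samples)) {
    stop("genus_panel must carry one mean_pct_ column per component",
         call. = FALSE)
  }
  for (cc in mean_cols) {
    if (any(genus_panel[[cc]] < 0) || sum(genus_panel[[cc]]) <= 0) {
      stop("component mean vector must be non-negative and non-zero",
           call. = FALSE)
    }
  }
  structure(
    list(n_samples = as.integer(n_samples), genus_panel = genus_panel,
         concentration = concentration, depth = as.integer(depth),
         phenotype_panel = phenotype_panel, coupling = coupling),
    class = "simulation_config"
  )
}

#' Simulate an enterotype-structured cohort
#'
#' Dirichlet-multinomial generative model: for each sample of component c,
#' genus proportions are drawn from Dirichlet(concentration x mean vector of
#' c) and counts from Multinomial(depth, proportions). Phenotypes are drawn
#' from Normal(component mean, sd); traits listed in the coupling map gain
#' additional rank dependence on a genus through a Gaussian copula on the
#' genus' realized abundance. Fully reproducible from `seed`.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @return A list with `counts` (a [feature_table()] of genus counts),
#'   `taxonomy` (tibble), `metadata` (tibble of phenotypes), and `truth`
#'   (tibble `sample_id`, `component`).
#' @export
simulate_cohort <- function(cfg = simulation_config(), seed = 1) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  panel <- cfg$genus_panel
  mean_cols <- grep("^mean_pct_", names(panel), value = TRUE)
  n_comp <- length(mean_cols)
  # component mean vectors on the proportion scale, remainder -> "other"
  comp_means <- lapply(mean_cols, function(cc) {
    p <- panel[[cc]] / 100
    other <- max(0, 1 - sum(p))
    v <- c(p, other)
    v / sum(v)
  })
  genera <- c(panel$genus, "other")

  n_total <- sum(cfg$n_samples)
  component <- rep(seq_len(n_comp), cfg$n_samples)
  sample_ids <- sprintf("goat%03d", seq_len(n_total))

  counts <- matrix(0L, nrow = length(genera), ncol = n_total,
                   dimnames = list(genera, sample_ids))
  props <- matrix(0, nrow = length(genera), ncol = n_total,
                  dimnames = list(genera, sample_ids))
  for (i in seq_len(n_total)) {
    a <- cfg$concentration * comp_means[[component[i]]]
    g <- stats::rgamma(length(a), shape = pmax(a, 1e-12), rate = 1)
    p <- g / sum(g)
    props[, i] <- p
    counts[, i] <- stats::rmultinom(1, size = cfg$depth, prob = p)
  }

  ph <- cfg$phenotype_panel
  meta <- tibble::tibble(sample_id = sample_ids)
  for (r in seq_len(nrow(ph))) {
    tr <- ph$trait[r]
    mu <- c(ph$mean_1[r], ph$mean_2[r])[pmin(component, 2L)]
    eps <- stats::rnorm(n_total)
    cp <- cfg$coupling[[tr]]
    if (!is.null(cp) && cp$genus %in% genera) {
      ab <- props[cp$genus, ]
      z <- stats::qnorm(rank(ab, ties.method = "average") / (n_total + 1))
      eps <- cp$rho * z + sqrt(1 - cp$rho^2) * eps
    }
    meta[[tr]] <- mu + ph$sd[r] * eps
  }

  list(
    counts = feature_table(counts, kind = "counts"),
    taxonomy = tibble::tibble(
      feature_id = genera,
      phylum = NA_character_, class = NA_character_, order = NA_character_,
      family = c(panel$family, NA_character_),
      genus = genera
    ),
    metadata = meta,
    truth = tibble::tibble(sample_id = sample_ids,
                           component = as.integer(component))
  )
}

#' Average daily gain
#'
#' Growth rate of a kid from birth to a later weighing:
#' (final weight - birth weight) / days.
#'
#' @param birth_weight,final_weight Weights in kg, non-negative.
#' @param days Number of days between weighings, > 0.
#' @return ADG in kg/day.
#' @examples
#' compute_adg(3.11, 30.11, 188)
#' @export
compute_adg <- function(birth_weight, final_weight, days) {
  if (any(days <= 0)) stop("days must be > 0", call. = FALSE)
  if (any(birth_weight < 0) || any(final_weight < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  (final_weight - birth_weight) / days
}
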
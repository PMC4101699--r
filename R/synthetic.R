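#' Synthetic cohort configuration
#'
#' Describes a simulated cohort with planted structure: two latent subject
#' classes (emulating moderate vs severe airflow limitation), a subset of
#' genes differentially expressed between the classes, and a panel of
#' clinical characteristics whose association with the latent classes is
#' tunable per trait. Defaults emulate the design the method was developed
#' on: 140 subjects in two classes of 70, a 16-characteristic panel, and
#' log2-scale array-like expression (2,000 genes for tests; raise
#' `n_genes` to ~20,000 for a full-size demonstration).
#'
#' @param n_subjects Number of subjects.
#' @param n_genes Number of genes.
#' @param class_sizes Integer vector of the two latent class sizes
#'   (must sum to `n_subjects`).
#' @param n_de_genes Number of genes shifted between the classes.
#' @param effect_size Mean shift of planted genes, log2 units.
#' @param noise_sd Residual SD of expression, log2 units.
#' @param traits Tibble with columns `name`, `kind` (continuous | binary |
#'   ordinal), `association` (`"none"` or `"planted"`), `strength`
#'   (class separation in latent SD units). Default: a 16-trait panel
#'   emulating severity, two emphysema readouts, BMI, phlegm, age, walking
#'   distance, cough, sex and seven blood biomarkers.
#' @param block_correlation Correlation, in `[0, 1)`, induced among the
#'   planted genes by a shared per-subject latent factor (default 0 —
#'   independent genes). The DE-count objective is sensitive to gene-gene
#'   correlation, so this knob exists for stress testing.
#' @param seed Integer seed.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 140L,
                         n_genes = 2000L,
                         class_sizes = NULL,
                         n_de_genes = 100L,
                         effect_size = 1,
                         noise_sd = 1,
                         traits = default_trait_panel(),
                         block_correlation = 0,
                         seed = 1L) {
  if (is.null(class_sizes)) {
    class_sizes <- c(floor(n_subjects / 2), n_subjects - floor(n_subjects / 2))
  }
  class_sizes <- as.integer(class_sizes)
  if (length(class_sizes) != 2L || sum(class_sizes) != n_subjects) {
    abort("`class_sizes` must be two sizes summing to `n_subjects`")
  }
  if (n_de_genes > n_genes) abort("`n_de_genes` must not exceed `n_genes`")
  assert_scalar_number(effect_size, "effect_size", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(block_correlation, "block_correlation", min = 0, max = 0.99)
  traits <- tibble::as_tibble(traits)
  need <- c("name", "kind", "association", "strength")
  if (!all(need %in% names(traits))) {
    abort("`traits` needs columns name, kind, association, strength")
  }
  if (anyDuplicated(traits$name)) abort("duplicate trait names")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_genes = as.integer(n_genes),
    class_sizes = class_sizes,
    n_de_genes = as.integer(n_de_genes),
    effect_size = effect_size,
    noise_sd = noise_sd,
    traits = traits,
    block_correlation = block_correlation,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Default synthetic trait panel
#'
#' Sixteen characteristics emulating the clinical panel the method was
#' applied to: an ordinal severity grade and two emphysema readouts
#' strongly tied to the latent classes, a moderately associated fibrinogen
#' level, weakly associated BMI / phlegm / age / walking distance, and
#' unassociated cough, sex and remaining biomarkers.
#'
#' @return Tibble with columns `name`, `kind`, `association`, `strength`.
#' @export
default_trait_panel <- function() {
  tibble::tribble(
    ~name,       ~kind,        ~association, ~strength,
    "GOLDCD",    "ordinal",    "planted",    2.0,
    "FV950",     "continuous", "planted",    1.5,
    "EMPHETCD",  "ordinal",    "planted",    1.2,
    "FIBRINOG",  "continuous", "planted",    0.8,
    "BMI",       "continuous", "planted",    0.6,
    "PHLEGM",    "binary",     "planted",    0.6,
    "AGE",       "continuous", "planted",    0.5,
    "DWALK",     "continuous", "planted",    0.5,
    "COUGH",     "binary",     "none",       0.0,
    "SEX",       "binary",     "none",       0.0,
    "IL6",       "continuous", "none",       0.0,
    "IL8",       "continuous", "none",       0.0,
    "HSCRP",     "continuous", "none",       0.0,
    "CCL18",     "continuous", "none",       0.0,
    "SPD",       "continuous", "none",       0.0,
    "TNFA",      "continuous", "none",       0.0
  )
}

#' Generate a synthetic cohort
#'
#' Expression value for gene g and subject s is drawn as
#' `Normal(mu_g + delta_g * class(s), noise_sd)` with baseline
#' `mu_g ~ Normal(8, 1.5)` log2 units and `delta_g = effect_size` for the
#' planted genes (0 otherwise). Planted continuous traits are
#' `strength * class(s) + Normal(0, 1)`; planted ordinal traits cut the
#' same latent variable into 5 levels; planted binary traits flip toward
#' the subject's class with probability `plogis(strength * (2 class - 1))`.
#' Everything is a deterministic function of the seed.
#'
#' @param config A [synth_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list of class `vista_synth` with `expression`
#'   ([expression_matrix()]), `clinical` ([clinical_table()]) and `truth`
#'   (list: `classes` named vector, `de_genes`, `trait_associations`).
#' @export
synth_generate <- function(config = synth_config(), seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(seed, {
    n <- config$n_subjects
    p <- config$n_genes
    subject_ids <- sprintf("S%03d", seq_len(n))
    gene_ids <- sprintf("G%05d", seq_len(p))
    cls <- rep(c(0L, 1L), times = config$class_sizes)

    mu <- rnorm(p, mean = 8, sd = 1.5)
    de_genes <- if (config$n_de_genes > 0) gene_ids[seq_len(config$n_de_genes)] else character()
    delta <- c(rep(config$effect_size, config$n_de_genes),
               rep(0, p - config$n_de_genes))
    noise <- matrix(rnorm(p * n, sd = config$noise_sd), p, n)
    rho <- config$block_correlation
    if (rho > 0 && config$n_de_genes > 0) {
      # shared per-subject factor across the planted block, variance kept
      # at noise_sd^2 so the marginal model is unchanged
      f <- rnorm(n, sd = config$noise_sd)
      block <- seq_len(config$n_de_genes)
      noise[block, ] <- sqrt(1 - rho) * noise[block, ] +
        matrix(sqrt(rho) * f, length(block), n, byrow = TRUE)
    }
    values <- noise + mu + outer(delta, cls)
    expr <- expression_matrix(values, gene_ids, subject_ids)

    tr <- config$traits
    cols <- list(subject_id = subject_ids)
    for (i in seq_len(nrow(tr))) {
      strength <- if (tr$association[i] == "planted") tr$strength[i] else 0
      latent <- strength * cls + rnorm(n)
      cols[[tr$name[i]]] <- switch(tr$kind[i],
        continuous = latent,
        ordinal = findInterval(latent, c(-1, 0, 1, 2)) + 1,
        binary = {
          pr <- stats::plogis(strength * (2 * cls - 1))
          c("no", "yes")[1L + (runif(n) < pr)]
        },
        abort(sprintf("unknown trait kind '%s'", tr$kind[i]))
      )
    }
    kinds <- setNames(tr$kind, tr$name)
    clinical <- suppressWarnings(clinical_table(tibble::as_tibble(cols), kinds))

    structure(list(
      expression = expr,
      clinical = clinical,
      truth = list(
        classes = setNames(cls, subject_ids),
        de_genes = de_genes,
        trait_associations = tr
      ),
      config = config,
      seed = seed
    ), class = "vista_synth")
  })
}

#' @export
print.vista_synth <- function(x, ...) {
  cat(sprintf(
    "<vista_synth> %d subjects (classes %s), %d genes (%d planted DE at shift %.2g), %d traits\n",
    x$config$n_subjects, paste(x$config$class_sizes, collapse = "/"),
    x$config$n_genes, x$config$n_de_genes, x$config$effect_size,
    nrow(x$config$traits)
  ))
  invisible(x)
}

#' Frozen simulation scenarios
#'
#' @param name One of:
#'   * `"null"` — no planted expression signal, no trait associations;
#'     calibration of type-I behaviour.
#'   * `"strong_core"` — 40 subjects in two classes of 20, 300 genes with
#'     30 planted at a 4-SD shift, one strongly class-associated trait;
#'     the planted-recovery test bed.
#'   * `"core_plus_trait"` — 60 subjects, 500 genes, a severity-like
#'     driver plus one weaker secondary (BMI-like) trait; the reduced
#'     end-to-end pipeline scenario.
#'   * `"full_scale"` — 140 subjects in two classes of 70, 20,000 genes;
#'     the full-size design (run counts and reservoir size to match are in
#'     [vista_params()] defaults).
#' @return A [synth_config()].
#' @export
scenario_library <- function(name) {
  known <- c("null", "strong_core", "core_plus_trait", "full_scale")
  if (!is.character(name) || length(name) != 1L || !name %in% known) {
    abort(sprintf("unknown scenario; available: %s", paste(known, collapse = ", ")))
  }
  strong_traits <- tibble::tribble(
    ~name,       ~kind,        ~association, ~strength,
    "SEVERITY",  "continuous", "planted",    2.5,
    "NULLTRAIT", "continuous", "none",       0.0,
    "NULLBIN",   "binary",     "none",       0.0
  )
  switch(name,
    null = synth_config(
      n_subjects = 40L, n_genes = 300L, class_sizes = c(20L, 20L),
      n_de_genes = 0L, effect_size = 0,
      traits = dplyr::mutate(default_trait_panel(),
                             association = "none", strength = 0),
      seed = 101L
    ),
    strong_core = synth_config(
      n_subjects = 40L, n_genes = 300L, class_sizes = c(20L, 20L),
      n_de_genes = 30L, effect_size = 4, noise_sd = 1,
      traits = strong_traits, seed = 202L
    ),
    core_plus_trait = synth_config(
      n_subjects = 60L, n_genes = 500L, class_sizes = c(30L, 30L),
      n_de_genes = 40L, effect_size = 3, noise_sd = 1,
      traits = tibble::tribble(
        ~name,       ~kind,        ~association, ~strength,
        "SEVERITY",  "ordinal",    "planted",    2.5,
        "BMI",       "continuous", "planted",    1.0,
        "NULLTRAIT", "continuous", "none",       0.0,
        "NULLBIN",   "binary",     "none",       0.0
      ),
      seed = 303L
    ),
    full_scale = synth_config(
      n_subjects = 140L, n_genes = 20000L, class_sizes = c(70L, 70L),
      n_de_genes = 1000L, effect_size = 1.5, noise_sd = 1,
      seed = 404L
    )
  )
}

#' Write a synthetic cohort to disk
#'
#' Writes the expression TSV, clinical CSV with YAML schema sidecar, and a
#' ground-truth JSON.
#'
#' @param x A `vista_synth` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(x, dir) {
  stopifnot(inherits(x, "vista_synth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(x$expression, file.path(dir, "expression.tsv"))
  write_clinical(x$clinical, file.path(dir, "clinical.csv"),
                 file.path(dir, "clinical.schema.yaml"))
  truth <- list(
    classes = as.list(x$truth$classes),
    de_genes = x$truth$de_genes,
    trait_associations = x$truth$trait_associations,
    seed = x$seed
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
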
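#' Run the full analysis pipeline
#'
#' Orchestrates the whole workflow from one configuration: load or
#' simulate the cohort, drive the shuffling runs, test clinical
#' characteristics on every division, aggregate co-occurrence with a
#' random-division baseline, and (optionally) build subtypes with their
#' differential expression, fold-change lists and pathway enrichment. All
#' artifacts are TSV/CSV/JSON plus a Markdown summary; every byte is a
#' deterministic function of the configuration, so rerunning a config
#' reproduces the output exactly.
#'
#' @param config Path to a YAML configuration file, or an equivalent
#'   nested list. Top-level keys:
#'   * `seed` — master seed (integer).
#'   * `data` — either `scenario: <name>` (see [scenario_library()]) or
#'     `expression`, `clinical`, `schema` file paths.
#'   * `vista` — optional overrides of [vista_params()] fields
#'     (`n_runs`, `reservoir_size`, `max_attempts`, `engine`,
#'     `fdr_threshold`, `n_permutations`, `plateau_window`).
#'   * `assoc` — optional `alpha`.
#'   * `cooccurrence` — optional `max_order`, `baseline_divisions`.
#'   * `subtypes` — optional: `fdr_threshold`, `min_fc`, `gmt` path, and
#'     `definitions`, a list of `{name, a_rule, b_rule}` entries.
#'   * `out_dir` — output directory.
#' @param out_dir Overrides `config$out_dir`.
#'
#' @return Invisibly, a list with the in-memory results (`fit`, `report`,
#'   `baseline`, `subtypes`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) abort("an output directory is required (out_dir)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- data -----------------------------------------------------------
  dat <- stage("data", {
    dc <- config$data
    if (is.null(dc)) abort("config$data is required")
    if (!is.null(dc$scenario)) {
      cfg <- scenario_library(dc$scenario)
      synth <- synth_generate(cfg, seed = derive_seed(seed, 0L))
      list(expr = synth$expression, clinical = synth$clinical, synth = synth)
    } else {
      if (is.null(dc$expression)) abort("config$data$expression path is missing")
      if (is.null(dc$clinical) || is.null(dc$schema)) {
        abort("config$data$clinical and config$data$schema paths are required")
      }
      expr <- suppressMessages(read_expression(dc$expression,
                                               dialect = dc$dialect %||% "tsv"))
      clinical <- read_clinical(dc$clinical, dc$schema)
      check_subject_alignment(expr, clinical)
      list(expr = expr, clinical = clinical, synth = NULL)
    }
  })

  # --- shuffling runs -------------------------------------------------
  vc <- config$vista %||% list()
  params <- vista_params(
    reservoir_size = vc$reservoir_size %||% 40L,
    max_attempts = vc$max_attempts %||% 2000L,
    plateau_window = vc$plateau_window,
    n_runs = vc$n_runs %||% 500L,
    seed = seed,
    engine = vc$engine %||% "sam",
    fdr_threshold = vc$fdr_threshold %||% 0.1,
    n_permutations = vc$n_permutations %||% 100L
  )
  fit <- stage("vista", vista_drive(dat$expr, params))

  # --- clinical association -------------------------------------------
  alpha <- (config$assoc %||% list())$alpha %||% 0.05
  fit <- stage("assoc", test_divisions(fit, dat$clinical, alpha = alpha))

  # --- co-occurrence + baseline ---------------------------------------
  cc <- config$cooccurrence %||% list()
  max_order <- cc$max_order %||% 4L
  report <- stage("cooccur", cooccurrence_report(fit, max_order = max_order))
  sizes <- partition_sizes(fit$divisions[[1]]$partition)
  baseline <- stage("baseline", random_division_baseline(
    dat$clinical, sizes = sizes,
    n_divisions = cc$baseline_divisions %||% 10000L,
    alpha = alpha, max_order = max_order,
    seed = derive_seed(seed, 999983L)
  ))

  # --- optional subtypes ----------------------------------------------
  subtypes <- NULL
  sc <- config$subtypes
  if (!is.null(sc) && length(sc$definitions %||% list())) {
    subtypes <- stage("subtypes", {
      defs <- purrr::map(sc$definitions, function(d) {
        subtype_definition(d$name, d$a_rule, d$b_rule,
                           core_traits = unlist(d$core_traits %||% character()),
                           distinctive_trait = d$distinctive_trait)
      })
      fdr <- sc$fdr_threshold %||% 0.05
      res <- purrr::map(defs, function(def) {
        grp <- suppressMessages(build_subtype_groups(dat$clinical, def))
        de <- if (identical(params$engine, "ttest")) {
          suppressMessages(ttest_count_de(dat$expr, grp$A, grp$B, fdr_threshold = fdr))
        } else {
          suppressMessages(sam_count_de(
            dat$expr, grp$A, grp$B,
            params = sam_params(n_permutations = vc$n_permutations %||% 100L,
                                fdr_threshold = fdr,
                                seed = derive_seed(seed, 424242L))
          ))
        }
        fc <- fold_change_genes(dat$expr, grp$A, grp$B,
                                min_fc = sc$min_fc %||% 2, de_result = de)
        list(definition = def, groups = grp, de = de, fold_changes = fc)
      })
      names(res) <- purrr::map_chr(defs, "name")
      venn <- if (length(res) >= 2L) venn_decompose(purrr::map(res, "de")) else NULL
      enrichment <- NULL
      if (!is.null(sc$gmt)) {
        sets <- read_gmt(sc$gmt)
        enrichment <- purrr::imap_dfr(res, function(r, nm) {
          q <- called_genes(r$de)
          if (!length(q)) return(tibble())
          dplyr::mutate(enrich(q, sets, universe = rownames(dat$expr)),
                        subtype = nm, .before = 1)
        })
      }
      list(results = res, venn = venn, enrichment = enrichment)
    })
  }

  stage("write", write_pipeline_outputs(out_dir, config, seed, params, alpha,
                                        dat, fit, report, baseline, subtypes))
  inform(sprintf("pipeline complete; artifacts in %s", out_dir))
  invisible(list(fit = fit, report = report, baseline = baseline,
                 subtypes = subtypes, out_dir = out_dir))
}

# Serialize all pipeline artifacts deterministically.
write_pipeline_outputs <- function(out_dir, config, seed, params, alpha,
                                   dat, fit, report, baseline, subtypes) {
  tsv <- function(df, name) readr::write_tsv(df, file.path(out_dir, name), progress = FALSE)

  assignments <- purrr::map_dfr(fit$divisions, function(d) {
    dplyr::mutate(tidy(d$partition), run_id = d$run_id, .before = 1)
  })
  tsv(assignments, "assignments.tsv")
  tsv(purrr::map_dfr(fit$divisions, tidy), "trajectories.tsv")
  tsv(tidy(fit), "runs.tsv")
  tsv(trait_tests_tbl(fit), "trait_tests.tsv")

  sig <- significance_matrix(fit)
  tsv(dplyr::mutate(tibble::as_tibble(sig), run_id = rownames(sig), .before = 1),
      "significance_matrix.tsv")

  tsv(report$singles, "cooccurrence_singles.tsv")
  tsv(dplyr::select(report$tuples, -"members"), "cooccurrence_tuples.tsv")
  tsv(baseline$singles, "baseline_singles.tsv")
  tsv(dplyr::select(baseline$tuples, -"members"), "baseline_tuples.tsv")

  if (!is.null(subtypes)) {
    purrr::iwalk(subtypes$results, function(r, nm) {
      slug <- gsub("[^A-Za-z0-9]+", "_", nm)
      tsv(tidy(r$de), sprintf("subtype_%s_de.tsv", slug))
      tsv(r$fold_changes$up, sprintf("subtype_%s_fc_up.tsv", slug))
      tsv(r$fold_changes$down, sprintf("subtype_%s_fc_down.tsv", slug))
    })
    if (!is.null(subtypes$venn)) {
      venn <- list(
        unique_counts = lapply(subtypes$venn$unique_sets, length),
        common_count = length(subtypes$venn$common),
        cells = subtypes$venn$cells
      )
      jsonlite::write_json(venn, file.path(out_dir, "venn.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    if (!is.null(subtypes$enrichment) && nrow(subtypes$enrichment)) {
      tsv(subtypes$enrichment, "enrichment.tsv")
    }
  }

  digest_file <- function(p) {
    if (is.null(p) || !is.character(p) || !file.exists(p)) return(NULL)
    unname(tools::md5sum(p))
  }
  manifest <- list(
    tool = "vista",
    version = as.character(utils::packageVersion("vista")),
    master_seed = seed,
    alpha = alpha,
    params = params[c("reservoir_size", "max_attempts", "n_runs", "fdr_threshold",
                      "n_permutations", "accept_ties")],
    engine = if (is.function(params$engine)) "custom" else params$engine,
    run_seeds = vapply(fit$divisions, function(d) d$seed, numeric(1)),
    input_digests = list(
      expression = digest_file(config$data$expression),
      clinical = digest_file(config$data$clinical),
      scenario = config$data$scenario
    ),
    n_subjects = length(fit$subject_ids),
    n_genes = nrow(dat$expr)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  top <- head(dplyr::arrange(report$singles, dplyr::desc(.data$k)), 5)
  frac_any <- mean(vapply(fit$divisions, function(d) length(d$significant_traits) > 0,
                          logical(1)))
  summary_md <- c(
    "# Divisive shuffling pipeline summary", "",
    sprintf("- runs: %d (reservoir %d, %d attempts, engine %s, objective FDR %.3g)",
            length(fit$divisions), params$reservoir_size, params$max_attempts,
            manifest$engine, params$fdr_threshold),
    sprintf("- divisions with at least one significant trait (alpha = %.3g): %.1f%%",
            alpha, 100 * frac_any),
    sprintf("- most frequent traits: %s",
            paste(sprintf("%s (%d/%d)", top$trait, top$k, report$n_runs), collapse = ", ")),
    sprintf("- random-division baseline: %d divisions", baseline$n_runs),
    ""
  )
  writeLines(summary_md, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}
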
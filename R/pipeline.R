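#' Run a declarative analysis pipeline
#'
#' Executes any subset of the package's stages from a single nested
#' configuration (a list, or a YAML file if the yaml package is installed),
#' in dependency order, collecting per-stage results and status into one
#' report. Configuration is validated before any computation: unknown stage
#' names and missing input files are rejected up front. A stage that fails
#' at run time yields `status = "error"` for that stage (with the message),
#' not a crash of the whole run.
#'
#' Recognised stages and their keys:
#' * `speciation`: `total_metal`, `total_ligand`, `kd` (vectors ok)
#' * `simulate`: `model`, `params`, `design` (a design name like
#'   `"initial_velocity"`, `"oxalate_vs_pep"`, ... or a data frame),
#'   `noise_scale`, `replicates`, `seed`
#' * `fit`: `data` (data frame or delimited file with header columns),
#'   `model`, optional `weights`, `seed`; or `data = "simulate"` to fit the
#'   simulated stage output
#' * `mechanism`: `velocity` (data frame/file for the pattern),
#'   `inhibition` — list of entries with `data` (data frame/file),
#'   `inhibitor`, `varied`, `analog_of`
#' * `interactions`: `pdb` (file), optional `protein` (for [pk_domains()])
#'   or `domains`, `kinds` (subset of pi_pi/salt_bridge/hbond/interface),
#'   `chain`, `exclude`
#' * `qtraj`: `reference` (PDB file), `trajectory` (file), optional
#'   `domain` (range string), `cutoff`, `min_seq_sep`, `tolerance_factor`
#' * `conserve`: `alignment` (FASTA file or named vector),
#'   `reference_id`, `positions`, optional `covariation` (anchor/partners)
#'
#' @param config Nested list, or path to a YAML file.
#' @return A `pk_report`: `results` (per-stage `status` + `value`),
#'   `settings` (the validated config), `stages`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs needs the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  known <- c("speciation", "simulate", "fit", "mechanism", "interactions",
             "qtraj", "conserve")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  if (!length(config)) abort("empty pipeline config")

  # validate file references before any computation
  for (stage in names(config)) {
    cfg <- config[[stage]]
    for (key in c("data", "pdb", "reference", "trajectory", "alignment")) {
      val <- cfg[[key]]
      if (is.character(val) && length(val) == 1 && val != "simulate" &&
          !file.exists(val)) {
        abort(paste0("stage `", stage, "`: input file not found: ", val))
      }
    }
    if (!is.null(cfg$model) &&
        !cfg$model %in% c(pk_models(), "ordered", "ping_pong")) {
      abort(paste0("stage `", stage, "`: unknown model `", cfg$model, "`"))
    }
  }

  results <- list()
  run_stage <- function(name, fn) {
    results[[name]] <<- tryCatch(
      list(status = "ok", value = fn()),
      error = function(e) list(status = "error", value = NULL,
                               error = conditionMessage(e))
    )
  }
  load_table <- function(x) {
    if (is.data.frame(x)) return(tibble::as_tibble(x))
    if (identical(x, "simulate")) {
      if (is.null(results$simulate$value)) abort("no simulate stage output")
      return(results$simulate$value)
    }
    tibble::as_tibble(utils::read.table(x, header = TRUE))
  }

  for (stage in names(config)) {
    cfg <- config[[stage]]
    switch(stage,
      speciation = run_stage("speciation", function() {
        speciate(total_metal = cfg$total_metal,
                 total_ligand = cfg$total_ligand, kd = cfg$kd)
      }),
      simulate = run_stage("simulate", function() {
        design <- if (is.data.frame(cfg$design)) cfg$design else
          switch(cfg$design,
            initial_velocity = design_initial_velocity(),
            design_inhibition(cfg$design))
        make_velocity_dataset(cfg$model, unlist(cfg$params), design,
          noise = noise_model(scale = cfg$noise_scale %||% 0.05),
          replicates = cfg$replicates %||% 1, seed = cfg$seed %||% 1)
      }),
      fit = run_stage("fit", function() {
        fit_global(load_table(cfg$data), cfg$model,
                   weights = cfg$weights %||% "none",
                   seed = cfg$seed %||% 1)
      }),
      mechanism = run_stage("mechanism", function() {
        pat <- double_reciprocal_pattern(load_table(cfg$velocity),
                                         varied = cfg$varied %||% "a",
                                         fixed = cfg$fixed %||% "b")
        ev <- purrr::map_dfr(cfg$inhibition, function(entry) {
          f <- fit_inhibition_series(load_table(entry$data))
          call <- classify_inhibition(f)
          tibble::tibble(inhibitor = entry$inhibitor,
                         varied = entry$varied, analog_of = entry$analog_of,
                         kind = call$kind, alpha_flag = call$alpha_flag)
        })
        infer_mechanism(pat, ev)
      }),
      interactions = run_stage("interactions", function() {
        s <- read_structure(cfg$pdb)
        doms <- if (!is.null(cfg$protein)) pk_domains(cfg$protein) else
          lapply(cfg$domains, function(d) domain_definition(d$name, d$ranges))
        kinds <- cfg$kinds %||% c("pi_pi", "salt_bridge", "hbond", "interface")
        out <- list()
        if ("pi_pi" %in% kinds) out$pi_pi <- pi_pi_pairs(s, chain = cfg$chain)
        if ("salt_bridge" %in% kinds) {
          out$salt_bridge <- salt_bridges(s, chain = cfg$chain)
        }
        if ("hbond" %in% kinds) out$hbond <- hbonds(s, chain = cfg$chain)
        if ("interface" %in% kinds) {
          out$interface <- interface_contacts(s, doms$A, doms$B,
                                              chain = cfg$chain,
                                              exclude = cfg$exclude)
        }
        out
      }),
      qtraj = run_stage("qtraj", function() {
        ref <- read_structure(cfg$reference)
        sel <- if (!is.null(cfg$domain)) {
          domain_definition("selection", cfg$domain)
        } else NULL
        cm <- native_contact_map(ref, cutoff = cfg$cutoff %||% 8,
                                 min_seq_sep = cfg$min_seq_sep %||% 3,
                                 selection = sel)
        tr <- read_trajectory(cfg$trajectory,
                              format = cfg$format %||% "pdb")
        q_trajectory(tr, cm,
                     tolerance_factor = cfg$tolerance_factor %||% 1.2)
      }),
      conserve = run_stage("conserve", function() {
        out <- list(profile = column_profile(cfg$alignment,
                                             cfg$reference_id,
                                             cfg$positions))
        if (!is.null(cfg$covariation)) {
          out$covariation <- covariation(cfg$alignment, cfg$reference_id,
                                         cfg$covariation$anchor,
                                         cfg$covariation$partners)
        }
        out
      })
    )
  }

  structure(list(results = results, settings = config,
                 stages = names(config)), class = "pk_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pk_report <- function(x, ...) {
  cat("<pk_report>", length(x$results), "stage(s)\n")
  for (nm in names(x$results)) {
    st <- x$results[[nm]]
    cat(" -", nm, ":", st$status,
        if (st$status == "error") paste0("(", st$error, ")") else "", "\n")
  }
  invisible(x)
}
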
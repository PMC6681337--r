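#' Pipeline configuration
#'
#' Declarative configuration for \code{\link{run_pipeline}}. Every value can
#' be overridden; unknown keys are rejected before any computation.
#'
#' @param input path to a subunit structure file (PDB/mmCIF), or
#'   \code{"synthetic"} (default) to generate a toy subunit.
#' @param chain chain id to take from \code{input} (default first chain).
#' @param segments named list of segment residue ranges to annotate on the
#'   subunit (e.g. \code{list(D0N = c(1, 46), L_STRETCH = c(47, 84), D1 =
#'   c(85, 221), D0C = c(222, 260))}, the default St-FlgG boundaries).
#' @param twist_deg,rise_A screw parameters (default: distal rod, 64.75 /
#'   4.13).
#' @param index_range lattice index range (default \code{c(-21, 0)}: 22
#'   subunits, four turns of the 1-start helix).
#' @param cutoff_A contact cutoff (default 4.0).
#' @param sensitivity_cutoffs cutoffs for the fingerprint sensitivity table.
#' @param fingerprint_segment segment to fingerprint (default
#'   \code{"L_STRETCH"}).
#' @param sites mutation sites to map (default integer(0)).
#' @param arm_direction,seed synthetic-subunit parameters (used only with
#'   \code{input = "synthetic"}).
#' @param out_dir output directory.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = "synthetic", chain = NULL,
                            segments = NULL, twist_deg = 64.75, rise_A = 4.13,
                            index_range = c(-21, 0), cutoff_A = 4.0,
                            sensitivity_cutoffs = c(3.5, 4.0, 4.5),
                            fingerprint_segment = "L_STRETCH",
                            sites = integer(0), arm_direction = -5, seed = 1,
                            out_dir = "axialkit_out") {
  cfg <- list(input = input, chain = chain, segments = segments,
              twist_deg = twist_deg, rise_A = rise_A,
              index_range = index_range, cutoff_A = cutoff_A,
              sensitivity_cutoffs = sensitivity_cutoffs,
              fingerprint_segment = fingerprint_segment, sites = sites,
              arm_direction = arm_direction, seed = seed, out_dir = out_dir)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  known <- c("input", "chain", "segments", "twist_deg", "rise_A",
             "index_range", "cutoff_A", "sensitivity_cutoffs",
             "fingerprint_segment", "sites", "arm_direction", "seed",
             "out_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (!is.numeric(cfg$twist_deg) || cfg$twist_deg <= 0 || cfg$twist_deg >= 360)
    stop("config: twist_deg must be in (0, 360)")
  if (!is.numeric(cfg$rise_A) || cfg$rise_A <= 0)
    stop("config: rise_A must be positive")
  if (length(cfg$index_range) != 2L || cfg$index_range[2] < cfg$index_range[1])
    stop("config: index_range must be c(n_min, n_max)")
  if (!is.numeric(cfg$cutoff_A) || cfg$cutoff_A <= 0)
    stop("config: cutoff_A must be positive")
  invisible(TRUE)
}

#' Run the assembly-and-analysis pipeline
#'
#' Ties the stages together the way the published rod/hook models were
#' analysed: load or simulate a subunit, build the helical assembly from
#' the screw parameters, verify the symmetry by re-inferring it from the
#' built coordinates, compute the contact network, fingerprint the chosen
#' segment at several cutoffs, and map mutation sites. All outputs are
#' written to \code{out_dir}: the assembly (PDB, or mmCIF when more than
#' 62 chains), the contact-edge table (TSV), the fingerprint summary
#' (JSON), the mutation-site report (TSV), the symmetry-inference report
#' (JSON), and a log with package version, seed, and parameters.
#'
#' @param config a \code{\link{pipeline_config}} (or plain list with the
#'   same keys).
#' @return list with the in-memory results (\code{assembly}, \code{edges},
#'   \code{fingerprint}, \code{sensitivity}, \code{symmetry_fit},
#'   \code{sites}, \code{files}).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sym <- screw_symmetry(config$twist_deg, config$rise_A)

  if (identical(config$input, "synthetic")) {
    sub <- make_toy_subunit(toy_subunit_spec(arm_direction = config$arm_direction,
                                             seed = config$seed), sym)
  } else {
    models <- read_structure(config$input)
    sub <- if (is.null(config$chain)) models[[1]] else models[[config$chain]]
    if (is.null(sub)) stop("chain '", config$chain, "' not found in ", config$input)
    if (!is.null(config$segments))
      sub <- subunit_model(sub$atoms, sub$chain_id,
                           segments = config$segments)
  }

  asm <- build_assembly(sub, sym, config$index_range)
  n_chains <- length(asm$indices)
  asm_path <- file.path(config$out_dir,
                        if (n_chains > 62) "assembly.cif" else "assembly.pdb")
  write_structure(asm, asm_path)

  fit <- infer_symmetry(asm)
  edges <- contact_map(asm, config$cutoff_A)
  utils::write.table(as.data.frame(edges),
                     file.path(config$out_dir, "contacts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  mid <- mean(range(asm$indices))
  ref <- asm$indices[which.min(abs(asm$indices - mid))]
  fp <- tryCatch(segment_fingerprint(edges, ref, config$fingerprint_segment),
                 error = function(e) NULL)
  sens <- tryCatch(fingerprint_sensitivity(asm, ref, config$fingerprint_segment,
                                           config$sensitivity_cutoffs),
                   error = function(e) NULL)
  jsonlite::write_json(
    list(reference_index = ref, segment = config$fingerprint_segment,
         cutoff_A = config$cutoff_A,
         fingerprint = fp, sensitivity = sens),
    file.path(config$out_dir, "fingerprint.json"),
    auto_unbox = TRUE, digits = NA, null = "null")

  sites_rep <- NULL
  if (length(config$sites)) {
    sites_rep <- map_mutation_sites(asm, config$sites, config$cutoff_A, ref)
    tab <- do.call(rbind, lapply(sites_rep, function(r) {
      env <- r$environment
      names(env)[names(env) == "segment"] <- "partner_segment"
      if (nrow(env))
        cbind(site = r$site, modeled = r$modeled, approximate = r$approximate,
              own_segment = r$segment, env)
      else data.frame(site = r$site, modeled = r$modeled,
                      approximate = r$approximate, own_segment = r$segment,
                      offset = NA, partner_segment = NA, resno = NA,
                      resid = NA, min_dist_A = NA)
    }))
    utils::write.table(tab, file.path(config$out_dir, "sites.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  jsonlite::write_json(
    list(input_twist_deg = config$twist_deg, input_rise_A = config$rise_A,
         inferred_twist_deg = fit$twist_deg, inferred_rise_A = fit$rise_A,
         max_step_rmsd_A = max(fit$steps$rmsd_A)),
    file.path(config$out_dir, "symmetry.json"), auto_unbox = TRUE, digits = NA)

  writeLines(c(paste("axialkit", as.character(utils::packageVersion("axialkit"))),
               paste("date:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               paste("seed:", config$seed),
               paste("input:", config$input),
               paste("twist_deg:", config$twist_deg),
               paste("rise_A:", config$rise_A),
               paste("index_range:", paste(config$index_range, collapse = ":")),
               paste("cutoff_A:", config$cutoff_A)),
             file.path(config$out_dir, "run_log.txt"))

  list(assembly = asm, edges = edges, fingerprint = fp, sensitivity = sens,
       symmetry_fit = fit, sites = sites_rep,
       files = list.files(config$out_dir, full.names = TRUE))
}
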
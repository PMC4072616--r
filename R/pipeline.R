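#' Run the whole screening pipeline from a config
#'
#' Executes read -> segment -> enumerate -> energy -> call -> burden ->
#' report, writing every table plus a reproducibility manifest to the
#' output directory.  With a fixed seed the outputs are byte-identical
#' across runs.
#'
#' @param config either a path to a YAML file or a list with elements
#'   `inputs` (`hairpins`, optionally `annotation`, `snps`, `targets`:
#'   file paths), `params` (any of `backend`, `linker`, `ext_size`,
#'   `iterations`, `alpha`, `seed`, `freq_range`) and `output_dir`.
#' @param output_dir overrides `config$output_dir` when given.
#' @param quiet suppress stage messages.
#' @return invisibly, a list with every intermediate table: `hairpins`,
#'   `segments`, `variants`, `energy`, `calls`, `burden`, `tiers`,
#'   `comparison`, and `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- modifyList(
    list(
      backend = "vienna", linker = "GGCGGGG", ext_size = 25,
      iterations = 1000, alpha = 0.05, seed = 1, freq_range = NULL
    ),
    config$params %||% list()
  )
  out_dir <- output_dir %||% config$output_dir
  if (is.null(out_dir)) stop("no output_dir configured", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[mirsnpscan] ", ...)
  inputs <- config$inputs

  say("reading inputs")
  hairpins <- read_hairpins(inputs$hairpins, inputs$annotation)
  known <- if (!is.null(inputs$snps)) read_snp_table(inputs$snps, hairpins) else NULL
  target_map <- if (!is.null(inputs$targets)) read_target_map(inputs$targets) else NULL

  say("segmenting ", nrow(hairpins), " hairpins")
  segments <- segment_hairpins(hairpins,
    ext_size = params$ext_size, backend = params$backend
  )

  say("enumerating variants")
  variants <- enumerate_artificial(hairpins, segments, known)

  say("computing free-energy changes (", params$backend, " backend)")
  energy <- compute_energy_changes(hairpins, segments, variants,
    target_map = target_map, backend = params$backend, linker = params$linker
  )

  say("calling candidates")
  calls <- select_inflection(direction_filter(energy))
  comparison <- compare_known_artificial(calls)

  say("burden ranking (", params$iterations, " iterations)")
  burden <- monte_carlo_burden(calls,
    iterations = params$iterations, alpha = params$alpha,
    seed = params$seed, freq_range = params$freq_range
  )

  say("writing results to ", out_dir)
  keys <- c("snp_id", "hairpin_id", "position", "ref", "alt", "segment_class")
  calls_full <- dplyr::left_join(
    calls, burden[c(keys, "selection_frequency", "burden")],
    by = keys
  )
  tiers <- summarize_tiers(energy, calls)
  readr::write_tsv(segments, file.path(out_dir, "segments.tsv"))
  write_results(energy, calls_full, file.path(out_dir, "results.tsv"))
  readr::write_tsv(
    dplyr::filter(calls_full, .data$candidate),
    file.path(out_dir, "candidates.tsv")
  )
  readr::write_tsv(tibble::as_tibble(burden), file.path(out_dir, "burden.tsv"))
  readr::write_tsv(tiers, file.path(out_dir, "tiers.tsv"))
  readr::write_tsv(comparison, file.path(out_dir, "known_vs_artificial.tsv"))
  writeLines(
    density_report(segments, variants, tiers),
    file.path(out_dir, "report.txt")
  )

  manifest <- list(
    package = paste0("mirsnpscan ", as.character(utils::packageVersion("mirsnpscan"))),
    backend = params$backend,
    backend_version = attr(fold_backend(params$backend), "version"),
    linker = params$linker,
    ext_size = params$ext_size,
    iterations = params$iterations,
    alpha = params$alpha,
    seed = params$seed,
    knee_method = "max_distance_to_chord",
    inputs = lapply(
      Filter(Negate(is.null), inputs[c("hairpins", "annotation", "snps", "targets")]),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))
    )
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(
    hairpins = hairpins, segments = segments, variants = variants,
    energy = energy, calls = calls_full, burden = burden, tiers = tiers,
    comparison = comparison, manifest = manifest
  ))
}
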
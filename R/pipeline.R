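#' Load and validate a pipeline configuration
#'
#' Configurations are plain lists, or paths to YAML/JSON files with the
#' same structure. The image pipeline expects `seed`, `out_dir` and a
#' `nuclei` list of [nucleus_params()] argument sets; the RINP pipeline
#' expects `seed`, `out_dir`, `genes` (gene model argument sets or a
#' `gtf` path), `stages` (name + unspliced fraction `u` each),
#' `replicates`, `n_reads` and `read_length`.
#'
#' @param config list or path to a `.yaml`/`.yml`/`.json` file.
#' @return the configuration list.
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
                     yaml = , yml = yaml::read_yaml(config),
                     json = jsonlite::read_json(config,
                                                simplifyVector = TRUE),
                     stop("unsupported config format: ", ext))
  }
  if (!is.list(config)) stop("validation error: config must be a list")
  config
}

provenance_block <- function(config, seed) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(cfg_json, tf)
  list(package_version =
         as.character(utils::packageVersion("nucarch")),
       config_hash = unname(tools::md5sum(tf)),
       seed = seed)
}

write_report_csv <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]],
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
}

#' Run the image analysis pipeline
#'
#' Simulates (or will later ingest) each configured nucleus, then runs
#' segmentation, volume measurement, seven-class intensity
#' classification with marker enrichment, shell extraction with
#' contact concordance, structure detection and the census, and writes
#' the per-nucleus result tables as CSV. Deterministic given the seed:
#' nucleus `i` uses substream `i` of the master seed.
#'
#' @param config list or config file path; see
#'   [load_pipeline_config()]. Required: `nuclei` (list of parameter
#'   sets for [nucleus_params()]). Optional: `seed` (default 1),
#'   `out_dir` (default: no files written), `analysis` (list with
#'   `k`, `thickness_nm`, `contact_nm`, `npc_nm`).
#' @return a `run_report` list with `volumes`, `enrichment`, `tests`,
#'   `concordance`, `census`, `structures` data frames and a
#'   `provenance` block (package version, config hash, seed).
#' @export
run_image_pipeline <- function(config) {
  config <- load_pipeline_config(config)
  if (is.null(config$nuclei) || !length(config$nuclei))
    stop("validation error: config$nuclei must list at least one nucleus")
  an <- config$analysis %||% list()
  k <- an$k %||% 7L
  seed <- config$seed %||% 1L
  for (nc in config$nuclei) {
    bad <- setdiff(names(nc), names(formals(nucleus_params)))
    if (length(bad))
      stop("validation error: unknown nucleus parameter(s): ",
           paste(bad, collapse = ", "))
  }
  volumes <- enrich_rows <- test_rows <- conc_rows <- list()
  census_in <- list()
  structures_rows <- list()
  for (i in seq_along(config$nuclei)) {
    args <- config$nuclei[[i]]
    args$seed <- substream(seed, i)
    p <- do.call(nucleus_params, args)
    sim <- gen_nucleus_stack(p)
    stack <- sim$stack
    # the lamina channel delineates the envelope even when chromatin
    # contacts only part of it, so it is the default volume channel here
    mask <- segment_nucleus(stack,
                            channel = an$segment_channel %||% "laminB")
    vol <- nuclear_volume(mask, stack)
    volumes[[i]] <- data.frame(nucleus = i, phenotype = p$phenotype,
                               volume_um3 = vol,
                               true_volume_um3 = sim$truth$volume_um3)
    cm <- classify_voxels(stack, "DAPI", region = mask, k = k)
    mm <- marker_mask(stack, "NUP153", region = mask)
    prof <- enrichment_profile(cm, mm)
    pe <- as.data.frame(prof)
    pe$nucleus <- i
    enrich_rows[[i]] <- pe
    gt <- gof_test(prof)
    test_rows[[i]] <- data.frame(nucleus = i, test = gt$method,
                                 statistic = gt$statistic, df = gt$df,
                                 p_value = gt$p_value,
                                 log10_p = gt$log10_p)
    shell <- lamina_shell(mask, stack,
                          thickness_nm = an$thickness_nm %||% 200,
                          contact_nm = an$contact_nm %||% 200,
                          npc_nm = an$npc_nm %||% 150)
    cc <- npc_chromatin_concordance(shell)
    conc_rows[[i]] <- data.frame(
      nucleus = i, odds_ratio = cc$odds_ratio, p_value = cc$p_value,
      frac_npc_contacted = cc$fraction_npc_contacted,
      frac_npc_noncontacted = cc$fraction_npc_noncontacted,
      degenerate = cc$degenerate)
    st <- detect_structures(stack, mask, shell)
    census_in[[i]] <- st
    sdf <- as.data.frame(st)
    if (nrow(sdf)) sdf$nucleus <- i
    structures_rows[[i]] <- sdf
  }
  census <- structure_census(census_in)
  tables <- list(volumes = do.call(rbind, volumes),
                 enrichment = do.call(rbind, enrich_rows),
                 tests = do.call(rbind, test_rows),
                 concordance = do.call(rbind, conc_rows),
                 structures = do.call(rbind, structures_rows),
                 census_groups = census$group_summary)
  if (!is.null(config$out_dir)) write_report_csv(tables, config$out_dir)
  structure(c(tables, list(census = census,
                           provenance = provenance_block(config, seed))),
            class = "run_report")
}

#' Run the RINP pipeline
#'
#' Simulates read alignments for each stage x replicate at the stage's
#' unspliced fraction, computes per-gene intron coverage and RINP, and
#' aggregates over gene sets and stages. Replicate `j` of stage `i`
#' uses substream `100 * i + j` of the master seed.
#'
#' @param config list or config file path. Required: `genes` (list of
#'   [gene_model()] argument sets) or `gtf` (file path), and `stages`
#'   (list of lists with `name` and `u`). Optional: `replicates`
#'   (default 3, matching the sequencing design of three replicates
#'   per stage), `n_reads` (default 2000), `read_length` (default 80),
#'   `gene_sets`, `seed`, `out_dir`.
#' @return a `run_report` list with `coverage` (per gene x stage x
#'   replicate), `rinp` (an `rinp_table`) and `provenance`.
#' @export
run_rinp_pipeline <- function(config) {
  config <- load_pipeline_config(config)
  if (!is.null(config$gtf)) {
    gms <- read_gene_models_gtf(config$gtf)
  } else {
    if (is.null(config$genes) || !length(config$genes))
      stop("validation error: empty gene list")
    gms <- lapply(config$genes, function(g) do.call(gene_model, g))
    names(gms) <- vapply(gms, `[[`, "", "gene_id")
  }
  if (is.null(config$stages) || !length(config$stages))
    stop("validation error: no stages configured")
  seed <- config$seed %||% 1L
  n_rep <- config$replicates %||% 3L
  n_reads <- config$n_reads %||% 2000L
  read_len <- config$read_length %||% 80L
  cov_rows <- list()
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$name) || is.null(st$u))
      stop("validation error: each stage needs `name` and `u`")
    for (j in seq_len(n_rep)) {
      rp <- read_sim_params(gms, unspliced_fraction = st$u,
                            n_reads = n_reads, read_length = read_len,
                            seed = substream(seed, 100L * i + j))
      al <- gen_reads(rp)
      for (gm in gms) {
        cc <- intronic_coverage(al, gm)
        cc$stage <- st$name
        cc$replicate <- j
        cov_rows[[length(cov_rows) + 1L]] <- cc
      }
    }
  }
  coverage <- do.call(rbind, cov_rows)
  rinp <- aggregate_rinp(coverage, gene_sets = config$gene_sets)
  tables <- list(coverage = coverage,
                 rinp_replicates = rinp$replicates,
                 rinp_stage_means = rinp$stage_means)
  if (!is.null(config$out_dir)) write_report_csv(tables, config$out_dir)
  structure(list(coverage = coverage, rinp = rinp,
                 provenance = provenance_block(config, seed)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("nucarch run report (package",
      x$provenance$package_version, ", seed", x$provenance$seed, ")\n")
  for (nm in setdiff(names(x), c("provenance", "census", "rinp"))) {
    if (is.data.frame(x[[nm]]))
      cat("  ", nm, ": ", nrow(x[[nm]]), " row(s)\n", sep = "")
  }
  invisible(x)
}
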
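## Workbench: configuration, end-to-end cohort analysis, reproducible
## pipeline runs with file outputs and a checksummed manifest.

#' Pipeline run configuration
#'
#' Collects every knob of a reproducible run. All randomness in the
#' pipeline derives from `seed` through per-stage child streams, so any
#' stage can be reproduced in isolation.
#'
#' @param seed master seed.
#' @param voxel_size_um phantom voxel size in micrometers (default 100,
#'   the desk-scale setting; 30 reproduces the scanner resolution at
#'   considerable cost).
#' @param jitter_sd latent-truth jitter, pp.
#' @param designs design acronyms to build.
#' @param out_dir output directory for [run_pipeline()].
#' @param write_volumes write phantom volumes as multipage TIFFs.
#' @param export_meshes write design STL meshes.
#' @param stages named logical vector enabling pipeline stages.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, voxel_size_um = 100, jitter_sd = 0.2,
                       designs = c("TC", "TB", "PB", "PC"),
                       out_dir = "osteoscaffold_run",
                       write_volumes = TRUE, export_meshes = FALSE,
                       stages = c(build = TRUE, cohort = TRUE,
                                  quantify = TRUE, score = TRUE,
                                  stats = TRUE)) {
  structure(list(seed = as.integer(seed),
                 voxel_size_um = voxel_size_um,
                 jitter_sd = jitter_sd, designs = designs,
                 out_dir = out_dir, write_volumes = write_volumes,
                 export_meshes = export_meshes,
                 stages = as.list(stages)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg$stages <- lapply(cfg$stages, isTRUE)
  cfg
}

## Substrate cache shared across seeds within a session.
.substrate_cache <- new.env(parent = emptyenv())

cached_substrate <- function(acronym, voxel_size) {
  key <- paste(acronym, format(voxel_size), sep = "@")
  if (is.null(.substrate_cache[[key]]))
    .substrate_cache[[key]] <- phantom_substrate(acronym,
                                                 voxel_size = voxel_size)
  .substrate_cache[[key]]
}

#' End-to-end cohort analysis in memory
#'
#' Generates the default cohort truth, builds all 24 phantoms,
#' quantifies the ingrowth fraction of each through the
#' material-appropriate segmentation path, extracts the five virtual
#' scoring sections per sample, scores them (truth scoring plus
#' three simulated raters resolved by consensus), renders one
#' fluorescence interface section per sample and measures the mineral
#' apposition rate, and runs the cohort statistics.
#'
#' @param seed master seed.
#' @param voxel_size phantom voxel size, mm (default 0.1).
#' @param jitter_sd latent-truth jitter, pp (default 0.2).
#' @param rater_p_err rater noise probability per direction.
#' @param keep_sections keep the section masks in the result (memory).
#' @return list with `cohort` (latent truth), `table` (24-row results:
#'   animal, leg, design, modulus, fraction, truth_pp), `sections_n`,
#'   `scores` (truth, raters, consensus, rescore log), `mar`
#'   (per-sample MAR, um/day), `classification`, `summary`,
#'   `regression`, `pairwise`.
#' @export
run_cohort_analysis <- function(seed = 1L, voxel_size = 0.1,
                                jitter_sd = 0.2, rater_p_err = 0.1,
                                keep_sections = FALSE) {
  cohort <- default_cohort(seed, jitter_sd = jitter_sd)
  truth <- cohort$truth
  n <- nrow(truth)
  fractions <- numeric(n)
  mar <- numeric(n)
  truth_scores <- vector("list", n)
  sections_n <- 0L
  kept <- if (keep_sections) vector("list", n) else NULL
  for (i in seq_len(n)) {
    row <- truth[i, ]
    sub <- cached_substrate(row$design, voxel_size)
    ph <- build_phantom(sub, row$latent_total_pp,
                        peripheral_pp = row$peripheral_pp,
                        seed = child_seed(seed, "noise", i))
    defect <- delineate_defect(ph)
    bone <- if (ph$titanium)
      segment_bone_local_interpolated(ph, defect = defect)
    else segment_bone_global(ph, defect = defect)
    fractions[i] <- ingrowth_fraction(bone, defect, ph$porosity)$fraction
    secs <- virtual_sections(ph, bone_mask = bone)
    sections_n <- sections_n + length(secs)
    sid <- paste0("A", row$animal, "_", row$leg)
    truth_scores[[i]] <- score_sections(secs, sample_id = sid)
    if (keep_sections) kept[[i]] <- secs
    central_pp <- row$latent_total_pp - row$peripheral_pp
    act <- max(0, min(1, central_pp / 15))
    off <- with_seed(child_seed(seed, "marband", i), runif(1, 28, 42))
    fs <- render_fluor_section(7.5, off, seed = child_seed(seed, "mar", i),
                               central_activity = act)
    mar[i] <- mineral_apposition_rate(fs)
    rm(ph, bone, defect)
  }
  truth_scores <- do.call(rbind, truth_scores)
  raters <- simulate_raters(truth_scores, n_raters = 3, p_err = rater_p_err,
                            seed = child_seed(seed, "raterdraw"))
  cons <- consensus_scores(raters, truth = truth_scores,
                           p_err = rater_p_err,
                           seed = child_seed(seed, "consensus"))
  table <- data.frame(animal = truth$animal, leg = truth$leg,
                      design = truth$design,
                      modulus = design_reference_modulus(truth$design),
                      fraction = fractions,
                      truth_pp = truth$latent_total_pp,
                      responder_truth = truth$responder_class,
                      stringsAsFactors = FALSE)
  classification <- classify_responders(table)
  out <- list(cohort = cohort, table = table, sections_n = sections_n,
              scores = list(truth = truth_scores, raters = raters,
                            consensus = cons$consensus,
                            rescore_log = cons$rescore_log),
              mar = mar,
              classification = classification,
              summary = summarize_cohort(table, classification),
              regression = stiffness_regression(table),
              pairwise = design_pairwise_tests(table))
  if (keep_sections) out$sections <- kept
  out
}

write_volume_tiff <- function(vol, path) {
  v <- vol / max(vol)
  v[v < 0] <- 0
  v[v > 1] <- 1
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Run the full pipeline with file outputs
#'
#' Executes build, cohort, quantify, score and stats stages according
#' to the configuration, writing per-stage outputs under
#' `config$out_dir` (`designs/`, `phantoms/`, `results.csv`,
#' `scores.csv`, `report.json`) plus `manifest.json` listing every
#' written file with its MD5 checksum and the configuration. Re-running
#' with the same configuration reproduces all stochastic outputs. When
#' the quantify stage is disabled, the stats stage re-reads the cached
#' `results.csv` so a stats-only rerun reproduces the report from disk.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (list with files/md5 and the report).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  h <- config$voxel_size_um / 1000
  report <- list(seed = config$seed, voxel_size_um = config$voxel_size_um)
  stage <- function(name) isTRUE(config$stages[[name]])
  fail <- function(name, e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)

  if (stage("build")) tryCatch({
    dir.create(file.path(out, "designs"), showWarnings = FALSE)
    for (acr in config$designs) {
      bl <- build_design_lattice(acr, voxel_size = max(h, 0.1),
                                 seed = child_seed(config$seed, "lattice"))
      pj <- file.path(out, "designs", paste0(acr, ".json"))
      jsonlite::write_json(list(acronym = acr, radius_mm = bl$radius,
                                porosity = bl$porosity,
                                nominal_porosity = bl$design$nominal_porosity,
                                reference_modulus_MPa =
                                  design_reference_modulus(acr),
                                struts = nrow(bl$lattice$struts),
                                seed = config$seed),
                          pj, auto_unbox = TRUE, digits = NA)
      files <- c(files, pj)
      if (isTRUE(config$export_meshes)) {
        ps <- file.path(out, "designs", paste0(acr, ".stl"))
        export_mesh(bl$lattice, ps, design = bl$design)
        files <- c(files, ps, sub("\\.stl$", ".json", ps))
      }
    }
  }, error = function(e) fail("build", e))

  res <- NULL
  if (stage("cohort") || stage("quantify") || stage("score")) tryCatch({
    res <- run_cohort_analysis(seed = config$seed, voxel_size = h,
                               jitter_sd = config$jitter_sd)
    ct <- file.path(out, "cohort_truth.csv")
    write.csv(cbind(res$cohort$truth, seed = config$seed), ct,
              row.names = FALSE)
    files <- c(files, ct)
  }, error = function(e) fail("cohort", e))

  if (stage("quantify") && !is.null(res)) tryCatch({
    rc <- file.path(out, "results.csv")
    write.csv(cbind(res$table, seed = config$seed), rc, row.names = FALSE)
    files <- c(files, rc)
    if (isTRUE(config$write_volumes)) {
      dir.create(file.path(out, "phantoms"), showWarnings = FALSE)
      for (i in seq_len(nrow(res$cohort$truth))) {
        row <- res$cohort$truth[i, ]
        sub <- cached_substrate(row$design, h)
        ph <- build_phantom(sub, row$latent_total_pp,
                            peripheral_pp = row$peripheral_pp,
                            seed = child_seed(config$seed, "noise", i))
        pt <- file.path(out, "phantoms",
                        sprintf("A%02d_%s_%s.tif", row$animal, row$leg,
                                row$design))
        write_volume_tiff(ph$vol, pt)
        files <- c(files, pt)
        rm(ph)
      }
    }
  }, error = function(e) fail("quantify", e))

  if (stage("score") && !is.null(res)) tryCatch({
    sc <- file.path(out, "scores.csv")
    write.csv(cbind(res$scores$raters, seed = config$seed), sc,
              row.names = FALSE)
    cc <- file.path(out, "scores_consensus.csv")
    write.csv(cbind(res$scores$consensus, seed = config$seed), cc,
              row.names = FALSE)
    files <- c(files, sc, cc)
  }, error = function(e) fail("score", e))

  if (stage("stats")) tryCatch({
    table <- if (!is.null(res)) res$table else {
      rc <- file.path(out, "results.csv")
      if (!file.exists(rc))
        stop("no in-memory results and no cached results.csv")
      read.csv(rc, stringsAsFactors = FALSE)
    }
    cls <- classify_responders(table)
    report$summary <- summarize_cohort(table, cls)
    report$regression <- stiffness_regression(table)
    report$pairwise <- design_pairwise_tests(table)
    report$classification <- cls
    if (!is.null(res)) {
      report$sections_n <- res$sections_n
      report$mar_um_per_day <- res$mar
    }
    rj <- file.path(out, "report.json")
    jsonlite::write_json(report, rj, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(files, rj)
  }, error = function(e) fail("stats", e))

  manifest <- list(seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("osteoscaffold")),
                   r_version = as.character(getRversion()),
                   config = unclass(config),
                   files = data.frame(
                     path = files,
                     md5 = unname(tools::md5sum(files)),
                     stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(manifest)
}

#' Verify a pipeline run against its manifest
#'
#' Recomputes the MD5 checksum of every file listed in the run's
#' `manifest.json` and errors, naming the file, on any mismatch.
#'
#' @param out_dir the run directory.
#' @return TRUE invisibly when all checksums match.
#' @export
verify_manifest <- function(out_dir) {
  mf <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                            simplifyVector = TRUE)
  for (i in seq_len(nrow(mf$files))) {
    p <- mf$files$path[i]
    if (!file.exists(p))
      stop("checksum error: missing file ", p)
    cur <- unname(tools::md5sum(p))
    if (!identical(cur, mf$files$md5[i]))
      stop("checksum error: file corrupted: ", p)
  }
  invisible(TRUE)
}
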
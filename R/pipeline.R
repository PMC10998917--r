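#' Pipeline configuration with published-parameter defaults
#'
#' Collects every stage's parameters in one object. The numeric defaults
#' are the profiling parameters of the original CellProfiler-style recipe:
#' 20 px QC tiles, focus cutoff 0.2, 50 px illumination blocks, 5% robust
#' trimming, 2 deviations, correction factor 0.89, smoothing scale 1.3488,
#' 5--50 px object diameters.
#'
#' @param metadata_csv,image_dir,output_dir file-system paths; all
#'   optional when running purely in memory.
#' @param qc list: `tile_px`, `focus_threshold`, and `channels` -- the
#'   channels whose focus score decides removal. The default is
#'   `"hoechst"`: every object carries Hoechst signal (the membrane
#'   permeable DNA dye stains live, dead and ETotic material alike), so
#'   its focus score measures optics, whereas SytoxGreen content varies
#'   with the biology of the field; use `c("hoechst", "sytox")` to require
#'   both channels to pass. Scores for both channels are always reported.
#' @param illumination list: `block_px`, `combine` (`subtract`/`divide`),
#'   `statistic` (`min`/`percentile`), `percentile`.
#' @param segmentation a [seg_params()].
#' @param gating list: `mode` (`auto`/`manual`), `control_treatment` (for
#'   auto gates), `gate_sytox`/`gate_hoechst` (for manual), `epsilon`,
#'   `min_et_area_px`.
#' @param stats list: `unit` (biological replication unit, `"animal"`, or
#'   `c("animal","replicate")` to treat every well as a sample),
#'   `control`, `metrics`, `welch`.
#' @param segment_channel image driving segmentation (`max`, `hoechst`,
#'   `sytox`).
#' @param seed integer seed recorded in the run manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(metadata_csv = NULL,
                            image_dir = NULL,
                            output_dir = NULL,
                            qc = list(tile_px = 20L, focus_threshold = 0.2,
                                      channels = "hoechst"),
                            illumination = list(block_px = 50L,
                                                combine = "subtract",
                                                statistic = "min",
                                                percentile = 0.02),
                            segmentation = seg_params(),
                            gating = list(mode = "auto",
                                          control_treatment = "control",
                                          gate_sytox = NULL,
                                          gate_hoechst = NULL,
                                          epsilon = 1e-6,
                                          min_et_area_px = NULL),
                            stats = list(unit = "animal",
                                         control = "control",
                                         metrics = c("pct_etotic", "pct_dead"),
                                         welch = FALSE),
                            segment_channel = "max",
                            seed = 1L) {
  cfg <- list(metadata_csv = metadata_csv, image_dir = image_dir,
              output_dir = output_dir, qc = qc,
              illumination = illumination, segmentation = segmentation,
              gating = gating, stats = stats,
              segment_channel = segment_channel, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a dataset of image pairs from a metadata table
#'
#' Loads the two registered channels of every field of view listed in the
#' metadata CSV (columns `image_id, animal, treatment, replicate,
#' hoechst_path, sytox_path`; paths relative to `image_dir`). TIFFs are
#' read on the `[0, 1]` dynamic-range scale.
#'
#' @param metadata_csv path to the CSV.
#' @param image_dir directory resolving relative image paths; defaults to
#'   the CSV's directory.
#' @return list of pairs (`image_id`, `animal`, `treatment`, `replicate`,
#'   `hoechst`, `sytox`), usable with [run_pipeline()].
#' @export
read_dataset <- function(metadata_csv, image_dir = dirname(metadata_csv)) {
  md <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  req <- c("image_id", "animal", "treatment", "replicate",
           "hoechst_path", "sytox_path")
  miss <- setdiff(req, names(md))
  if (length(miss))
    stop_stage("read_dataset", "metadata missing columns: ",
               paste(miss, collapse = ", "))
  if (nrow(md) == 0L) {
    warning("metadata CSV is empty: ", metadata_csv)
    return(list())
  }
  if (anyDuplicated(md$image_id))
    stop_stage("read_dataset", "duplicate image_id: ",
               md$image_id[duplicated(md$image_id)][1])
  lapply(seq_len(nrow(md)), function(i) {
    read_ch <- function(p, ch) {
      fp <- file.path(image_dir, p)
      if (is.na(p) || !nzchar(p) || !file.exists(fp))
        stop_stage("read_dataset",
                   sprintf("missing %s image for image_id '%s': %s",
                           ch, md$image_id[i], fp))
      img <- tiff::readTIFF(fp)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      pmax(img, 0)
    }
    h <- read_ch(md$hoechst_path[i], "hoechst")
    s <- read_ch(md$sytox_path[i], "sytox")
    if (!all(dim(h) == dim(s)))
      stop_stage("read_dataset",
                 sprintf("channel shape mismatch for image_id '%s'",
                         md$image_id[i]))
    list(image_id = md$image_id[i], animal = md$animal[i],
         treatment = md$treatment[i], replicate = md$replicate[i],
         hoechst = h, sytox = s)
  })
}

#' Run the full profiling pipeline on a set of image pairs
#'
#' Executes the fixed stage order: focus QC filter, per-channel
#' illumination correction, robust-background segmentation with
#' declumping, per-object measurement, merge/QC exclusion, bivariate
#' gating, replicate aggregation and the treatment-vs-control t tests.
#' Deterministic given the dataset and configuration; when
#' `config$output_dir` is set, all tables are written as CSV alongside a
#' YAML run manifest recording every parameter and the gate provenance.
#'
#' @param config a [pipeline_config()].
#' @param pairs list of image pairs (from [read_dataset()] or
#'   [simulate_dataset()]); when `NULL`, read from `config$metadata_csv`.
#' @return list of class `tq_run` with elements `qc`, `per_image`,
#'   `objects` (classified), `summaries`, `per_unit`, `stats`, `gates`,
#'   `config`.
#' @export
run_pipeline <- function(config, pairs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(pairs)) {
    if (is.null(config$metadata_csv))
      stop_stage("run_pipeline", "no pairs given and no metadata_csv configured")
    pairs <- read_dataset(config$metadata_csv,
                          config$image_dir %||% dirname(config$metadata_csv))
  }
  if (length(pairs) == 0L)
    stop_stage("run_pipeline", "dataset is empty")

  ## 1. focus QC on the raw images
  qc <- qc_report(pairs, tile_px = config$qc$tile_px,
                  threshold = config$qc$focus_threshold)
  decide <- qc[qc$channel %in% (config$qc$channels %||% "hoechst"), ,
               drop = FALSE]
  verdict <- qc_filter(decide, threshold = config$qc$focus_threshold)
  kept <- pairs[vapply(pairs, `[[`, "", "image_id") %in% verdict$kept]
  if (length(kept) == 0L)
    stop_stage("qc", "all images removed by the focus filter")

  ## 2--4. correct, segment, measure each kept pair
  per_image <- list()
  objects <- list()
  for (p in kept) {
    corr <- lapply(p[c("hoechst", "sytox")], function(img) {
      fld <- estimate_background(img, block_px = config$illumination$block_px,
                                 statistic = config$illumination$statistic,
                                 percentile = config$illumination$percentile)
      correct_illumination(img, fld, combine = config$illumination$combine)
    })
    seg <- tryCatch(
      segment_pair(corr$hoechst, corr$sytox, config$segmentation,
                   channel = config$segment_channel),
      error = function(e) stop_stage("segmentation",
                                     sprintf("image '%s': %s", p$image_id,
                                             conditionMessage(e))))
    per_image[[length(per_image) + 1L]] <-
      data.frame(image_id = p$image_id, threshold = seg$threshold,
                 n_objects = seg$n_objects, degenerate = seg$degenerate,
                 stringsAsFactors = FALSE)
    objects[[length(objects) + 1L]] <-
      measure_objects(seg$labels, corr$hoechst, corr$sytox,
                      metadata = list(image_id = p$image_id,
                                      animal = p$animal,
                                      treatment = p$treatment,
                                      replicate = p$replicate))
  }
  per_image <- do.call(rbind, per_image)
  objects <- do.call(rbind, objects)
  rownames(objects) <- NULL

  ## 5. merge with QC (already filtered; the join re-asserts exclusion)
  objects <- merge_image_and_object_tables(objects, decide)

  ## 6. gates
  g <- config$gating
  gates <- if (identical(g$mode, "manual")) {
    gate_config(g$gate_sytox, g$gate_hoechst, epsilon = g$epsilon,
                min_et_area_px = g$min_et_area_px)
  } else {
    ctrl <- objects[objects$treatment == g$control_treatment, , drop = FALSE]
    if (nrow(ctrl) == 0L)
      stop_stage("gating", "no objects in control treatment '",
                 g$control_treatment, "' to derive auto gates")
    auto_gates(ctrl, epsilon = g$epsilon, min_et_area_px = g$min_et_area_px)
  }

  ## 7. classify and summarise
  objects <- classify_objects(objects, gates)
  summaries <- population_percentages(objects,
                                      group_keys = c("animal", "treatment",
                                                     "replicate"))

  ## 8. aggregate to the biological unit and test
  per_unit <- aggregate_replicates(summaries, unit = config$stats$unit)
  # the t test needs at least two biological units per arm
  testable <- length(unique(per_unit$treatment)) > 1L &&
    config$stats$control %in% per_unit$treatment &&
    min(table(per_unit$treatment)) >= 2L
  stats_tab <- if (testable)
    compare_treatments(per_unit, control = config$stats$control,
                       metrics = config$stats$metrics,
                       welch = isTRUE(config$stats$welch))
  else NULL

  bundle <- structure(list(qc = qc, per_image = per_image,
                           objects = objects, summaries = summaries,
                           per_unit = per_unit, stats = stats_tab,
                           gates = gates, config = config),
                      class = "tq_run")
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

#' @export
print.tq_run <- function(x, ...) {
  cat(sprintf("profiling run: %d images (%d passed QC), %d objects\n",
              length(unique(x$qc$image_id)), nrow(x$per_image),
              nrow(x$objects)))
  print(x$gates)
  if (!is.null(x$stats)) {
    cat("comparisons:\n")
    print(x$stats[, c("treatment_a", "metric", "t", "p", "stars",
                      "mean_increase_pct")], row.names = FALSE)
  }
  invisible(x)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) if (!is.null(x))
    utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  wcsv(bundle$qc, "qc.csv")
  wcsv(bundle$per_image, "per_image.csv")
  wcsv(bundle$objects, "per_object.csv")
  wcsv(bundle$summaries, "summaries.csv")
  wcsv(bundle$per_unit, "per_unit.csv")
  wcsv(bundle$stats, "stats.csv")
  g <- bundle$gates
  manifest <- list(seed = bundle$config$seed,
                   qc = bundle$config$qc,
                   illumination = bundle$config$illumination,
                   segmentation = unclass(bundle$config$segmentation),
                   segment_channel = bundle$config$segment_channel,
                   gates = list(gate_sytox = g$gate_sytox,
                                gate_hoechst = g$gate_hoechst,
                                epsilon = g$epsilon,
                                provenance = g$provenance,
                                degenerate = g$degenerate),
                   stats = bundle$config$stats)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_pipeline_config`, a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- do.call(seg_params, y$segmentation %||% list())
  args <- y[setdiff(names(y), "segmentation")]
  args$segmentation <- seg
  # merge user lists over defaults so partial YAML blocks are valid
  base <- pipeline_config()
  for (blk in c("qc", "illumination", "gating", "stats"))
    if (!is.null(args[[blk]]))
      args[[blk]] <- utils::modifyList(base[[blk]], args[[blk]])
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()] to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$segmentation <- unclass(y$segmentation)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Figures summarising a pipeline run
#'
#' Writes, per treatment, a log-log bivariate scatter of the classified
#' objects with the gate lines drawn at their configured coordinates, and
#' one bar chart of mean population percentages per treatment with
#' significance stars for the ETotic comparison. Produces placeholder
#' panels rather than failing when a table is empty.
#'
#' @param bundle a `tq_run` from [run_pipeline()].
#' @param dir output directory for the PNG files.
#' @return character vector of files written, invisibly.
#' @export
make_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  cols <- c(live = "#4575b4", etotic = "#91bfdb", dead = "#d73027")
  treatments <- unique(bundle$objects$treatment)
  if (length(treatments) == 0L) treatments <- "none"
  for (tr in treatments) {
    f <- file.path(dir, paste0("scatter_", tr, ".png"))
    grDevices::png(f, width = 600, height = 600)
    ob <- bundle$objects[bundle$objects$treatment == tr, , drop = FALSE]
    if (nrow(ob) == 0L) {
      graphics::plot.new()
      graphics::title(main = paste0(tr, " (no objects)"))
    } else {
      graphics::plot(ob$log_hoechst, ob$log_sytox,
                     col = cols[ob$class], pch = 16, cex = 0.5,
                     xlab = "log10 Hoechst mean intensity",
                     ylab = "log10 SytoxGreen mean intensity",
                     main = tr)
      graphics::abline(h = bundle$gates$gate_sytox, lty = 2)
      graphics::abline(v = bundle$gates$gate_hoechst, lty = 2)
      graphics::legend("topleft", legend = names(cols), col = cols,
                       pch = 16, bty = "n")
    }
    grDevices::dev.off()
    files <- c(files, f)
  }
  f <- file.path(dir, "population_bars.png")
  grDevices::png(f, width = 700, height = 500)
  if (nrow(bundle$per_unit) == 0L) {
    graphics::plot.new(); graphics::title(main = "no data")
  } else {
    agg <- aggregate_replicates(
      transform(bundle$per_unit, animal = "all"), unit = "animal")
    m <- t(as.matrix(agg[, c("pct_live", "pct_etotic", "pct_dead")]))
    colnames(m) <- agg$treatment
    bp <- graphics::barplot(m, beside = TRUE, col = cols,
                            ylab = "% of objects", ylim = c(0, 110))
    if (!is.null(bundle$stats)) {
      et <- bundle$stats[bundle$stats$metric == "pct_etotic", ]
      for (i in seq_len(nrow(et))) {
        j <- match(et$treatment_a[i], colnames(m))
        if (!is.na(j)) graphics::text(bp[2, j], m[2, j] + 6, et$stars[i])
      }
    }
    graphics::legend("topright", legend = rownames(m), fill = cols,
                     bty = "n")
  }
  grDevices::dev.off()
  invisible(c(files, f))
}

#' Match measured objects to ground-truth cells
#'
#' Assigns every measured object the nearest ground-truth cell centroid,
#' accepting the match when the distance is within the truth cell's
#' nominal radius (times `slack`). Used to compute recovery and per-class
#' recall on synthetic scenes.
#'
#' @param objects per-object table for one scene (needs `centroid_row`,
#'   `centroid_col`).
#' @param truth the `truth` element of a [generate_scene()] result.
#' @param slack multiplier on the truth radius for match acceptance.
#' @return `objects` with added `truth_id` and `truth_class` (`NA` when
#'   unmatched).
#' @export
match_objects_to_truth <- function(objects, truth, slack = 1) {
  cells <- truth$cells
  objects$truth_id <- NA_integer_
  objects$truth_class <- NA_character_
  if (nrow(objects) == 0L || nrow(cells) == 0L) return(objects)
  for (i in seq_len(nrow(objects))) {
    d <- sqrt((cells$row - objects$centroid_row[i])^2 +
              (cells$col - objects$centroid_col[i])^2)
    j <- which.min(d)
    if (d[j] <= slack * cells$radius_px[j]) {
      objects$truth_id[i] <- cells$id[j]
      objects$truth_class[i] <- cells$class[j]
    }
  }
  objects
}
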